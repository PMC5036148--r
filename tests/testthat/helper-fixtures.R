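# Shared fixture builders. All randomness is seeded explicitly at use sites.

# Sheet with the standard graphene constants.
std_sheet <- function(A = 27.55) graphene_sheet(2.265, 2.1, 0.34, A)

# Single-frame trajectory with particles at given z (nm), optional
# Maxwell-Boltzmann velocities at temperature T (K).
point_trajectory <- function(z, mass = M_WATER_FIX, box = c(5, 5, 5),
                             temperature = NULL, n_frames = 1, dt = 1,
                             seed = NULL) {
  n <- length(z)
  if (!is.null(seed)) set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    fr <- list(positions = cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), z))
    if (!is.null(temperature)) {
      # v ~ N(0, kB T / m) per axis, in nm/ps
      m_kg <- mass * 1e-3 / 6.02214076e23
      sd_ms <- sqrt(1.380649e-23 * temperature / m_kg)
      fr$velocities <- matrix(rnorm(3 * n, sd = sd_ms / 1e3), n, 3)
    }
    fr
  })
  trajectory(frames, masses = rep(mass, n), species = rep("W", n),
             box = box, times = (seq_len(n_frames) - 1) * dt)
}

M_WATER_FIX <- 18.01528

# Lattice spec in the lumped limit: the sheet-water junction is the
# bottleneck resistance, everything downstream is fast and light.
lumped_lattice <- function(g_interface = 2e-10, c_sheet = 5e-21,
                           n_steps = 50000, dt = 0.005, seed = 1) {
  lattice_thermal_spec(
    layer_sites = c(1, 2, 2),
    site_heat_capacity = c(c_sheet, 5e-22, 5e-22),
    link_conductance = c(4e-8, 4e-8, 4e-8),
    interface_conductance = c(g_interface, 4e-8),
    sink_temperature = 300, sink_coupling = 4e-8,
    dt = dt, n_steps = n_steps, noise_amplitude = 0, seed = seed)
}

# Two-peak layered-water fixture emulating a ~1.8 nm gallery.
gallery_spec <- function(n_molecules = 40000, gap = 1.82, seed = 7) {
  layered_density_spec(
    bulk_density = 1.05,
    peaks = list(c(0.32, 1.4, 0.05), c(0.65, 0.6, 0.07)),
    gap_extent = gap, area = 27.55, n_molecules = n_molecules, seed = seed)
}
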