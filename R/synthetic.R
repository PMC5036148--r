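#' Specification of a layered interfacial water density
#'
#' Describes the target mass-density profile of a water gallery confined
#' between a planar wall (z = 0) and a membrane: a bulk plateau plus Gaussian
#' near-wall peaks, the structure characteristic of nanoconfined water. Used
#' by [generate_layered_positions()] to draw particle positions whose binned
#' density converges to this profile.
#'
#' @param bulk_density Bulk plateau density, g cm^-3.
#' @param peaks List of peaks, each `c(center, amplitude, width)`:
#'   center z in nm, amplitude in g cm^-3 *above* bulk, Gaussian sigma in nm.
#' @param gap_extent Span of the water gallery in nm (z in `[0, gap_extent]`).
#' @param area Interface area in nm^2.
#' @param n_molecules Number of water molecules to draw.
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return An object of class `layered_density_spec`.
#' @export
layered_density_spec <- function(bulk_density, peaks = list(), gap_extent,
                                 area, n_molecules, seed = 1L) {
  stopifnot(bulk_density >= 0, gap_extent > 0, area > 0, n_molecules > 0)
  for (p in peaks) {
    if (length(p) != 3) stop("each peak must be c(center, amplitude, width)")
    if (p[2] < 0) stop("peak amplitudes must be >= 0")
    if (p[3] <= 0) stop("peak widths must be > 0")
    if (p[1] < 0 || p[1] > gap_extent)
      stop("peak centers must lie within [0, gap_extent]")
  }
  structure(list(bulk_density = bulk_density, peaks = peaks,
                 gap_extent = gap_extent, area = area,
                 n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed)),
            class = "layered_density_spec")
}

# Evaluate the generating density (g cm^-3) of a layered spec at z (nm).
layered_density_fun <- function(spec) {
  function(z) {
    d <- rep(spec$bulk_density, length(z))
    for (p in spec$peaks)
      d <- d + p[2] * exp(-(z - p[1])^2 / (2 * p[3]^2))
    d
  }
}

#' Draw water positions from a layered density specification
#'
#' Samples `n_molecules` z-coordinates by inverse-CDF sampling of the mixture
#' density (bulk plateau + Gaussian peaks) over `[0, gap_extent]`, with x and
#' y uniform over the interface area. Per-particle masses are assigned so that
#' the binned mass-density profile converges to the specified density as the
#' number of molecules grows.
#'
#' @param spec A [layered_density_spec()].
#' @return A single-frame [trajectory()] of species `"W"`.
#' @examples
#' spec <- layered_density_spec(0.997, list(c(0.3, 1.5, 0.08)),
#'                              gap_extent = 1.82, area = 27.55,
#'                              n_molecules = 5000, seed = 7)
#' trj <- generate_layered_positions(spec)
#' @export
generate_layered_positions <- function(spec) {
  stopifnot(inherits(spec, "layered_density_spec"))
  dens <- layered_density_fun(spec)
  ngrid <- 4096L
  z <- seq(0, spec$gap_extent, length.out = ngrid)
  d <- dens(z)
  dz <- z[2] - z[1]
  total <- sum((d[-1] + d[-ngrid]) / 2) * dz  # trapezoid, g cm^-3 * nm
  if (total <= 0) stop("non-normalizable density: total density is zero")
  cdf <- c(0, cumsum((d[-1] + d[-ngrid]) / 2) * dz) / total

  set.seed(spec$seed)
  n <- spec$n_molecules
  u <- stats::runif(n)
  zi <- stats::approx(cdf, z, xout = u, ties = "ordered")$y
  side <- sqrt(spec$area)
  pos <- cbind(stats::runif(n, 0, side), stats::runif(n, 0, side), zi)

  # total mass implied by the spec density (g), split evenly; masses in g/mol
  mass_total_g <- spec$area * total * NM3_TO_CM3
  m <- rep(mass_total_g * N_AVOGADRO / n, n)
  trajectory(list(list(positions = pos)), masses = m,
             species = rep("W", n),
             box = c(side, side, spec$gap_extent), times = 0)
}

#' Specification of a Brownian test trajectory
#'
#' @param diffusion_coefficient Diffusion coefficient D in nm^2 ps^-1.
#' @param n_particles Number of independent walkers.
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame spacing in ps.
#' @param dims Spatial dimensionality of the walk (1, 2 or 3); remaining axes
#'   stay frozen at their initial coordinate.
#' @param seed Integer RNG seed.
#' @return An object of class `brownian_spec`.
#' @export
brownian_spec <- function(diffusion_coefficient, n_particles, n_frames, dt,
                          dims = 3L, seed = 1L) {
  stopifnot(diffusion_coefficient >= 0, n_particles >= 1, n_frames >= 2,
            dt > 0, dims %in% 1:3)
  structure(list(diffusion_coefficient = diffusion_coefficient,
                 n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames), dt = dt,
                 dims = as.integer(dims), seed = as.integer(seed)),
            class = "brownian_spec")
}

#' Generate an ideal Brownian trajectory
#'
#' Independent Gaussian increments per diffusing axis with variance
#' \eqn{2 D \Delta t} per step, so the ensemble MSD is exactly
#' \eqn{2 d_i D t}. Coordinates are unwrapped (no periodic imaging).
#'
#' @param spec A [brownian_spec()].
#' @return A [trajectory()] with `n_frames` frames.
#' @export
generate_brownian_trajectory <- function(spec) {
  stopifnot(inherits(spec, "brownian_spec"))
  set.seed(spec$seed)
  n <- spec$n_particles
  nf <- spec$n_frames
  sd_step <- sqrt(2 * spec$diffusion_coefficient * spec$dt)
  box_side <- 50
  start <- matrix(stats::runif(3 * n, 0, box_side), ncol = 3)
  # increments: frames-1 x particles per axis; frozen axes get zero increments
  frames <- vector("list", nf)
  coords <- start
  frames[[1]] <- list(positions = coords)
  for (k in 2:nf) {
    step <- matrix(0, n, 3)
    if (sd_step > 0)
      step[, seq_len(spec$dims)] <-
        matrix(stats::rnorm(n * spec$dims, sd = sd_step), n, spec$dims)
    coords <- coords + step
    frames[[k]] <- list(positions = coords)
  }
  trajectory(frames, masses = rep(M_WATER, n), species = rep("W", n),
             box = rep(box_side, 3), periodic = c(FALSE, FALSE, FALSE),
             times = (seq_len(nf) - 1) * spec$dt)
}

#' Specification of the 1-D layered heat-conduction lattice
#'
#' A chain of lumped thermal nodes in three layers (sheet, water, lipid) with
#' per-layer site heat capacities and internal link conductances, distinct
#' junction conductances at the sheet-water and water-lipid interfaces, and a
#' heat sink coupled to the far (lipid) end. The lattice is the desk-scale
#' surrogate for heating / pulse-relaxation molecular-dynamics protocols.
#'
#' @param layer_sites Integer length-3: sites in (sheet, water, lipid).
#' @param site_heat_capacity Numeric length-3: J K^-1 per site per layer.
#' @param link_conductance Numeric length-3: W K^-1 between adjacent sites
#'   within each layer.
#' @param interface_conductance Numeric length-2: W K^-1 at the sheet-water
#'   and water-lipid junctions.
#' @param sink_temperature Heat-sink temperature, K.
#' @param sink_coupling Conductance to the sink from the last lipid site,
#'   W K^-1 (0 decouples the sink).
#' @param heating_power Power into the sheet layer, W (heating protocol).
#' @param dt Time step, ps.
#' @param n_steps Number of steps.
#' @param noise_amplitude Std-dev (K) of observation noise added to recorded
#'   temperatures; the interior dynamics are unaffected.
#' @param seed Integer RNG seed (used only for observation noise).
#' @return An object of class `lattice_thermal_spec`.
#' @export
lattice_thermal_spec <- function(layer_sites, site_heat_capacity,
                                 link_conductance, interface_conductance,
                                 sink_temperature = 300, sink_coupling = 0,
                                 heating_power = 0, dt = 0.1,
                                 n_steps = 1000L, noise_amplitude = 0,
                                 seed = 1L) {
  stopifnot(length(layer_sites) == 3, all(layer_sites >= 1),
            length(site_heat_capacity) == 3, all(site_heat_capacity > 0),
            length(link_conductance) == 3, all(link_conductance > 0),
            length(interface_conductance) == 2,
            all(interface_conductance > 0),
            sink_temperature > 0, sink_coupling >= 0, heating_power >= 0,
            dt > 0, n_steps >= 1, noise_amplitude >= 0)
  spec <- structure(list(layer_sites = as.integer(layer_sites),
                         site_heat_capacity = site_heat_capacity,
                         link_conductance = link_conductance,
                         interface_conductance = interface_conductance,
                         sink_temperature = sink_temperature,
                         sink_coupling = sink_coupling,
                         heating_power = heating_power, dt = dt,
                         n_steps = as.integer(n_steps),
                         noise_amplitude = noise_amplitude,
                         seed = as.integer(seed)),
                    class = "lattice_thermal_spec")
  g_max <- max(link_conductance, interface_conductance, sink_coupling)
  c_min <- min(site_heat_capacity)
  if (dt * 1e-12 * g_max / c_min >= 0.5)
    stop("unstable time step: dt * max(conductance) / min(capacity) = ",
         signif(dt * 1e-12 * g_max / c_min, 3), " >= 0.5")
  spec
}

# Assemble the site-level capacity vector and adjacent-link conductances.
lattice_topology <- function(spec) {
  ns <- spec$layer_sites
  layer <- rep(c("sheet", "water", "lipid"), ns)
  cap <- rep(spec$site_heat_capacity, ns)
  # conductance between site i and i+1
  g <- numeric(sum(ns) - 1)
  pos <- 0
  for (l in 1:3) {
    if (ns[l] > 1)
      g[pos + seq_len(ns[l] - 1)] <- spec$link_conductance[l]
    pos <- pos + ns[l]
    if (l < 3) g[pos] <- spec$interface_conductance[l]
  }
  list(layer = layer, cap = cap, g = g)
}

#' Simulate heat conduction on the layered lattice
#'
#' Explicit forward-Euler update of the energy balance
#' \eqn{C_i dT_i = \sum_j g_{ij}(T_j - T_i) dt + s_i dt}: pure pairwise
#' exchange (exactly energy-conserving), a constant power source into the
#' sheet layer under the `heating` protocol, and under `pulse_relaxation` a
#' drive that raises the sheet to `pulse_target` during `pulse_duration`
#' followed by free relaxation. The sink exchanges heat with the last lipid
#' site through `sink_coupling`.
#'
#' @param spec A [lattice_thermal_spec()].
#' @param protocol `"heating"` or `"pulse_relaxation"`.
#' @param pulse_duration Pulse length in ps (pulse protocol).
#' @param pulse_target Sheet temperature targeted by the pulse, K.
#' @param record_every Record every k-th step (thins the output).
#' @return A list of class `lattice_run` with elements
#'   `series` (named list of [temperature_series()] per layer, observation
#'   noise applied), `profile` (sites x recorded-times matrix, K, noise-free),
#'   `times` (ps), `layer` (site layer labels), `energy` (total lattice energy
#'   trace, J), `sink_heat` (cumulative heat delivered to the sink, J),
#'   `source_heat` (cumulative heat injected, J), and `spec`.
#' @export
simulate_lattice <- function(spec, protocol = c("heating", "pulse_relaxation"),
                             pulse_duration = 100, pulse_target = 500,
                             record_every = 1L) {
  stopifnot(inherits(spec, "lattice_thermal_spec"))
  protocol <- match.arg(protocol)
  topo <- lattice_topology(spec)
  nsite <- length(topo$cap)
  dt_s <- spec$dt * 1e-12
  temp <- rep(spec$sink_temperature, nsite)
  sheet_idx <- which(topo$layer == "sheet")
  last <- nsite

  nrec <- spec$n_steps %/% record_every
  prof <- matrix(NA_real_, nsite, nrec)
  times <- numeric(nrec)
  energy <- numeric(nrec)
  sink_tr <- numeric(nrec)
  source_tr <- numeric(nrec)
  sink_heat <- 0
  source_heat <- 0
  set.seed(spec$seed)
  # drive time constant for the pulse: fast relative to the pulse length
  drive_tau_s <- pulse_duration * 1e-12 / 10

  rec <- 0L
  for (step in seq_len(spec$n_steps)) {
    t_ps <- step * spec$dt
    flow <- topo$g * diff(temp)               # W into site i from i+1
    dE <- c(flow, 0) - c(0, flow)             # antisymmetric exchange
    dE <- dE * dt_s
    if (spec$sink_coupling > 0) {
      q_sink <- spec$sink_coupling * (temp[last] - spec$sink_temperature) * dt_s
      dE[last] <- dE[last] - q_sink
      sink_heat <- sink_heat + q_sink
    }
    if (protocol == "heating" && spec$heating_power > 0) {
      dE[sheet_idx] <- dE[sheet_idx] +
        spec$heating_power * dt_s / length(sheet_idx)
      source_heat <- source_heat + spec$heating_power * dt_s
    }
    if (protocol == "pulse_relaxation" && t_ps <= pulse_duration) {
      pull <- (pulse_target - temp[sheet_idx]) *
        (1 - exp(-dt_s / drive_tau_s))
      dE[sheet_idx] <- dE[sheet_idx] + topo$cap[sheet_idx] * pull
      source_heat <- source_heat + sum(topo$cap[sheet_idx] * pull)
    }
    temp <- temp + dE / topo$cap
    if (any(!is.finite(temp)) || any(abs(temp) > 1e7))
      stop("lattice simulation diverged at step ", step,
           " (t = ", signif(t_ps, 4), " ps); reduce dt")
    if (step %% record_every == 0L) {
      rec <- rec + 1L
      prof[, rec] <- temp
      times[rec] <- t_ps
      energy[rec] <- sum(topo$cap * temp)
      sink_tr[rec] <- sink_heat
      source_tr[rec] <- source_heat
    }
  }

  noise <- function(x) x + stats::rnorm(length(x), sd = spec$noise_amplitude)
  series <- lapply(c(sheet = "sheet", water = "water", lipid = "lipid"),
                   function(l) {
    idx <- which(topo$layer == l)
    temperature_series(times, noise(colMeans(prof[idx, , drop = FALSE])),
                       label = l)
  })
  structure(list(series = series, profile = prof, times = times,
                 layer = topo$layer, energy = energy, sink_heat = sink_tr,
                 source_heat = source_tr, spec = spec),
            class = "lattice_run")
}

#' @export
print.lattice_run <- function(x, ...) {
  cat("lattice_run: ", length(x$layer), " sites (",
      paste(x$spec$layer_sites, collapse = "/"), "), ",
      length(x$times), " recorded steps, t = ",
      signif(max(x$times), 4), " ps\n", sep = "")
  fin <- vapply(x$series, function(s) s$temperature[length(s$temperature)],
                numeric(1))
  cat("  final layer T [K]: ",
      paste(names(fin), signif(fin, 5), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
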