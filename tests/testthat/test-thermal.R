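test_that("slab temperatures recover a Maxwell-Boltzmann ensemble", {
  set.seed(14)
  trj <- point_trajectory(z = runif(3000, 0, 3), temperature = 300,
                          n_frames = 10, seed = 14)
  prof <- slab_temperature_profile(trj, bin_width = 1)
  expect_true(all(abs(prof$temperature / 300 - 1) < 0.03))

  # kinetic scaling identity: v -> sqrt(2) v doubles T exactly
  doubled <- trajectory(lapply(trj$frames, function(f)
    list(positions = f$positions, velocities = sqrt(2) * f$velocities)),
    trj$masses, trj$species, trj$box, trj$times, trj$periodic)
  prof2 <- slab_temperature_profile(doubled, bin_width = 1)
  expect_equal(prof2$temperature, 2 * prof$temperature, tolerance = 1e-12)
})

test_that("empty slabs are reported missing, not cold", {
  set.seed(15)
  z <- c(runif(50, 0, 1), runif(50, 2, 3))  # nobody between 1 and 2 nm
  trj <- point_trajectory(z = z, temperature = 300, seed = 15)
  prof <- slab_temperature_profile(trj, bin_width = 1)
  expect_true(is.na(prof$temperature[2]))
  expect_false(anyNA(prof$temperature[c(1, 3)]))
})

test_that("relaxation fit is the identity on exact exponentials", {
  # the transient-set constants give tau = rho c d / G = 159.1 ps
  t <- seq(0, 800, 2)
  ser <- temperature_series(t, 300 + 200 * exp(-t / 159.1), "sheet")
  expect_lt(abs(relaxation_time(ser, 300)$tau / 159.1 - 1), 1e-3)

  for (tau in c(10, 100, 1000, 1e4)) {
    t <- seq(0, 5 * tau, length.out = 400)
    ser <- temperature_series(t, 300 + 150 * exp(-t / tau), "sheet")
    expect_lt(abs(relaxation_time(ser, 300)$tau / tau - 1), 1e-3)
  }

  flat <- temperature_series(0:50, rep(300, 51), "sheet")
  expect_error(relaxation_time(flat, 300), "above the environment")
  hot_flat <- temperature_series(0:50, rep(400, 51), "sheet")
  expect_error(relaxation_time(hot_flat, 300), "does not decay")
})

test_that("lattice pulse relaxation matches the lumped C/G time constant", {
  g1 <- 2e-10
  c_sheet <- 5e-21
  run <- simulate_lattice(lumped_lattice(g_interface = g1,
                                         c_sheet = c_sheet),
                          "pulse_relaxation", pulse_duration = 100,
                          pulse_target = 500, record_every = 10)
  post <- run$times > 100
  ser <- temperature_series(run$times[post],
                            run$series$sheet$temperature[post], "sheet")
  tau <- relaxation_time(ser, 300)$tau
  expect_lt(abs(tau / (c_sheet / g1 * 1e12) - 1), 0.05)
})

test_that("Kapitza conductance is the areal heat capacity over tau", {
  sheet <- std_sheet()
  expect_equal(areal_heat_capacity(sheet), 1.617e-3, tolerance = 1e-3)
  expect_equal(kapitza_conductance(sheet, 159.1), 10.16, tolerance = 1e-3)
  # intensive: independent of the sheet area
  expect_equal(kapitza_conductance(std_sheet(A = 1), 159.1),
               kapitza_conductance(std_sheet(A = 1000), 159.1))
  # tau -> infinity limit
  expect_lt(kapitza_conductance(sheet, 1e12), 1e-8)
  expect_error(kapitza_conductance(sheet, 0))
})

test_that("critical power interpolates the threshold crossing", {
  p <- seq(0, 12, 0.5)
  curve <- delta_t_curve(p, pmax(0, 4 * (p - 2.5)))
  expect_equal(critical_power(curve, 20), 7.5, tolerance = 1e-12)

  flat <- delta_t_curve(p, rep(3, length(p)))
  expect_error(critical_power(flat, 20), "never crossed")

  # noisy replicate curves: averaged crossing within 10% of the truth
  set.seed(77)
  reps <- replicate(5, pmax(0, 4 * (p - 2.5)) + rnorm(length(p), sd = 1))
  noisy <- delta_t_curve(p, rowMeans(reps),
                         stderr = apply(reps, 1, sd) / sqrt(5))
  expect_lt(abs(critical_power(noisy, 20) / 7.5 - 1), 0.1)

  # p_c is non-increasing in the response slope
  p_wide <- seq(0, 16, 0.5)
  pcs <- vapply(c(2, 4, 8), function(a)
    critical_power(delta_t_curve(p_wide, pmax(0, a * (p_wide - 2.5))), 20),
    numeric(1))
  expect_true(all(diff(pcs) <= 0))
})

test_that("lattice steady state seen through pseudo-particles matches the resistor model", {
  # lumped-limit heating run; map lattice conductances onto the continuum
  # model through a notional area
  g1 <- 2e-10
  p_watt <- 3e-11
  sp <- lattice_thermal_spec(
    layer_sites = c(1, 2, 2), site_heat_capacity = c(5e-21, 5e-22, 5e-22),
    link_conductance = c(4e-8, 4e-8, 4e-8),
    interface_conductance = c(g1, 4e-8), sink_temperature = 300,
    sink_coupling = 4e-8, heating_power = p_watt, dt = 0.005,
    n_steps = 60000, seed = 6)
  run <- simulate_lattice(sp, "heating", record_every = 100)
  steady <- run$profile[, ncol(run$profile)]

  a_m2 <- 5e-21 / areal_heat_capacity(std_sheet())
  dz <- 0.1                                     # nm between lattice sites
  stack <- interface_stack(G_C = g1 / a_m2 / 1e6,
                           kappa_L = 4e-8 * dz * 1e-9 / a_m2,
                           delta = 2 * dz, t_W = 2 * dz, z_s = 2 * dz)
  ss <- steady_state_profile(stack, p = p_watt / a_m2 / 1e9)
  expect_lt(abs(steady[1] / ss$T_G - 1), 0.02)          # sheet node
  expect_lt(abs(mean(steady[2:3]) / ss$T_W - 1), 0.02)  # water plateau

  # pseudo-particle readout: slabs at each site's temperature (jitter keeps
  # every particle inside its site's slab)
  z_site <- (seq_along(steady) - 1) * dz + dz / 2
  set.seed(16)
  z <- rep(z_site, each = 400) + runif(400 * length(steady), -0.045, 0.045)
  trj <- point_trajectory(z = z, n_frames = 4, temperature = 300, seed = 16)
  for (f in seq_along(trj$frames))
    trj$frames[[f]]$velocities <- trj$frames[[f]]$velocities *
      rep(sqrt(steady / 300), each = 400)
  prof <- slab_temperature_profile(trj, bin_width = dz)
  expect_equal(prof$temperature, steady, tolerance = 0.05)
})
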