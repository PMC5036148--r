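test_that("layered position generator reproduces its target density", {
  # flat case: no peaks, binned profile sits at the bulk plateau
  spec <- layered_density_spec(0.997, list(), gap_extent = 2, area = 25,
                               n_molecules = 1e5, seed = 3)
  prof <- density_profile(generate_layered_positions(spec), bin_width = 0.1)
  expect_lt(max(abs(prof$density / 0.997 - 1)), 0.06)

  # two-peak gallery: exactly two layering peaks, both above bulk
  prof2 <- density_profile(generate_layered_positions(gallery_spec()),
                           bin_width = 0.1)
  prof2$bulk_density <- 0.997
  peaks <- detect_peaks(prof2)
  expect_length(peaks, 2)
  expect_true(all(vapply(peaks, `[[`, numeric(1), "amplitude") > 0.997))

  # binned profile matches the generating density pointwise (4 sigma of the
  # multinomial count per bin)
  dens <- nanoheat:::layered_density_fun(gallery_spec())
  mids <- bin_centers(prof2)
  # the generating density has support [0, gap]: clip the edge bins
  expected <- vapply(mids, function(z)
    stats::integrate(dens, max(z - 0.05, 0),
                     min(z + 0.05, 1.82))$value / 0.1, numeric(1))
  n_tot <- 40000
  p_bin <- expected * 0.1 / sum(expected * 0.1)
  count_sd <- sqrt(n_tot * p_bin * (1 - p_bin))
  obs_count <- prof2$density / sum(prof2$density) * n_tot
  exp_count <- n_tot * p_bin
  expect_lt(max(abs(obs_count - exp_count) / count_sd), 4)
})

test_that("layered generator recovers a known Gaussian peak mass", {
  spec <- layered_density_spec(0.4, list(c(0.5, 1.2, 0.06)), gap_extent = 2,
                               area = 25, n_molecules = 1e5, seed = 4)
  prof <- density_profile(generate_layered_positions(spec), bin_width = 0.05)
  prof$bulk_density <- 0.4
  pk <- detect_peaks(prof)[[1]]
  m1 <- first_peak_mass(prof, pk)
  f <- function(z) 0.4 + 1.2 * exp(-(z - 0.5)^2 / (2 * 0.06^2))
  oracle <- 25 * stats::integrate(f, pk$z0, pk$z1)$value * 1e-21
  expect_lt(abs(m1 / oracle - 1), 0.02)
})

test_that("layered generator rejects a zero density and is seed-stable", {
  expect_error(
    generate_layered_positions(
      layered_density_spec(0, list(), gap_extent = 1, area = 10,
                           n_molecules = 10)),
    "non-normalizable")
  a <- generate_layered_positions(gallery_spec(n_molecules = 500, seed = 9))
  b <- generate_layered_positions(gallery_spec(n_molecules = 500, seed = 9))
  c <- generate_layered_positions(gallery_spec(n_molecules = 500, seed = 10))
  expect_identical(a$frames[[1]]$positions, b$frames[[1]]$positions)
  expect_false(identical(a$frames[[1]]$positions, c$frames[[1]]$positions))
})

test_that("Brownian generator honours D = 0 and the seed contract", {
  frozen <- generate_brownian_trajectory(brownian_spec(0, 20, 10, 0.5,
                                                       seed = 2))
  for (f in 2:10)
    expect_identical(frozen$frames[[f]]$positions,
                     frozen$frames[[1]]$positions)

  t1 <- generate_brownian_trajectory(brownian_spec(0.25, 150, 800, 1,
                                                   seed = 31))
  t2 <- generate_brownian_trajectory(brownian_spec(0.25, 150, 800, 1,
                                                   seed = 32))
  expect_false(identical(t1$frames[[2]]$positions, t2$frames[[2]]$positions))
  d1 <- diffusion_coefficient(msd(t1))$D
  d2 <- diffusion_coefficient(msd(t2))$D
  expect_lt(abs(d1 / 0.25 - 1), 0.1)
  expect_lt(abs(d2 / 0.25 - 1), 0.1)
})

test_that("equilibrated lattice with no heating stays at the sink temperature", {
  sp <- lattice_thermal_spec(c(1, 3, 3), c(2e-21, 1e-21, 1e-21),
                             c(1e-9, 1e-9, 1e-9), c(4e-10, 6e-10),
                             sink_temperature = 300, sink_coupling = 1e-9,
                             heating_power = 0, dt = 0.05, n_steps = 2000,
                             seed = 5)
  run <- simulate_lattice(sp, "heating")
  expect_equal(max(abs(run$profile - 300)), 0)
})

test_that("pulse relaxation decays monotonically and is single-exponential in the lumped limit", {
  run <- simulate_lattice(lumped_lattice(), "pulse_relaxation",
                          pulse_duration = 100, pulse_target = 500,
                          record_every = 10)
  post <- run$times > 100
  sheet <- run$series$sheet$temperature[post]
  expect_gt(sheet[1], 350)           # pulse heated the sheet well above sink
  expect_true(all(diff(sheet) <= 1e-9))
  ser <- temperature_series(run$times[post], sheet, "sheet")
  rx <- relaxation_time(ser, 300)
  expect_lt(rx$residual_sd / rx$delta_T0, 0.01)
})

test_that("steady heating drop across the sheet-water junction is power over conductance", {
  g1 <- 4e-10
  sp <- lattice_thermal_spec(c(1, 4, 4), c(2e-21, 4e-22, 4e-22),
                             c(1e-9, 5e-9, 1e-9), c(g1, 1e-9),
                             sink_temperature = 300, sink_coupling = 2e-9,
                             heating_power = 1e-9, dt = 0.02,
                             n_steps = 60000, seed = 3)
  run <- simulate_lattice(sp, "heating", record_every = 200)
  nrec <- length(run$times)
  drop <- run$profile[1, nrec] - run$profile[2, nrec]
  expect_lt(abs(drop * g1 / 1e-9 - 1), 0.02)

  # flux continuity: power delivered to the sink equals power injected
  late <- (nrec - 50):nrec
  p_sink <- mean(diff(run$sink_heat[late]) / diff(run$times[late])) / 1e-12
  expect_lt(abs(p_sink / 1e-9 - 1), 0.02)
})

test_that("lattice conserves energy with the sink decoupled", {
  sp <- lattice_thermal_spec(c(2, 4, 4), c(2e-21, 1e-21, 1e-21),
                             c(1e-9, 1e-9, 1e-9), c(4e-10, 6e-10),
                             sink_temperature = 300, sink_coupling = 0,
                             dt = 0.05, n_steps = 1e5, seed = 2)
  run <- simulate_lattice(sp, "pulse_relaxation", pulse_duration = 5,
                          pulse_target = 500, record_every = 100)
  post <- run$times > 5          # free evolution after the pulse
  drift <- diff(range(run$energy[post])) / mean(run$energy[post])
  expect_lt(drift, 1e-6)
})

test_that("lattice rejects unstable time steps and is reproducible by seed", {
  expect_error(
    lattice_thermal_spec(c(1, 2, 2), c(1e-22, 1e-22, 1e-22),
                         c(5e-9, 5e-9, 5e-9), c(5e-9, 5e-9),
                         dt = 0.05, n_steps = 10),
    "unstable")
  sp <- lattice_thermal_spec(c(1, 2, 2), c(2e-21, 1e-21, 1e-21),
                             c(1e-9, 1e-9, 1e-9), c(4e-10, 6e-10),
                             sink_coupling = 1e-9, dt = 0.05, n_steps = 500,
                             noise_amplitude = 1, seed = 42)
  r1 <- simulate_lattice(sp, "pulse_relaxation")
  r2 <- simulate_lattice(sp, "pulse_relaxation")
  expect_identical(r1$profile, r2$profile)
  expect_identical(r1$series$sheet$temperature, r2$series$sheet$temperature)
})
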