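fig5_stack <- function(...) interface_stack(G_C = 12.60, kappa_L = 0.12,
                                            delta = 4, ...)

test_that("steady-state solution reproduces the serial-resistor algebra", {
  st <- fig5_stack()
  cold <- steady_state_profile(st, p = 0)
  expect_true(all(cold$profile$temperature == 300))

  ss <- steady_state_profile(st, p = 1)
  expect_equal(ss$T_G - ss$T_W, 79.37, tolerance = 1e-4)   # q / G_C
  expect_equal(ss$T_W - 300, 33.33, tolerance = 1e-3)      # q delta / kappa_L
  expect_equal(ss$T_G, 412.70, tolerance = 1e-4)

  # linearity: halving kappa_L doubles the lipid drop, leaves the interface
  # drop untouched
  half <- steady_state_profile(interface_stack(G_C = 12.60, kappa_L = 0.06,
                                               delta = 4), p = 1)
  expect_equal(half$T_W - 300, 2 * (ss$T_W - 300), tolerance = 1e-12)
  expect_equal(half$T_G - half$T_W, ss$T_G - ss$T_W, tolerance = 1e-12)

  # flux continuity: lipid conductive flux equals the through-interface flux
  grad <- (ss$T_W - 300) / (st$delta * 1e-9)
  expect_equal(st$kappa_L * grad, ss$q_W_m2, tolerance = 1e-12)

  # superposition in p
  s2 <- steady_state_profile(st, p = 2.5)
  expect_equal(s2$profile$temperature - 300,
               2.5 * (ss$profile$temperature - 300), tolerance = 1e-12)
})

test_that("lumped transient solution satisfies its energy balance", {
  sheet <- std_sheet()
  st <- interface_stack(G_C = 10.16, kappa_L = 0.12)
  ser <- transient_graphene_temperature(sheet, st, p = 16.25, times = 0:400)
  expect_equal(ser$temperature[1], 300)
  late <- transient_graphene_temperature(sheet, st, p = 16.25, times = 1e6)
  expect_equal(late$temperature, 300 + 1599.4, tolerance = 1e-4)

  # ODE residual by central differences: C dT/dt = eta p - G (T - T_W)
  h <- 1e-3
  t0 <- c(10, 50, 150, 300)
  tt <- function(t) transient_graphene_temperature(sheet, st, 16.25,
                                                   t)$temperature
  dTdt <- (tt(t0 + h) - tt(t0 - h)) / (2 * h * 1e-12)
  rhs <- 16.25e9 - 10.16e6 * (tt(t0) - 300)
  resid <- areal_heat_capacity(sheet) * dTdt - rhs
  expect_lt(max(abs(resid / 16.25e9)), 1e-5)

  # independent numerical integration of the same balance
  out <- deSolve::ode(
    y = c(T = 300), times = seq(0, 400, 1) * 1e-12,
    func = function(t, y, p)
      list((16.25e9 - 10.16e6 * (y - 300)) / areal_heat_capacity(sheet)))
  expect_equal(ser$temperature, unname(out[, "T"]), tolerance = 1e-6)

  # the transient plateau equals the steady solution's sheet temperature
  # when anchored at the steady water plateau
  ss <- steady_state_profile(interface_stack(G_C = 10.16, kappa_L = 0.12),
                             p = 16.25)
  plateau <- transient_graphene_temperature(
    sheet, interface_stack(G_C = 10.16, kappa_L = 0.12), p = 16.25,
    times = 1e7, T_w = ss$T_W)
  expect_equal(plateau$temperature, ss$T_G, tolerance = 1e-10)
})

test_that("steady-parameter fit is exact on noiseless profiles and robust to noise", {
  st <- fig5_stack()
  geom <- list(z_s = st$z_s, delta = st$delta, T_e = 300, eta = 1)
  ss <- steady_state_profile(st, p = 1)
  fit <- fit_steady_parameters(ss$profile, p = 1, geometry = geom)
  expect_lt(abs(fit$G_C / 12.60 - 1), 1e-3)
  expect_lt(abs(fit$kappa_L / 0.12 - 1), 1e-3)

  # additive N(0, 2 K) noise on ~80 bins: recovery within 5%
  st6 <- interface_stack(G_C = 12.60, kappa_L = 0.12, delta = 6)
  ss6 <- steady_state_profile(st6, p = 1)
  set.seed(23)
  noisy <- temperature_profile(
    ss6$profile$z_bins,
    ss6$profile$temperature + rnorm(length(ss6$profile$temperature), sd = 2))
  fit6 <- fit_steady_parameters(noisy, p = 1,
                                geometry = list(z_s = st6$z_s, delta = 6,
                                                T_e = 300, eta = 1))
  expect_gt(length(ss6$profile$temperature), 75)
  expect_lt(abs(fit6$G_C / 12.60 - 1), 0.05)
  expect_lt(abs(fit6$kappa_L / 0.12 - 1), 0.05)

  # zero interface drop: conductance unidentifiable
  flat <- ss$profile
  flat$temperature[bin_centers(flat) < 0] <- ss$T_W
  expect_warning(bad <- fit_steady_parameters(flat, 1, geom),
                 "unidentifiable")
  expect_identical(bad$G_C, Inf)

  # no lipid gradient at all: degenerate
  degen <- temperature_profile(ss$profile$z_bins,
                               rep(350, length(ss$profile$temperature)))
  expect_error(fit_steady_parameters(degen, 1, geom), "degenerate")
})

test_that("transient fit recovers the conductance and flags short series", {
  sheet <- std_sheet()
  st <- interface_stack(G_C = 10.16, kappa_L = 0.12)
  ser <- transient_graphene_temperature(sheet, st, p = 16.25, times = 0:400)
  fit <- fit_transient(ser, sheet, p = 16.25)
  expect_lt(abs(fit$G_C / 10.16 - 1), 1e-3)
  expect_true(fit$identifiable)

  early <- transient_graphene_temperature(sheet, st, p = 16.25, times = 0:10)
  expect_warning(flag <- fit_transient(early, sheet, p = 16.25),
                 "weakly identified")
  expect_false(flag$identifiable)
})

test_that("transient fit agrees with the lattice surrogate's conductance", {
  g1 <- 2e-10
  c_sheet <- 5e-21
  a_m2 <- c_sheet / areal_heat_capacity(std_sheet())
  p_watt <- 3e-11
  sp <- lattice_thermal_spec(
    layer_sites = c(1, 2, 2), site_heat_capacity = c(c_sheet, 5e-22, 5e-22),
    link_conductance = c(4e-8, 4e-8, 4e-8),
    interface_conductance = c(g1, 4e-8), sink_temperature = 300,
    sink_coupling = 4e-8, heating_power = p_watt, dt = 0.005,
    n_steps = 40000, seed = 8)
  run <- simulate_lattice(sp, "heating", record_every = 20)
  fit <- fit_transient(run$series$sheet, std_sheet(),
                       p = p_watt / a_m2 / 1e9)
  expect_lt(abs(fit$G_C / (g1 / a_m2 / 1e6) - 1), 0.05)
})

test_that("critical-power inversion follows the steady model", {
  st <- fig5_stack()
  expect_equal(predict_critical_power(st, 20, "lipid_surface"), 0.6,
               tolerance = 1e-12)
  expect_equal(predict_critical_power(st, 40, "lipid_surface"), 1.2,
               tolerance = 1e-12)
  expect_equal(predict_critical_power(st, 20, "lipid_average"), 1.2,
               tolerance = 1e-12)
  # partition factor that reconciles the serial model with an observed
  # critical power of 7.5 GW m^-2 at a 20 K threshold
  expect_equal(fit_flux_partition(st, 7.5, 20), 0.08, tolerance = 1e-12)
})
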