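#' Serial-resistor description of the sheet-water-membrane interface
#'
#' Parameters of the analytical Fourier model: heat injected into the sheet
#' crosses the sheet/water/lipid interface (conductance `G_C`), traverses the
#' intercalated water layer (treated as isothermal: its conductivity, ~0.61
#' W m^-1 K^-1, is large against the lipid's ~0.12), then conducts through
#' the lipid bilayer (conductivity `kappa_L`, thickness `delta`) into the
#' heat sink at `T_e`. The flux-partition factor `eta` is the fraction of the
#' injected power that takes this serial path; `eta = 1` is the pure serial
#' model, `eta < 1` accounts for parallel leakage through bulk water outside
#' the confined region.
#'
#' @param G_C Interfacial thermal conductance, MW m^-2 K^-1.
#' @param kappa_L Lipid thermal conductivity, W m^-1 K^-1.
#' @param delta Lipid bilayer thickness, nm (default 4, a typical POPC
#'   bilayer).
#' @param kappa_W Water thermal conductivity, W m^-1 K^-1 (default 0.61).
#' @param t_W Intercalated water layer thickness, nm.
#' @param z_s Position of the lipid surface, nm (default: `t_W`, i.e. water
#'   fills `[0, z_s]`).
#' @param T_e Heat-sink temperature, K (default 300).
#' @param eta Flux-partition factor in `[0, 1]` (default 1).
#' @return An object of class `interface_stack`.
#' @export
interface_stack <- function(G_C, kappa_L, delta = 4, kappa_W = 0.61,
                            t_W = 1.82, z_s = t_W, T_e = 300, eta = 1) {
  stopifnot(G_C > 0, kappa_L > 0, delta > 0, kappa_W > 0, t_W >= 0,
            z_s >= 0, T_e > 0, eta >= 0, eta <= 1)
  structure(list(G_C = G_C, kappa_L = kappa_L, delta = delta,
                 kappa_W = kappa_W, t_W = t_W, z_s = z_s, T_e = T_e,
                 eta = eta),
            class = "interface_stack")
}

#' @export
print.interface_stack <- function(x, ...) {
  cat("interface_stack: G_C = ", x$G_C, " MW m^-2 K^-1, kappa_L = ",
      x$kappa_L, " W m^-1 K^-1, delta = ", x$delta, " nm, z_s = ", x$z_s,
      " nm, T_e = ", x$T_e, " K, eta = ", x$eta, "\n", sep = "")
  invisible(x)
}

#' Steady-state temperature profile of the serial-resistor model
#'
#' With through-interface flux \eqn{q = \eta p}, the steady solution of the
#' Fourier equations is: water plateau \eqn{T_W = T_e + q\delta/\kappa_L}
#' (the plateau is pinned to the lipid inner-surface temperature), sheet
#' temperature \eqn{T_G = T_W + q/G_C} across the interfacial resistance, a
#' linear gradient from \eqn{T_W} at `z_s` to \eqn{T_e} at `z_s + delta` in
#' the lipid, and \eqn{T_e} beyond. The profile shows the characteristic
#' abrupt drop at the sheet-water interface followed by a plateau in water
#' and a gradient in the lipid.
#'
#' @param stack An [interface_stack()].
#' @param p Heating power density, GW m^-2.
#' @param bin_width Profile bin width in nm (default 0.1).
#' @return A list with `profile` (a [temperature_profile()]; the bin left of
#'   z = 0 holds the sheet), `T_G`, `T_W`, `T_zs` (all K), and `q_W_m2`
#'   (through-interface flux, W m^-2).
#' @examples
#' st <- interface_stack(G_C = 12.60, kappa_L = 0.12, delta = 4)
#' steady_state_profile(st, p = 1)$T_G  # 412.70 K
#' @export
steady_state_profile <- function(stack, p, bin_width = 0.1) {
  stopifnot(inherits(stack, "interface_stack"), p >= 0, bin_width > 0)
  q <- stack$eta * p * 1e9                       # W m^-2
  T_W <- stack$T_e + q * (stack$delta * 1e-9) / stack$kappa_L
  T_G <- T_W + q / (stack$G_C * 1e6)
  zmax <- stack$z_s + stack$delta
  n_bins <- ceiling(zmax / bin_width - 1e-9) + 1L  # one sheet bin left of 0
  edges <- bin_width * (-1:(n_bins - 1))
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  temp <- ifelse(mid < 0, T_G,
          ifelse(mid < stack$z_s, T_W,
          ifelse(mid <= zmax,
                 T_W + (stack$T_e - T_W) * (mid - stack$z_s) / stack$delta,
                 stack$T_e)))
  list(profile = temperature_profile(edges, temp),
       T_G = T_G, T_W = T_W, T_zs = T_W, q_W_m2 = q)
}

#' Transient sheet temperature by the lumped-parameter method
#'
#' Treats the sheet as a single heat-capacity node exchanging heat with the
#' (constant-temperature) water layer through the interfacial conductance:
#' \deqn{\rho_g c_g d \, dT/dt = \eta p - G_C (T - T_W), \quad T(0) = T_W,}
#' whose solution is
#' \deqn{T_g(t) = T_W + \frac{\eta p}{G_C}\left(1 -
#'   e^{-G_C t/(\rho_g c_g d)}\right),}
#' an exponential approach to the plateau \eqn{T_W + \eta p / G_C} with time
#' constant \eqn{\tau = \rho_g c_g d / G_C}.
#'
#' @param sheet A [graphene_sheet()].
#' @param stack An [interface_stack()].
#' @param p Heating power density, GW m^-2.
#' @param times Evaluation times in ps.
#' @param T_w Constant water-layer temperature, K (default: the stack's sink
#'   temperature `T_e`).
#' @return A [temperature_series()] labelled `"sheet"`.
#' @export
transient_graphene_temperature <- function(sheet, stack, p, times,
                                           T_w = stack$T_e) {
  stopifnot(inherits(sheet, "graphene_sheet"),
            inherits(stack, "interface_stack"), p >= 0)
  ca <- areal_heat_capacity(sheet)               # J m^-2 K^-1
  g <- stack$G_C * 1e6                           # W m^-2 K^-1
  q <- stack$eta * p * 1e9                       # W m^-2
  t_s <- times * 1e-12
  temp <- T_w + (q / g) * (1 - exp(-g * t_s / ca))
  temperature_series(times, temp, label = "sheet")
}

#' Recover interface conductance and lipid conductivity from a steady profile
#'
#' Least-squares fit of the piecewise steady-state solution to a measured
#' temperature profile: the lipid conductivity from the regression slope in
#' the lipid region (\eqn{\kappa_L = -q / (dT/dz)}), and the interfacial
#' conductance from the sheet-minus-plateau drop
#' (\eqn{G_C = q / (T_G - T_W)}).
#'
#' @param profile A [temperature_profile()] covering the sheet bin (z < 0),
#'   the water plateau and the lipid gradient.
#' @param p Heating power density used, GW m^-2.
#' @param geometry List with `z_s`, `delta` (nm), `T_e` (K) and `eta`.
#' @return A list with `G_C` (MW m^-2 K^-1, `Inf` with a warning when the
#'   interface drop vanishes), `kappa_L` (W m^-1 K^-1), standard errors
#'   `G_C_se` / `kappa_L_se`, and the component estimates `T_G`, `T_W`.
#' @export
fit_steady_parameters <- function(profile, p, geometry) {
  stopifnot(inherits(profile, "temperature_profile"), p > 0)
  g <- geometry
  stopifnot(!is.null(g$z_s), !is.null(g$delta))
  if (is.null(g$T_e)) g$T_e <- 300
  if (is.null(g$eta)) g$eta <- 1
  q <- g$eta * p * 1e9
  mid <- bin_centers(profile)
  temp <- profile$temperature
  sheet <- !is.na(temp) & mid < 0
  water <- !is.na(temp) & mid >= 0 & mid < g$z_s
  lipid <- !is.na(temp) & mid >= g$z_s & mid <= g$z_s + g$delta
  if (!any(sheet)) stop("profile has no sheet bin (z < 0)")
  if (!any(water)) stop("profile has no water bins (0 <= z < z_s)")
  if (sum(lipid) < 3) stop("profile has fewer than 3 lipid bins")

  T_G <- mean(temp[sheet])
  T_W <- mean(temp[water])
  fit <- stats::lm(temp[lipid] ~ mid[lipid])
  slope_nm <- stats::coef(fit)[[2]]              # K nm^-1
  slope_se <- suppressWarnings(summary(fit))$coefficients[2, "Std. Error"]
  if (abs(slope_nm) < 1e-12)
    stop("degenerate profile: no temperature gradient in the lipid region")
  slope_si <- slope_nm / 1e-9                    # K m^-1
  kappa_L <- -q / slope_si
  kappa_L_se <- abs(q / slope_si^2) * slope_se / 1e-9

  drop <- T_G - T_W
  if (drop <= .Machine$double.eps^0.5 * max(1, T_G)) {
    warning("zero interface drop: G_C is unidentifiable (returned Inf)")
    G_C <- Inf
    G_C_se <- NA_real_
  } else {
    G_C <- q / drop / 1e6
    sd_w <- if (sum(water) > 1) stats::sd(temp[water]) / sqrt(sum(water)) else 0
    G_C_se <- (q / drop^2) * sd_w / 1e6
  }
  list(G_C = G_C, kappa_L = kappa_L, G_C_se = G_C_se,
       kappa_L_se = kappa_L_se, T_G = T_G, T_W = T_W)
}

#' Recover the interface conductance from a transient heating curve
#'
#' Nonlinear least-squares fit of the lumped-parameter heating solution
#' (see [transient_graphene_temperature()]) for the interfacial conductance
#' `G_C`, with the sheet constants and power known. The initial value is
#' taken from the apparent plateau. Series that have not begun to saturate
#' (duration short against the fitted time constant, or a weakly determined
#' estimate) are flagged with a warning: the early linear regime carries no
#' conductance information.
#'
#' @param series A [temperature_series()] from a constant-power heating run.
#' @param sheet A [graphene_sheet()].
#' @param p Heating power density, GW m^-2.
#' @param eta Flux-partition factor (fixed; default 1).
#' @param T_w Water-layer baseline temperature, K (default: first point).
#' @return A list with `G_C` (MW m^-2 K^-1), `G_C_se`, `tau` (ps),
#'   `identifiable` (logical) and `fit`.
#' @export
fit_transient <- function(series, sheet, p, eta = 1, T_w = NULL) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(sheet, "graphene_sheet"), p > 0)
  t_s <- (series$times - series$times[1]) * 1e-12
  temp <- series$temperature
  if (is.null(T_w)) T_w <- temp[1]
  ca <- areal_heat_capacity(sheet)
  q <- eta * p * 1e9
  plateau <- max(temp) - T_w
  g0 <- if (plateau > 0) q / plateau / 1e6 else 10   # MW m^-2 K^-1
  fit <- minpack.lm::nlsLM(
    temp ~ T_w + (q / (g6 * 1e6)) * (1 - exp(-(g6 * 1e6) * t_s / ca)),
    start = list(g6 = g0),
    data = list(temp = temp, t_s = t_s, T_w = T_w, q = q, ca = ca),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  g_hat <- stats::coef(fit)[["g6"]]
  g_se <- summary(fit)$coefficients["g6", "Std. Error"]
  tau_ps <- ca / (g_hat * 1e6) * 1e12
  identifiable <- TRUE
  if (max(series$times) - series$times[1] < 0.5 * tau_ps ||
      (is.finite(g_se) && g_se > 0.5 * abs(g_hat))) {
    identifiable <- FALSE
    warning("heating curve has not saturated: G_C is weakly identified ",
            "(duration ", signif(max(series$times) - series$times[1], 3),
            " ps vs time constant ", signif(tau_ps, 3), " ps)")
  }
  list(G_C = g_hat, G_C_se = g_se, tau = tau_ps,
       identifiable = identifiable, fit = fit)
}

#' Critical power density predicted by the serial-resistor model
#'
#' Inverts the steady-state solution for the power density at which the
#' lipid temperature rise reaches the threshold \eqn{\Delta T_c}: at the
#' lipid surface the rise is \eqn{\eta p \delta / \kappa_L}, so
#' \eqn{p_c = \kappa_L \Delta T_c / (\eta \delta)}; the bilayer volume
#' average of the linear profile is half the surface rise, giving
#' \eqn{p_c = 2 \kappa_L \Delta T_c / (\eta \delta)}.
#'
#' @param stack An [interface_stack()].
#' @param delta_T_c Threshold temperature rise, K.
#' @param location `"lipid_surface"` or `"lipid_average"`: where the rise is
#'   evaluated.
#' @return p_c in GW m^-2.
#' @export
predict_critical_power <- function(stack, delta_T_c,
                                   location = c("lipid_surface",
                                                "lipid_average")) {
  stopifnot(inherits(stack, "interface_stack"), delta_T_c > 0)
  location <- match.arg(location)
  if (stack$eta <= 0) stop("eta must be positive to carry flux")
  p_surface <- stack$kappa_L * delta_T_c /
    (stack$eta * stack$delta * 1e-9) / 1e9
  if (location == "lipid_surface") p_surface else 2 * p_surface
}

#' Flux-partition factor implied by an observed critical power
#'
#' Solves the steady-state inversion of [predict_critical_power()] for
#' `eta`: the fraction of injected power crossing the serial path that makes
#' the model's critical power match an observed one. Reported as a fitted
#' partition, not a prediction.
#'
#' @param stack An [interface_stack()] (its `eta` is ignored).
#' @param p_c_obs Observed critical power density, GW m^-2.
#' @param delta_T_c Threshold temperature rise, K.
#' @param location As in [predict_critical_power()].
#' @return eta (dimensionless).
#' @export
fit_flux_partition <- function(stack, p_c_obs, delta_T_c,
                               location = c("lipid_surface",
                                            "lipid_average")) {
  stopifnot(p_c_obs > 0, delta_T_c > 0)
  location <- match.arg(location)
  fac <- if (location == "lipid_surface") 1 else 2
  fac * stack$kappa_L * delta_T_c / (stack$delta * 1e-9) / (p_c_obs * 1e9)
}
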