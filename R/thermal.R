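#' Slab kinetic-temperature profile
#'
#' Per-slab kinetic temperature \eqn{T = \sum m v^2 / (3 N k_B)} (three
#' translational degrees of freedom per particle), binned along z in slabs of
#' `bin_width` and time-averaged over the frames inside `window`. Slabs that
#' are never occupied are reported as `NA`, not zero.
#'
#' @param traj A [trajectory()] whose frames carry velocities.
#' @param selection Species labels or particle index (`NULL` = all).
#' @param bin_width Slab width in nm (default 0.1).
#' @param window `c(t0, t1)` in ps delimiting the averaging window
#'   (`NULL` = all frames).
#' @param origin z-position of the sheet plane in nm.
#' @return A [temperature_profile()].
#' @export
slab_temperature_profile <- function(traj, selection = NULL, bin_width = 0.1,
                                     window = NULL, origin = 0) {
  stopifnot(inherits(traj, "trajectory"), bin_width > 0)
  if (is.null(traj$frames[[1]]$velocities))
    stop("trajectory carries no velocities")
  idx <- resolve_selection(traj, selection)
  use <- if (is.null(window)) seq_along(traj$frames) else
    which(traj$times >= window[1] & traj$times <= window[2])
  if (length(use) == 0) stop("no frames inside the averaging window")
  m_kg <- traj$masses[idx] * 1e-3 / N_AVOGADRO

  zall <- axis_matrix(traj, 3, idx)[use, , drop = FALSE] - origin
  zr <- range(zall)
  n_bins <- max(1L, ceiling((zr[2] - zr[1]) / bin_width - 1e-9))
  edges <- zr[1] + bin_width * (0:n_bins)
  ke_acc <- numeric(n_bins)   # sum of m v^2 (J), over frames
  n_acc <- numeric(n_bins)    # particle-frame counts
  for (f in use) {
    fr <- traj$frames[[f]]
    v <- fr$velocities[idx, , drop = FALSE] * NMPS_TO_MS
    mv2 <- m_kg * rowSums(v^2)
    b <- findInterval(fr$positions[idx, 3] - origin, edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
    ke_acc <- ke_acc + bin_sums(mv2, b, n_bins)
    n_acc <- n_acc + tabulate(b, nbins = n_bins)
  }
  temp <- ifelse(n_acc > 0, ke_acc / (3 * n_acc * KB), NA_real_)
  temperature_profile(edges, temp,
                      averaging_window = diff(range(traj$times[use])))
}

#' Thermal relaxation time from an exponential decay
#'
#' Fits \eqn{T(t) = T_{env} + \Delta T_0 \exp(-t/\tau)} to a post-pulse
#' cooling series by nonlinear least squares, initialized from a log-linear
#' regression of \eqn{\log(T - T_{env})} on t. All points are weighted
#' equally.
#'
#' @param series A [temperature_series()] starting above `T_env`.
#' @param T_env Environment (sink) temperature in K.
#' @return A list with `tau` (ps), `delta_T0` (K), `fit` (the `nls` object)
#'   and `residual_sd` (K).
#' @export
relaxation_time <- function(series, T_env = 300) {
  stopifnot(inherits(series, "temperature_series"))
  t <- series$times - series$times[1]
  temp <- series$temperature
  if (temp[1] <= T_env)
    stop("series must start above the environment temperature")
  excess <- temp - T_env
  # decay sanity: late-time excess must be well below the initial excess
  late <- mean(utils::tail(excess, max(2L, length(excess) %/% 5)))
  if (late > 0.95 * excess[1])
    stop("series does not decay toward T_env; cannot fit a relaxation time")
  pos <- excess > 0
  if (sum(pos) < 3) stop("too few points above T_env for the fit")
  init <- stats::lm(log(excess[pos]) ~ t[pos])
  tau0 <- -1 / stats::coef(init)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
  a0 <- exp(stats::coef(init)[[1]])
  fit <- minpack.lm::nlsLM(temp ~ T_env + a * exp(-t / tau),
                           start = list(a = a0, tau = tau0),
                           data = list(temp = temp, t = t, T_env = T_env),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  list(tau = est[["tau"]], delta_T0 = est[["a"]], fit = fit,
       residual_sd = stats::sigma(fit))
}

#' Kapitza (interfacial thermal) conductance from a relaxation time
#'
#' \eqn{G_K = C / (\tau A) = \rho_g c_g d / \tau}: the sheet's areal heat
#' capacity over the relaxation time. The per-area formulation makes G_K
#' independent of the sheet area, as an intensive interfacial property must
#' be.
#'
#' @param sheet A [graphene_sheet()].
#' @param tau Relaxation time in ps.
#' @return G_K in MW m^-2 K^-1.
#' @export
kapitza_conductance <- function(sheet, tau) {
  stopifnot(tau > 0)
  areal_heat_capacity(sheet) / (tau * 1e-12) / 1e6
}

#' Critical heating power density from a temperature-rise curve
#'
#' Locates the first upward crossing of the threshold \eqn{\Delta T_c} on a
#' measured \eqn{\Delta T(p)} curve by piecewise-linear interpolation between
#' the measured power densities.
#'
#' @param curve A [delta_t_curve()].
#' @param delta_T_c Threshold temperature rise in K (20 K is the conventional
#'   cell-viability threshold).
#' @return p_c in GW m^-2.
#' @export
critical_power <- function(curve, delta_T_c) {
  stopifnot(inherits(curve, "delta_t_curve"), delta_T_c > 0)
  p <- curve$power
  dT <- curve$delta_T
  if (max(dT) < delta_T_c)
    stop("threshold never crossed: max temperature rise is ",
         signif(max(dT), 4), " K < ", delta_T_c, " K")
  if (dT[1] >= delta_T_c) return(p[1])
  i <- which(dT[-1] >= delta_T_c & dT[-length(dT)] < delta_T_c)[1]
  frac <- (delta_T_c - dT[i]) / (dT[i + 1] - dT[i])
  p[i] + frac * (p[i + 1] - p[i])
}
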