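#' Mean-square displacement with multiple time origins
#'
#' Ensemble- and time-origin-averaged squared displacement
#' \eqn{\langle |r(t_0 + \tau) - r(t_0)|^2 \rangle} restricted to the first
#' `d_i` coordinate axes, for every lag up to `max_lag_fraction` of the
#' trajectory length (origin stride 1 frame). Computed per particle with the
#' standard FFT decomposition of the time-origin sum, so long trajectories
#' stay tractable.
#'
#' Coordinates must be unwrapped: a single-step displacement larger than half
#' the box on a periodic axis is taken as a wrap artefact and rejected.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param selection Species labels or particle index (`NULL` = all).
#' @param d_i Spatial dimensionality of the analysis: axes `1:d_i` enter the
#'   displacement (3 = full 3-D, 2 = in-plane, 1 = along x).
#' @param max_lag_fraction Largest lag as a fraction of the trajectory span.
#' @return An object of class `msd_curve` with fields `lag_times` (ps),
#'   `msd` (nm^2, `msd[1] = 0` at lag 0), `dims`, `n_origins`.
#' @export
msd <- function(traj, selection = NULL, d_i = 3, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory"), d_i %in% 1:3,
            max_lag_fraction > 0, max_lag_fraction <= 1)
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  idx <- resolve_selection(traj, selection)
  nf <- n_frames(traj)
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("msd requires uniformly spaced frames")
  max_lag <- max(1L, floor((nf - 1) * max_lag_fraction))

  total <- numeric(max_lag + 1)
  for (ax in seq_len(d_i)) {
    x <- axis_matrix(traj, ax, idx)  # frames x particles
    step <- abs(diff(x))
    if (traj$periodic[ax] && any(step > traj$box[ax] / 2))
      stop("single-step displacement exceeds half the box on axis ", ax,
           ": coordinates appear wrapped; unwrap periodic images first")
    for (p in seq_along(idx))
      total <- total + msd_1d_fft(x[, p], max_lag)
  }
  msd_vals <- total / length(idx)
  structure(list(lag_times = (0:max_lag) * dts[1], msd = msd_vals,
                 dims = as.integer(d_i), n_origins = nf - (0:max_lag)),
            class = "msd_curve")
}

# Time-origin-averaged squared displacement of one scalar coordinate series,
# for lags 0..max_lag: MSD(m) = S1(m) - 2*S2(m), with S2 the autocorrelation
# evaluated by zero-padded FFT and S1 by the telescoping recursion.
msd_1d_fft <- function(x, max_lag) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1)] / nfft
  d <- x^2
  q <- 2 * sum(d)
  s1 <- numeric(max_lag + 1)
  for (m in 0:max_lag) {
    if (m > 0) q <- q - d[m] - d[n - m + 1]
    s1[m + 1] <- q / (n - m)
  }
  s1 - 2 * ac / (n - 0:max_lag)
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("msd_curve: ", length(x$lag_times), " lags to ",
      signif(max(x$lag_times), 4), " ps (d_i = ", x$dims, "), msd max = ",
      signif(max(x$msd), 4), " nm^2\n", sep = "")
  invisible(x)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Least-squares slope of the MSD over a lag window, divided by
#' \eqn{2 d_i}: \eqn{D = \lim_{t\to\infty} \langle|r(t)-r(0)|^2\rangle /
#' (2 d_i t)}. The default window, 10-50% of the maximum lag, skips the
#' short-time ballistic/caging regime and the poorly averaged tail. A list of
#' curves from independent runs is averaged: D is the mean of per-run
#' estimates and the standard error is over runs.
#'
#' @param curve An `msd_curve`, or a list of them from independent runs.
#' @param fit_window `c(f0, f1)` fractions of the maximum lag to fit over.
#' @return A list with `D` (nm^2 ps^-1), `D_m2_per_s`, `stderr`, and
#'   `n_runs`. A negative fitted slope yields `D = 0` with a warning.
#' @export
diffusion_coefficient <- function(curve, fit_window = c(0.1, 0.5)) {
  if (inherits(curve, "msd_curve")) curve <- list(curve)
  stopifnot(length(curve) >= 1,
            all(vapply(curve, inherits, logical(1), "msd_curve")))
  fits <- lapply(curve, function(cv) {
    tmax <- max(cv$lag_times)
    lo <- fit_window[1] * tmax
    hi <- fit_window[2] * tmax
    sel <- cv$lag_times >= lo & cv$lag_times <= hi & cv$lag_times > 0
    if (sum(sel) < 2) stop("fit window contains fewer than 2 lags")
    fit <- stats::lm(msd ~ lag_times, data = list(msd = cv$msd[sel],
                                                  lag_times = cv$lag_times[sel]))
    slope <- stats::coef(fit)[["lag_times"]]
    se <- suppressWarnings(summary(fit))$coefficients["lag_times",
                                                      "Std. Error"]
    c(D = slope / (2 * cv$dims), se = se / (2 * cv$dims))
  })
  d_vals <- vapply(fits, `[[`, numeric(1), "D")
  d_hat <- mean(d_vals)
  se <- if (length(d_vals) > 1) {
    stats::sd(d_vals) / sqrt(length(d_vals))
  } else {
    fits[[1]][["se"]]
  }
  if (d_hat < 0) {
    warning("negative fitted MSD slope; returning D = 0")
    d_hat <- 0
  }
  list(D = d_hat, D_m2_per_s = d_hat * 1e-6, stderr = se,
       n_runs = length(d_vals))
}
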