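#' Binned mass-density profile
#'
#' Mass density versus distance z from the sheet plane (z increasing toward
#' the membrane), on contiguous bins.
#'
#' @param bin_edges Numeric vector of bin edges in nm (length n_bins + 1).
#' @param density Numeric vector of densities per bin, g cm^-3.
#' @param area Interface area A in nm^2.
#' @param bulk_density Reference bulk density in g cm^-3 (may be `NA` and set
#'   later via [estimate_bulk_density()] or directly).
#' @return An object of class `density_profile`.
#' @export
density_profile_obj <- function(bin_edges, density, area,
                                bulk_density = NA_real_) {
  stopifnot(length(bin_edges) == length(density) + 1,
            all(diff(bin_edges) > 0), all(density >= 0), area > 0)
  structure(list(bin_edges = as.numeric(bin_edges),
                 density = as.numeric(density), area = area,
                 bulk_density = bulk_density),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile: ", length(x$density), " bins over z = [",
      signif(min(x$bin_edges), 4), ", ", signif(max(x$bin_edges), 4),
      "] nm\n", sep = "")
  cat("  max density ", signif(max(x$density), 4), " g cm^-3; bulk ref ",
      signif(x$bulk_density, 4), " g cm^-3; A = ", signif(x$area, 4),
      " nm^2\n", sep = "")
  invisible(x)
}

#' Bin centers of a density or temperature profile
#' @param x A `density_profile` or `temperature_profile`.
#' @return Numeric vector of bin midpoints in nm.
#' @export
bin_centers <- function(x) {
  e <- if (!is.null(x$bin_edges)) x$bin_edges else x$z_bins
  (e[-1] + e[-length(e)]) / 2
}

#' Temperature time series of a named layer
#'
#' @param times Times in ps, increasing.
#' @param temperature Temperatures in K.
#' @param label Layer name (e.g. `"sheet"`).
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(times, temperature, label = "layer") {
  stopifnot(length(times) == length(temperature))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(temperature <= 0, na.rm = TRUE))
    stop("temperatures must be positive")
  structure(list(times = as.numeric(times),
                 temperature = as.numeric(temperature),
                 label = label),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat("temperature_series [", x$label, "]: ", length(x$times),
      " points, t = ", signif(x$times[1], 4), " .. ",
      signif(x$times[length(x$times)], 4), " ps, T = ",
      signif(min(x$temperature), 5), " .. ", signif(max(x$temperature), 5),
      " K\n", sep = "")
  invisible(x)
}

#' Temperature-versus-position profile
#'
#' @param z_bins Bin edges in nm (length n_bins + 1).
#' @param temperature Per-bin temperatures in K (`NA` marks empty bins).
#' @param averaging_window Time window the profile was averaged over, ps.
#' @return An object of class `temperature_profile`.
#' @export
temperature_profile <- function(z_bins, temperature, averaging_window = NA) {
  stopifnot(length(z_bins) == length(temperature) + 1,
            all(diff(z_bins) > 0))
  if (any(temperature <= 0, na.rm = TRUE))
    stop("temperatures in occupied bins must be positive")
  structure(list(z_bins = as.numeric(z_bins),
                 temperature = as.numeric(temperature),
                 averaging_window = averaging_window),
            class = "temperature_profile")
}

#' @export
print.temperature_profile <- function(x, ...) {
  occ <- sum(!is.na(x$temperature))
  cat("temperature_profile: ", length(x$temperature), " bins (", occ,
      " occupied) over z = [", signif(min(x$z_bins), 4), ", ",
      signif(max(x$z_bins), 4), "] nm\n", sep = "")
  invisible(x)
}

#' Graphene/GO sheet constants
#'
#' Holds the sheet mass density, specific heat, nominal thickness and area,
#' from which the lumped heat capacity \eqn{C = \rho_g c_g d A} derives.
#' Defaults are the standard graphene values: density 2.265 g cm^-3,
#' Dulong-Petit specific heat 3 N_A k_B = 2.1 J g^-1 K^-1, van der Waals
#' thickness 0.34 nm.
#'
#' @param rho_g Mass density, g cm^-3.
#' @param c_g Specific heat, J g^-1 K^-1.
#' @param d Nominal sheet thickness, nm.
#' @param A Sheet area, nm^2.
#' @return An object of class `graphene_sheet`.
#' @export
graphene_sheet <- function(rho_g = 2.265, c_g = 2.1, d = 0.34, A = 27.55) {
  stopifnot(rho_g > 0, c_g > 0, d > 0, A > 0)
  structure(list(rho_g = rho_g, c_g = c_g, d = d, A = A),
            class = "graphene_sheet")
}

#' @export
print.graphene_sheet <- function(x, ...) {
  cat("graphene_sheet: rho_g = ", x$rho_g, " g cm^-3, c_g = ", x$c_g,
      " J g^-1 K^-1, d = ", x$d, " nm, A = ", x$A, " nm^2 (C/A = ",
      signif(areal_heat_capacity(x), 4), " J m^-2 K^-1)\n", sep = "")
  invisible(x)
}

#' Areal heat capacity of a sheet
#'
#' \eqn{C/A = \rho_g c_g d} in J m^-2 K^-1 (the per-area form of the lumped
#' heat capacity).
#'
#' @param sheet A [graphene_sheet()].
#' @return Areal heat capacity in J m^-2 K^-1.
#' @export
areal_heat_capacity <- function(sheet) {
  stopifnot(inherits(sheet, "graphene_sheet"))
  # g cm^-3 -> kg m^-3 (*1e3); J g^-1 K^-1 -> J kg^-1 K^-1 (*1e3); nm -> m
  (sheet$rho_g * 1e3) * (sheet$c_g * 1e3) * (sheet$d * 1e-9)
}

#' Temperature-rise-versus-power curve
#'
#' Membrane temperature rise \eqn{\Delta T} as a function of the heating
#' power density p injected into the sheet.
#'
#' @param power Power densities in GW m^-2, non-negative.
#' @param delta_T Temperature rises in K.
#' @param stderr Optional per-point standard errors (K) from replicate runs.
#' @return An object of class `delta_t_curve`.
#' @export
delta_t_curve <- function(power, delta_T, stderr = NULL) {
  stopifnot(length(power) == length(delta_T), all(power >= 0),
            all(is.finite(delta_T)))
  if (!is.null(stderr)) stopifnot(length(stderr) == length(delta_T))
  o <- order(power)
  structure(list(power = as.numeric(power)[o],
                 delta_T = as.numeric(delta_T)[o],
                 stderr = if (is.null(stderr)) NULL else
                   as.numeric(stderr)[o]),
            class = "delta_t_curve")
}
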