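#' Slab mass-density profile along the interface normal
#'
#' Bins the selected particles into slabs of width `bin_width` along z
#' (measured from the sheet plane at `origin`, increasing toward the
#' membrane), converting the per-bin mass to g cm^-3 through the interface
#' area, and averages over frames. Total binned mass is conserved exactly.
#'
#' @param traj A [trajectory()].
#' @param species_filter Species labels to include (`NULL` = all particles),
#'   or a logical/integer particle index.
#' @param bin_width Slab width in nm (default 0.1, the profiling convention
#'   shared with temperature slabs).
#' @param origin z-position of the sheet plane in nm; densities are reported
#'   against z - origin.
#' @param range Optional `c(zmin, zmax)` (after origin shift) for the binned
#'   window; default spans the selected coordinates.
#' @return A [density_profile_obj()] with `bulk_density = NA` (set it with
#'   [estimate_bulk_density()] or assign a reference value).
#' @export
density_profile <- function(traj, species_filter = NULL, bin_width = 0.1,
                            origin = 0, range = NULL) {
  stopifnot(inherits(traj, "trajectory"), bin_width > 0)
  idx <- resolve_selection(traj, species_filter)
  area <- traj$box[1] * traj$box[2]
  z <- axis_matrix(traj, 3, idx) - origin  # frames x particles
  if (is.null(range)) range <- base::range(z)
  n_bins <- max(1L, ceiling((range[2] - range[1]) / bin_width - 1e-9))
  edges <- range[1] + bin_width * (0:n_bins)
  mass_g <- traj$masses[idx] / N_AVOGADRO
  acc <- numeric(n_bins)
  nf <- nrow(z)
  for (f in seq_len(nf)) {
    b <- findInterval(z[f, ], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    acc <- acc + bin_sums(mass_g, b, n_bins)
  }
  dens <- (acc / nf) / (area * bin_width * NM3_TO_CM3)
  density_profile_obj(edges, dens, area)
}

#' Estimate the bulk reference density from a far-field window
#'
#' The mean density over a user-designated window taken to represent
#' unstructured bulk water; stored in the profile's `bulk_density` field.
#'
#' @param profile A `density_profile`.
#' @param window `c(z0, z1)` in nm delimiting the far-field region.
#' @return The profile with `bulk_density` set.
#' @export
estimate_bulk_density <- function(profile, window) {
  stopifnot(inherits(profile, "density_profile"), length(window) == 2)
  mid <- bin_centers(profile)
  sel <- mid >= window[1] & mid <= window[2]
  if (!any(sel)) stop("no bins inside the bulk window")
  profile$bulk_density <- mean(profile$density[sel])
  profile
}

#' Locate density peaks above the bulk reference
#'
#' Finds local maxima of the profile with amplitude at least the bulk
#' density, on a lightly smoothed copy (running mean over `smooth` bins) so
#' that single-bin sampling jitter does not spawn spurious peaks. A maximum
#' must additionally rise above its flanking minima by at least
#' `min_prominence` of the profile's super-bulk excursion. Each peak's
#' boundaries `[z0, z1]` are set at the flanking local minima, clipped to
#' where the density crosses back below bulk (or the profile limits);
#' boundary ties break toward the wall. Peaks are returned ordered by
#' distance from the wall (z = 0).
#'
#' @param profile A `density_profile` with `bulk_density` set.
#' @param smooth Odd running-mean window (bins) used for extremum detection
#'   (1 disables smoothing). Amplitudes are reported from the raw profile.
#' @param min_prominence Minimum peak prominence as a fraction of
#'   `max(density) - bulk_density`.
#' @return A list of `peak_region` objects, each with fields `z0`, `z1`
#'   (nm boundaries), `z_max` (nm position of the maximum) and `amplitude`
#'   (g cm^-3).
#' @export
detect_peaks <- function(profile, smooth = 3L, min_prominence = 0.1) {
  stopifnot(inherits(profile, "density_profile"))
  if (is.na(profile$bulk_density))
    stop("bulk_density must be set (see estimate_bulk_density)")
  d <- profile$density
  n <- length(d)
  if (n < 3) stop("need at least 3 bins to detect peaks")
  mid <- bin_centers(profile)
  bulk <- profile$bulk_density
  s <- d
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(d, k, sides = 2)
    s[!is.na(sm)] <- sm[!is.na(sm)]
  }
  # strict rise from the left, non-strict fall to the right: plateau maxima
  # resolve to their wall-side bin
  is_max <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] &
                s[2:(n - 1)] >= s[3:n], FALSE)
  is_max[1] <- s[1] > s[2]
  is_max[n] <- s[n] > s[n - 1]
  prom_ref <- max(max(d) - bulk, .Machine$double.eps)
  peaks <- list()
  seen <- integer(0)
  for (i in which(is_max & s >= bulk)) {
    j0 <- i
    while (j0 > 1 && s[j0 - 1] <= s[j0] && s[j0 - 1] >= bulk) j0 <- j0 - 1
    j1 <- i
    while (j1 < n && s[j1 + 1] <= s[j1] && s[j1 + 1] >= bulk) j1 <- j1 + 1
    # refine on the raw profile: the smoothed curve locates the region, the
    # raw bins carry the amplitude and prominence
    i_raw <- j0 - 1L + which.max(d[j0:j1])
    if (i_raw %in% seen || d[i_raw] < bulk) next
    prom <- d[i_raw] - max(d[j0], d[j1])
    if (s[j0] >= bulk && s[j1] >= bulk && prom < min_prominence * prom_ref)
      next  # interior ripple, not a layering peak
    seen <- c(seen, i_raw)
    peaks[[length(peaks) + 1]] <-
      structure(list(z0 = profile$bin_edges[j0], z1 = profile$bin_edges[j1 + 1],
                     z_max = mid[i_raw], amplitude = d[i_raw]),
                class = "peak_region")
  }
  peaks[order(vapply(peaks, function(p) p$z_max, numeric(1)))]
}

#' @export
print.peak_region <- function(x, ...) {
  cat("peak_region: z_max = ", signif(x$z_max, 4), " nm, amplitude = ",
      signif(x$amplitude, 4), " g cm^-3, bounds [", signif(x$z0, 4), ", ",
      signif(x$z1, 4), "] nm\n", sep = "")
  invisible(x)
}

#' Thickness of the intercalated water layer
#'
#' The layer thickness t_W is the span of the region where the water mass
#' density is equal to or higher than the bulk value. Implemented as the
#' maximal contiguous run of super-bulk bins containing the first density
#' peak, with isolated sub-bulk bins (sampling dips of one bin) bridged.
#' When the profile never reaches bulk density the thickness is 0 and a
#' warning is raised.
#'
#' @param profile A `density_profile` with `bulk_density` set.
#' @param bridge Number of consecutive sub-bulk bins tolerated inside the
#'   layer (default 1).
#' @return t_W in nm; attribute `below_bulk` is `TRUE` when the profile is
#'   everywhere below bulk.
#' @export
water_layer_thickness <- function(profile, bridge = 1L) {
  stopifnot(inherits(profile, "density_profile"))
  if (is.na(profile$bulk_density))
    stop("bulk_density must be set (see estimate_bulk_density)")
  ok <- profile$density >= profile$bulk_density
  if (!any(ok)) {
    warning("density is everywhere below the bulk reference; t_W = 0")
    return(structure(0, below_bulk = TRUE))
  }
  # bridge short sub-bulk gaps between super-bulk runs
  r <- rle(ok)
  gaps <- which(!r$values & r$lengths <= bridge)
  interior <- gaps[gaps > 1 & gaps < length(r$values)]
  if (length(interior)) {
    r$values[interior] <- TRUE
    ok <- inverse.rle(r)
    r <- rle(ok)
  }
  # the run containing the first peak = first super-bulk run from the wall
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  first_run <- which(r$values)[1]
  i0 <- starts[first_run]
  i1 <- ends[first_run]
  structure(profile$bin_edges[i1 + 1] - profile$bin_edges[i0],
            below_bulk = FALSE)
}

#' Mass of water under the first density peak
#'
#' Integrates \eqn{A \rho(z)} by the trapezoidal rule over the boundaries
#' `[z0, z1]` of the first peak (the qualifying peak nearest the wall, with
#' amplitude at least the bulk density).
#'
#' @param profile A `density_profile` with `bulk_density` set.
#' @param peak Optionally a `peak_region` to integrate over; by default the
#'   first peak from [detect_peaks()].
#' @return M_1 in g, with attribute `per_nm2` (g nm^-2, M_1 / A).
#' @export
first_peak_mass <- function(profile, peak = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  if (is.null(peak)) {
    peaks <- detect_peaks(profile)
    peaks <- Filter(function(p) p$amplitude >= profile$bulk_density, peaks)
    if (length(peaks) == 0)
      stop("no qualifying peak: no local maximum reaches the bulk density")
    peak <- peaks[[1]]
  }
  mid <- bin_centers(profile)
  sel <- mid >= peak$z0 & mid <= peak$z1
  if (sum(sel) < 2) stop("first peak spans fewer than 2 bins")
  # trapezoid over the bin centers, extended to the exact boundaries by
  # linear interpolation so the edge half-bins are not dropped
  z <- mid[sel]
  rho <- profile$density[sel]
  interp <- stats::approx(mid, profile$density, xout = c(peak$z0, peak$z1),
                          rule = 2)$y
  z <- c(peak$z0, z, peak$z1)
  rho <- c(interp[1], rho, interp[2])
  integral <- sum(diff(z) * (rho[-1] + rho[-length(rho)]) / 2)  # g cm^-3 nm
  m1 <- profile$area * integral * NM3_TO_CM3                    # g
  structure(m1, per_nm2 = m1 / profile$area)
}
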