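#' Particle trajectory container
#'
#' A `trajectory` holds frames of particle positions (and optionally
#' velocities) together with per-particle masses and species labels, the
#' simulation box and frame timestamps. Units: positions nm, velocities
#' nm ps^-1, masses g mol^-1, box lengths nm, times ps.
#'
#' @param frames List of frames. Each frame is a list with `positions`
#'   (numeric n x 3 matrix, nm) and optionally `velocities` (n x 3, nm ps^-1).
#' @param masses Numeric vector of per-particle masses (g mol^-1).
#' @param species Character vector of per-particle species labels.
#' @param box Numeric length-3 vector `(Lx, Ly, Lz)` in nm.
#' @param times Numeric vector of frame times in ps, strictly increasing.
#' @param periodic Logical length-3 vector of periodicity flags per axis.
#' @return An object of class `trajectory`.
#' @examples
#' pos <- matrix(rnorm(30), ncol = 3)
#' trj <- trajectory(list(list(positions = pos)), masses = rep(18.015, 10),
#'                   species = rep("W", 10), box = c(5, 5, 5), times = 0)
#' trj
#' @export
trajectory <- function(frames, masses, species, box, times,
                       periodic = c(TRUE, TRUE, FALSE)) {
  stopifnot(is.list(frames), length(frames) >= 1)
  n <- nrow(frames[[1]]$positions)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f$positions) || ncol(f$positions) != 3)
      stop("frame ", i, ": positions must be an n x 3 matrix")
    if (nrow(f$positions) != n)
      stop("frame ", i, ": particle count ", nrow(f$positions),
           " differs from frame 1 (", n, ")")
    if (!is.null(f$velocities) &&
        (!is.matrix(f$velocities) || !all(dim(f$velocities) == c(n, 3))))
      stop("frame ", i, ": velocities must match positions dimensions")
  }
  if (length(masses) != n) stop("masses must have one entry per particle")
  if (any(!is.finite(masses)) || any(masses <= 0)) stop("masses must be > 0")
  if (length(species) != n) stop("species must have one entry per particle")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (length(times) != length(frames))
    stop("times must have one entry per frame")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(frames = frames, masses = as.numeric(masses),
                 species = as.character(species), box = as.numeric(box),
                 periodic = as.logical(periodic), times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$frames[[1]]$positions)
  has_v <- !is.null(x$frames[[1]]$velocities)
  cat("trajectory: ", length(x$frames), " frame(s), ", n, " particles",
      if (has_v) " (+velocities)", "\n", sep = "")
  cat("  box [nm]: ", paste(signif(x$box, 4), collapse = " x "),
      "  t [ps]: ", signif(x$times[1], 4), " .. ",
      signif(x$times[length(x$times)], 4), "\n", sep = "")
  cat("  species: ", paste(utils::head(unique(x$species), 5), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames / particles in a trajectory
#' @param traj A [trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' @rdname n_frames
#' @export
n_particles <- function(traj) nrow(traj$frames[[1]]$positions)

#' Subset a trajectory by particle
#'
#' @param traj A [trajectory()].
#' @param which Logical or integer index over particles.
#' @return A [trajectory()] restricted to the selected particles.
#' @export
select_particles <- function(traj, which) {
  idx <- if (is.logical(which)) base::which(which) else as.integer(which)
  if (length(idx) == 0) stop("empty particle selection")
  frames <- lapply(traj$frames, function(f) {
    out <- list(positions = f$positions[idx, , drop = FALSE])
    if (!is.null(f$velocities))
      out$velocities <- f$velocities[idx, , drop = FALSE]
    out
  })
  trajectory(frames, traj$masses[idx], traj$species[idx], traj$box,
             traj$times, traj$periodic)
}

# Resolve a species filter (NULL = all, character = label match,
# logical/integer = index) into an integer particle index.
resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(n_particles(traj)))
  if (is.character(selection)) {
    idx <- which(traj$species %in% selection)
    if (length(idx) == 0)
      stop("no particles match species filter: ",
           paste(selection, collapse = ", "))
    return(idx)
  }
  idx <- if (is.logical(selection)) which(selection) else as.integer(selection)
  if (length(idx) == 0) stop("empty particle selection")
  idx
}

# Sum of per-particle weights by bin index, keeping empty bins (rowsum drops
# them).
bin_sums <- function(w, bin, n_bins) {
  out <- numeric(n_bins)
  s <- rowsum(w, bin)
  out[as.integer(rownames(s))] <- s
  out
}

# Stack one coordinate axis across frames into a frames x particles matrix.
axis_matrix <- function(traj, axis = 3, idx = NULL, what = "positions") {
  if (is.null(idx)) idx <- seq_len(n_particles(traj))
  do.call(rbind, lapply(traj$frames, function(f) f[[what]][idx, axis]))
}
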