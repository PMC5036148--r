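#' Write a trajectory as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying
#' `Lattice="..." Properties=... Time=...`, then one line per particle with
#' species, position (nm), velocity (nm ps^-1, when present) and mass
#' (g mol^-1). Numbers are written with enough digits for a lossless
#' round trip through [read_trajectory()].
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_particles(traj)
  has_v <- !is.null(traj$frames[[1]]$velocities)
  props <- if (has_v) "species:S:1:pos:R:3:vel:R:3:mass:R:1" else
    "species:S:1:pos:R:3:mass:R:1"
  lat <- sprintf("%.10g 0 0 0 %.10g 0 0 0 %.10g",
                 traj$box[1], traj$box[2], traj$box[3])
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    writeLines(as.character(n), con)
    writeLines(sprintf('Lattice="%s" Properties=%s Time=%.10g', lat, props,
                       traj$times[f]), con)
    cols <- cbind(fr$positions, if (has_v) fr$velocities, traj$masses)
    num <- apply(cols, 1, function(r) paste(sprintf("%.10g", r),
                                            collapse = " "))
    writeLines(paste(traj$species, num), con)
  }
  invisible(path)
}

#' Read a trajectory from extended-XYZ or LAMMPS-dump text
#'
#' Extended XYZ is read as written by [write_trajectory()] (coordinates nm,
#' velocities nm ps^-1, masses g mol^-1). LAMMPS dump files (`ITEM:` dialect)
#' are read with columns among `id type element x y z xs ys zs vx vy vz
#' mass`; scaled coordinates (`xs ys zs`) are unscaled against the box
#' bounds, lengths are converted from `length_unit` to nm and times from the
#' `TIMESTEP` item through `timestep` (ps per dump step). Malformed headers
#' and inconsistent atom counts raise line-numbered errors.
#'
#' @param path Input file path.
#' @param dialect `"extended_xyz"` or `"lammps_dump"`.
#' @param length_unit Length unit of a LAMMPS dump: `"angstrom"` (default)
#'   or `"nm"`.
#' @param timestep ps per LAMMPS dump timestep unit (default 1e-3, i.e. fs).
#' @param masses Optional named vector mapping LAMMPS `type` (or `element`)
#'   to mass in g mol^-1 when the dump has no mass column; unmapped types
#'   default to the water molecule mass.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, dialect = c("extended_xyz", "lammps_dump"),
                            length_unit = c("angstrom", "nm"),
                            timestep = 1e-3, masses = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  switch(dialect,
         extended_xyz = read_extxyz(lines, path),
         lammps_dump = read_lammps_dump(lines, path,
                                        match.arg(length_unit),
                                        timestep, masses))
}

read_extxyz <- function(lines, path) {
  frames <- list()
  times <- numeric(0)
  box <- NULL
  species <- NULL
  mass <- NULL
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(path, ":", i, ": expected an atom count, got '", lines[i], "'")
    n <- as.integer(lines[i])
    frame_no <- frame_no + 1L
    if (i + 1 > length(lines))
      stop(path, ":", i + 1, ": missing comment line in frame ", frame_no)
    hdr <- lines[i + 1]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    if (length(lat) == 0)
      stop(path, ":", i + 1, ": frame ", frame_no, " has no Lattice field")
    lv <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
    this_box <- lv[c(1, 5, 9)]
    tm <- regmatches(hdr, regexpr("Time=[-0-9.eE+]+", hdr))
    t_f <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else frame_no - 1
    has_v <- grepl("vel:R:3", hdr)
    if (i + 1 + n > length(lines))
      stop(path, ":", length(lines), ": frame ", frame_no,
           " truncated: expected ", n, " atom lines")
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol_expect <- if (has_v) 8L else 5L
    bad <- which(lengths(toks) != ncol_expect)
    if (length(bad))
      stop(path, ":", i + 1 + bad[1], ": frame ", frame_no,
           " atom line has ", lengths(toks)[bad[1]], " fields, expected ",
           ncol_expect)
    sp <- vapply(toks, `[[`, character(1), 1)
    num <- matrix(as.numeric(unlist(lapply(toks, `[`, -1))),
                  nrow = n, byrow = TRUE)
    fr <- list(positions = num[, 1:3, drop = FALSE])
    if (has_v) fr$velocities <- num[, 4:6, drop = FALSE]
    m_f <- num[, ncol(num)]
    if (is.null(species)) {
      species <- sp; mass <- m_f; box <- this_box
    } else if (n != length(species)) {
      stop(path, ":", i, ": frame ", frame_no, " has ", n,
           " atoms, expected ", length(species))
    }
    frames[[frame_no]] <- fr
    times[frame_no] <- t_f
    i <- i + 2L + n
  }
  if (frame_no == 0L) stop(path, ": no frames found")
  trajectory(frames, mass, species, box, times)
}

read_lammps_dump <- function(lines, path, length_unit, timestep, masses) {
  to_nm <- if (length_unit == "angstrom") 0.1 else 1
  frames <- list()
  times <- numeric(0)
  species <- NULL
  mass <- NULL
  box <- NULL
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!grepl("^ITEM: TIMESTEP", lines[i]))
      stop(path, ":", i, ": expected 'ITEM: TIMESTEP'")
    step <- as.numeric(lines[i + 1])
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2]))
      stop(path, ":", i + 2, ": expected 'ITEM: NUMBER OF ATOMS'")
    n <- as.integer(lines[i + 3])
    if (!grepl("^ITEM: BOX BOUNDS", lines[i + 4]))
      stop(path, ":", i + 4, ": expected 'ITEM: BOX BOUNDS'")
    bounds <- t(vapply(lines[i + 5:7], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])[1:2], numeric(2)))
    atom_hdr <- lines[i + 8]
    if (!grepl("^ITEM: ATOMS", atom_hdr))
      stop(path, ":", i + 8, ": expected 'ITEM: ATOMS'")
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", atom_hdr), "\\s+")[[1]]
    if (i + 8 + n > length(lines))
      stop(path, ":", length(lines), ": frame ", frame_no + 1,
           " truncated: expected ", n, " atom lines")
    body <- lines[(i + 9):(i + 8 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(toks) != length(cols))
    if (length(bad))
      stop(path, ":", i + 8 + bad[1], ": atom line has ",
           lengths(toks)[bad[1]], " fields, expected ", length(cols))
    tab <- matrix(unlist(toks), nrow = n, byrow = TRUE)
    colnames(tab) <- cols
    getn <- function(nm) if (nm %in% cols) as.numeric(tab[, nm]) else NULL
    scaled <- all(c("xs", "ys", "zs") %in% cols)
    if (scaled) {
      pos <- cbind(bounds[1, 1] + getn("xs") * diff(bounds[1, ]),
                   bounds[2, 1] + getn("ys") * diff(bounds[2, ]),
                   bounds[3, 1] + getn("zs") * diff(bounds[3, ])) * to_nm
    } else if (all(c("x", "y", "z") %in% cols)) {
      pos <- cbind(getn("x"), getn("y"), getn("z")) * to_nm
    } else {
      stop(path, ":", i + 8, ": no coordinate columns (x y z or xs ys zs)")
    }
    if (!is.null(id <- getn("id"))) {
      o <- order(id)
      tab <- tab[o, , drop = FALSE]
      pos <- pos[o, , drop = FALSE]
    }
    fr <- list(positions = pos)
    if (all(c("vx", "vy", "vz") %in% cols)) {
      # dump velocity unit: length_unit per dump time unit -> nm ps^-1
      fr$velocities <- cbind(as.numeric(tab[, "vx"]),
                             as.numeric(tab[, "vy"]),
                             as.numeric(tab[, "vz"])) * to_nm / timestep
    }
    sp_f <- if ("element" %in% cols) tab[, "element"] else
      if ("type" %in% cols) tab[, "type"] else rep("X", n)
    m_f <- if ("mass" %in% cols) as.numeric(tab[, "mass"]) else {
      if (is.null(masses)) rep(M_WATER, n) else {
        mm <- masses[sp_f]
        ifelse(is.na(mm), M_WATER, mm)
      }
    }
    frame_no <- frame_no + 1L
    if (is.null(species)) {
      species <- sp_f; mass <- m_f
      box <- (bounds[, 2] - bounds[, 1]) * to_nm
    } else if (n != length(species)) {
      stop(path, ":", i + 3, ": frame ", frame_no, " has ", n,
           " atoms, expected ", length(species))
    }
    frames[[frame_no]] <- fr
    times[frame_no] <- step * timestep
    i <- i + 9L + n
  }
  if (frame_no == 0L) stop(path, ": no frames found")
  trajectory(frames, mass, species, box, times)
}

#' Write profile / series objects as CSV
#'
#' Two-column CSV with a header naming the quantity and unit:
#' `z_nm,density_g_cm3` for density profiles, `z_nm,temperature_K` for
#' temperature profiles, `time_ps,temperature_K` for series,
#' `lag_ps,msd_nm2` for MSD curves, `power_GW_m2,delta_T_K` for
#' temperature-rise curves.
#'
#' @param x A `density_profile`, `temperature_profile`,
#'   `temperature_series`, `msd_curve` or `delta_t_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(x, path) {
  df <- as_table(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_table <- function(x) {
  if (inherits(x, "density_profile"))
    return(data.frame(z_nm = bin_centers(x), density_g_cm3 = x$density))
  if (inherits(x, "temperature_profile"))
    return(data.frame(z_nm = bin_centers(x), temperature_K = x$temperature))
  if (inherits(x, "temperature_series"))
    return(data.frame(time_ps = x$times, temperature_K = x$temperature))
  if (inherits(x, "msd_curve"))
    return(data.frame(lag_ps = x$lag_times, msd_nm2 = x$msd))
  if (inherits(x, "delta_t_curve"))
    return(data.frame(power_GW_m2 = x$power, delta_T_K = x$delta_T))
  stop("unsupported object of class ", paste(class(x), collapse = "/"))
}

#' Read a temperature-rise curve or temperature series from CSV
#'
#' @param path CSV with columns `power_GW_m2,delta_T_K[,stderr_K]` (curve)
#'   or `time_ps,temperature_K` (series).
#' @return A [delta_t_curve()] or [temperature_series()], by the columns
#'   present.
#' @export
read_csv_table <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("power_GW_m2", "delta_T_K") %in% names(df)))
    return(delta_t_curve(df$power_GW_m2, df$delta_T_K,
                         stderr = df$stderr_K))
  if (all(c("time_ps", "temperature_K") %in% names(df)))
    return(temperature_series(df$time_ps, df$temperature_K))
  stop(path, ": unrecognized columns: ", paste(names(df), collapse = ", "))
}
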