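#' Read / write intensity tables
#'
#' CSV schema: temperature_K, replicate, species, intensity. Temperature
#' must be in kelvin; values below 200 are rejected as probable Celsius
#' to avoid silent unit bugs.
#'
#' @param path file path
#' @return an [intensity_table()]
#' @export
read_intensity_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(x$temperature_K < 200))
    stop("temperature_K below 200 K: temperatures must be in kelvin, ",
         "not degrees Celsius")
  intensity_table(x)
}

#' @rdname read_intensity_csv
#' @param table an [intensity_table()]
#' @export
write_intensity_csv <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read / write centre-of-mass trajectories
#'
#' Two-column CSV (time_ns, distance_nm); temperature and box edge are
#' carried in `#`-prefixed header comments.
#'
#' @param path file path
#' @return a [com_trajectory()]
#' @export
read_com_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key) {
    ln <- grep(paste0(key, "\\s*="), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(paste0(".*", key, "\\s*=\\s*"), "", ln[1]))
    else NULL
  }
  temperature <- grab("temperature_K")
  box_edge <- grab("box_edge_nm")
  if (is.null(temperature))
    stop("trajectory header must record temperature_K")
  x <- utils::read.csv(path, comment.char = "#")
  com_trajectory(times = x$time_ns, distances = x$distance_nm,
                 temperature = temperature, box_edge = box_edge)
}

#' @rdname read_com_csv
#' @param traj a [com_trajectory()]
#' @export
write_com_csv <- function(traj, path) {
  stopifnot(inherits(traj, "com_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K = %g", traj$temperature), con)
  if (!is.null(traj$box_edge))
    writeLines(sprintf("# box_edge_nm = %g", traj$box_edge), con)
  utils::write.csv(data.frame(time_ns = traj$times,
                              distance_nm = traj$distances),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read / write XYZ coordinate files
#'
#' Plain multi-frame XYZ: atom count line, comment line, then
#' `name x y z` rows (coordinates in nm here). The comment line written
#' by the package records the box edge as `box_edge_nm=<value>` and is
#' parsed back on read.
#'
#' @param path file path
#' @param box_edge optional box edge override, nm
#' @return a [coordinate_frame_set()]
#' @export
read_xyz <- function(path, box_edge = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1]
    if (is.null(box_edge) && grepl("box_edge_nm=", comment))
      box_edge <- as.numeric(sub(".*box_edge_nm=([0-9.eE+-]+).*", "\\1",
                                 comment))
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    coords <- apply(parts[, 2:4, drop = FALSE], 2, as.numeric)
    if (n == 1) coords <- matrix(coords, nrow = 1)
    colnames(coords) <- c("x", "y", "z")
    rownames(coords) <- parts[, 1]
    frames[[length(frames) + 1]] <- coordinate_frame(coords, box_edge)
    i <- i + 2 + n
  }
  coordinate_frame_set(frames, box_edge = box_edge)
}

#' @rdname read_xyz
#' @param frames a [coordinate_frame_set()]
#' @param names atom names recycled over rows
#' @export
write_xyz <- function(frames, path, names = "X") {
  stopifnot(inherits(frames, "coordinate_frame_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames$frames) {
    n <- nrow(fr$coords)
    writeLines(as.character(n), con)
    writeLines(if (!is.null(fr$box_edge))
      sprintf("box_edge_nm=%g", fr$box_edge) else "", con)
    nm <- rep_len(names, n)
    writeLines(sprintf("%s %.6f %.6f %.6f", nm, fr$coords[, 1],
                       fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' Fixed-width GROMACS GRO format, single frame; the cubic box edge is
#' taken from the first field of the final box line (orthorhombic boxes
#' only).
#'
#' @param path file path
#' @return a [coordinate_frame()]
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  atom_lines <- lines[3:(2 + n)]
  coords <- t(vapply(atom_lines, function(ln) {
    c(as.numeric(substr(ln, 21, 28)),
      as.numeric(substr(ln, 29, 36)),
      as.numeric(substr(ln, 37, 44)))
  }, numeric(3)))
  colnames(coords) <- c("x", "y", "z")
  rownames(coords) <- trimws(substr(atom_lines, 11, 15))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  coordinate_frame(coords, box_edge = box[1])
}

#' Read / write peak lists
#'
#' Two-column CSV: mz, intensity.
#'
#' @param path file path
#' @export
read_peak_csv <- function(path) {
  peak_list(utils::read.csv(path))
}

#' @rdname read_peak_csv
#' @param peaks a [peak_list()]
#' @export
write_peak_csv <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

#' Write a free-energy profile as CSV
#'
#' Columns: coordinate, free_energy_kJmol, variance, counts.
#'
#' @param fep a `free_energy_profile`
#' @param path file path
#' @export
write_fep_csv <- function(fep, path) {
  stopifnot(inherits(fep, "free_energy_profile"))
  utils::write.csv(data.frame(
    coordinate = fep$bin_center,
    free_energy_kJmol = fep$free_energy,
    variance = if (!is.null(fep$variance)) fep$variance else NA_real_,
    counts = fep$counts), path, row.names = FALSE)
  invisible(path)
}

#' Write a thermodynamics report row set as CSV
#'
#' One row per regime with breakpoint, dH, -TdS, dG and sds.
#'
#' @param fit a `two_regime_fit`
#' @param reference_temperature K
#' @param reaction label recorded in the file
#' @param path file path
#' @export
write_thermo_csv <- function(fit, path, reference_temperature = 293,
                             reaction = "dimerization") {
  stopifnot(inherits(fit, "two_regime_fit"))
  rows <- lapply(c(low = "low_regime", high = "high_regime"), function(rg) {
    tq <- thermo_from_fit(fit[[rg]], reference_temperature)
    data.frame(reaction = reaction,
               regime = sub("_regime", "", rg),
               breakpoint_K = fit$breakpoint,
               dH_kJmol = tq$dH, dH_sd = tq$dH_sd,
               mTdS_kJmol = tq$mTdS_at_ref, mTdS_sd = tq$mTdS_sd,
               dG_kJmol = tq$dG_at_ref, dG_sd = tq$dG_sd,
               T_ref_K = reference_temperature)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
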