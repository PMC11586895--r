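#' Coordinate frame
#'
#' A single frame of particle positions (nm) with an optional cubic
#' periodic box.
#'
#' @param coords numeric matrix, n x 3 (columns x, y, z), nm
#' @param box_edge cubic box edge, nm, or NULL for a non-periodic frame
#' @export
coordinate_frame <- function(coords, box_edge = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, is.numeric(coords))
  if (!is.null(box_edge)) stopifnot(box_edge > 0)
  structure(list(coords = coords, box_edge = box_edge),
            class = "coordinate_frame")
}

#' Set of coordinate frames sharing one box
#'
#' @param frames list of [coordinate_frame()]s
#' @param box_edge cubic box edge, nm (may be NULL)
#' @export
coordinate_frame_set <- function(frames, box_edge = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, inherits, logical(1), "coordinate_frame")))
  structure(list(frames = frames, box_edge = box_edge),
            class = "coordinate_frame_set")
}

#' Centre-of-mass distance trajectory
#'
#' Time series of the interchain centre-of-mass distance, the collective
#' coordinate that separates dimer, transition and monomer structures.
#'
#' @param times frame times, ns
#' @param distances COM distances, nm (>= 0)
#' @param temperature simulation temperature, K
#' @param box_edge cubic box edge, nm, or NULL
#' @param frame_interval time between frames, ns (inferred when missing)
#' @export
com_trajectory <- function(times, distances, temperature,
                           box_edge = NULL, frame_interval = NULL) {
  stopifnot(length(times) == length(distances), length(times) >= 1,
            all(distances >= 0), temperature > 0)
  if (length(times) > 1) {
    dtv <- diff(times)
    if (max(dtv) - min(dtv) > 1e-6 * max(abs(dtv)))
      stop("frame interval must be uniform")
    if (is.null(frame_interval)) frame_interval <- dtv[1]
  } else if (is.null(frame_interval)) frame_interval <- NA_real_
  structure(list(times = times, distances = distances,
                 temperature = temperature, box_edge = box_edge,
                 frame_interval = frame_interval),
            class = "com_trajectory")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat(sprintf("COM trajectory: %d frames, %.4g ns/frame, T = %g K\n",
              length(x$times), x$frame_interval, x$temperature))
  cat(sprintf("  distance range %.3f - %.3f nm\n",
              min(x$distances), max(x$distances)))
  invisible(x)
}

# minimum-image displacement for a cubic periodic box
.min_image <- function(delta, box_edge) {
  if (is.null(box_edge)) return(delta)
  delta - box_edge * round(delta / box_edge)
}

#' Interchain centre-of-mass distance from coordinate frames
#'
#' Mass-weighted COM of each chain per frame, then the COM-COM distance
#' under the minimum-image convention in the cubic box. Chains are
#' assumed whole (not wrapped across the boundary); the minimum image is
#' applied to the COM-COM displacement only.
#'
#' @param frames a [coordinate_frame_set()]
#' @param chain_a,chain_b integer row indices of the atoms of each chain
#' @param masses_a,masses_b atomic masses (> 0), recycled if length 1
#' @param box_edge cubic box edge, nm; defaults to the set's box
#' @param temperature temperature recorded on the result, K
#' @param frame_interval ns between frames
#' @return a [com_trajectory()]
#' @export
com_distance_series <- function(frames, chain_a, chain_b,
                                masses_a = 1, masses_b = 1,
                                box_edge = frames$box_edge,
                                temperature = 300, frame_interval = 1) {
  stopifnot(inherits(frames, "coordinate_frame_set"),
            length(chain_a) >= 1, length(chain_b) >= 1,
            all(masses_a > 0), all(masses_b > 0))
  masses_a <- rep_len(masses_a, length(chain_a))
  masses_b <- rep_len(masses_b, length(chain_b))
  dists <- vapply(frames$frames, function(fr) {
    co <- fr$coords
    if (is.null(box_edge) && any(co < 0))
      stop("coordinates outside box bounds but no box edge given")
    com_a <- colSums(co[chain_a, , drop = FALSE] * masses_a) / sum(masses_a)
    com_b <- colSums(co[chain_b, , drop = FALSE] * masses_b) / sum(masses_b)
    sqrt(sum(.min_image(com_a - com_b, box_edge)^2))
  }, numeric(1))
  com_trajectory(times = seq_along(dists) * frame_interval,
                 distances = dists, temperature = temperature,
                 box_edge = box_edge, frame_interval = frame_interval)
}

#' Classify frames as dimer, transition or monomer
#'
#' The dimer is formed when the COM distance is below the dimer
#' threshold and the chains are fully separated monomers above the
#' monomer threshold; everything in between (including frames exactly
#' at a threshold, since the defining inequalities are strict) is the
#' transition region.
#'
#' @param traj a [com_trajectory()] or numeric distance vector
#' @param dimer_threshold nm, default 2.0
#' @param monomer_threshold nm, default 3.5
#' @return a `state_labels` object: factor with levels dimer,
#'   transition, monomer plus the thresholds used
#' @export
classify_states <- function(traj, dimer_threshold = 2.0,
                            monomer_threshold = 3.5) {
  if (dimer_threshold >= monomer_threshold)
    stop("dimer_threshold must be below monomer_threshold")
  d <- if (inherits(traj, "com_trajectory")) traj$distances else traj
  lab <- factor(ifelse(d < dimer_threshold, "dimer",
                ifelse(d > monomer_threshold, "monomer", "transition")),
                levels = c("dimer", "transition", "monomer"))
  structure(list(labels = lab,
                 thresholds = c(dimer = dimer_threshold,
                                monomer = monomer_threshold)),
            class = "state_labels")
}

#' State occupancy probabilities
#'
#' P(state) = frames in the state / total frames; the three
#' probabilities always sum to one.
#'
#' @param labels a `state_labels` object (or factor of labels)
#' @return named numeric vector over dimer, transition, monomer
#' @export
state_occupancy <- function(labels) {
  lab <- if (inherits(labels, "state_labels")) labels$labels else labels
  if (length(lab) == 0) stop("empty trajectory")
  tab <- table(lab)
  as.numeric(tab) / length(lab) -> p
  names(p) <- names(tab)
  p
}

#' Min-max normalized reaction coordinate
#'
#' Maps distances linearly onto the unit interval. By default the range
#' is taken from the analyzed series itself; pass `range` (e.g.
#' c(0, 4)) for cross-trajectory comparability.
#'
#' @param traj a [com_trajectory()] or numeric vector
#' @param range optional fixed c(min, max), nm
#' @return numeric vector in (at least approximately) [0, 1]
#' @export
normalize_coordinate <- function(traj, range = NULL) {
  d <- if (inherits(traj, "com_trajectory")) traj$distances else traj
  if (is.null(range)) range <- base::range(d)
  if (diff(range) <= 0) stop("constant series cannot be normalized")
  (d - range[1]) / diff(range)
}

#' Boltzmann-inversion free-energy profile
#'
#' Histograms the coordinate, converts bin probabilities to free
#' energies F_i = -R T ln P_i, masks bins with fewer than `min_count`
#' samples (rather than assigning them infinite energy), and shifts the
#' unmasked minimum to zero. Energies are molar (kJ/mol) at the stated
#' temperature.
#'
#' @param series numeric coordinate samples (raw nm or normalized), or a
#'   [com_trajectory()]
#' @param temperature temperature, K
#' @param n_bins number of equal-width bins (>= 2)
#' @param min_count bins with fewer samples are masked (NA)
#' @param breaks optional explicit bin breaks overriding `n_bins`
#' @return a `free_energy_profile`: data.frame-like list with
#'   bin_center, free_energy (kJ/mol, min-shifted), counts, plus breaks
#'   and temperature
#' @export
free_energy_profile <- function(series, temperature = 300, n_bins = 50,
                                min_count = 10, breaks = NULL) {
  x <- if (inherits(series, "com_trajectory")) series$distances else series
  stopifnot(n_bins >= 2, length(x) >= 1, temperature > 0)
  if (is.null(breaks)) {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  counts <- .bin_counts(x, breaks)
  if (all(counts < min_count)) stop("all bins below min_count")
  p <- counts / sum(counts)
  RT <- peptherm_constants$R_kJ * temperature
  f <- ifelse(counts >= min_count & p > 0, -RT * log(p), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  structure(list(
    bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
    free_energy = f, counts = counts, breaks = breaks,
    temperature = temperature, min_count = min_count
  ), class = "free_energy_profile")
}

# histogram counts with inclusive outer edges
.bin_counts <- function(x, breaks) {
  x <- x[x >= breaks[1] & x <= breaks[length(breaks)]]
  idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1)
}

#' @export
print.free_energy_profile <- function(x, ...) {
  ok <- !is.na(x$free_energy)
  cat(sprintf(
    "Free-energy profile: %d/%d bins populated (min_count %d), T = %g K\n",
    sum(ok), length(ok), x$min_count, x$temperature))
  cat(sprintf("  max F = %.3f kJ/mol\n", max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Free energies of the coarse states
#'
#' Boltzmann inversion over the three-state partition instead of
#' distance bins: F(state) = -R T ln P(state), min-shifted.
#'
#' @param occupancy output of [state_occupancy()]
#' @param temperature K
#' @return named numeric vector, kJ/mol
#' @export
state_free_energy <- function(occupancy, temperature = 300) {
  RT <- peptherm_constants$R_kJ * temperature
  f <- ifelse(occupancy > 0, -RT * log(occupancy), NA_real_)
  f - min(f, na.rm = TRUE)
}

#' Block-bootstrap variance band for a free-energy profile
#'
#' Circular block bootstrap over contiguous blocks of frames (the
#' default respects the autocorrelation of a diffusive trajectory;
#' block_length = 1 degenerates to the naive iid bootstrap). Every
#' resample is re-binned with the same breaks as the point estimate and
#' the per-bin variance of the min-shifted free energy across resamples
#' is reported.
#'
#' @param series numeric coordinate samples or a [com_trajectory()]
#' @param temperature K
#' @param n_bins,min_count,breaks as in [free_energy_profile()]
#' @param n_boot number of bootstrap resamples (>= 2)
#' @param block_length frames per block (>= 1, < series length)
#' @param seed integer RNG seed
#' @return the point-estimate `free_energy_profile` with an added
#'   `variance` element (kJ/mol)^2 per bin
#' @export
bootstrap_fep <- function(series, temperature = 300, n_bins = 50,
                          min_count = 10, n_boot = 100,
                          block_length = 100, seed = 1, breaks = NULL) {
  x <- if (inherits(series, "com_trajectory")) series$distances else series
  n <- length(x)
  stopifnot(n_boot >= 2, block_length >= 1)
  if (block_length >= n) stop("block_length must be below the series length")
  point <- free_energy_profile(x, temperature, n_bins, min_count, breaks)
  brk <- point$breaks
  n_blocks <- ceiling(n / block_length)
  fmat <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      starts <- sample.int(n, n_blocks, replace = TRUE)
      idx <- (rep(starts, each = block_length) +
                rep(seq_len(block_length) - 1L, n_blocks) - 1L) %% n + 1L
      idx <- idx[seq_len(n)]
      fp <- free_energy_profile(x[idx], temperature, min_count = min_count,
                                breaks = brk)
      fp$free_energy
    }, numeric(length(point$bin_center)))
  })
  point$variance <- apply(fmat, 1, stats::var, na.rm = TRUE)
  point$variance[is.na(point$free_energy)] <- NA_real_
  point$n_boot <- n_boot
  point$block_length <- block_length
  point
}

#' Geometric hydrogen-bond criteria
#'
#' Standard geometric convention: donor-acceptor distance at most
#' `max_da_distance` and deviation of the donor-hydrogen-acceptor angle
#' from linearity at most `max_deviation_angle`.
#'
#' @param max_da_distance nm, default 0.35
#' @param max_deviation_angle degrees in (0, 90], default 30
#' @export
hbond_criteria <- function(max_da_distance = 0.35,
                           max_deviation_angle = 30) {
  stopifnot(max_da_distance > 0, max_deviation_angle > 0,
            max_deviation_angle <= 90)
  structure(list(max_da_distance = max_da_distance,
                 max_deviation_angle = max_deviation_angle),
            class = "hbond_criteria")
}

#' Count hydrogen bonds in a frame
#'
#' Tests every (donor, hydrogen) pair against every acceptor: a bond is
#' counted when the D-A distance and the D-H-A deviation from linearity
#' both satisfy the criteria. `donors` and `hydrogens` are parallel
#' vectors (hydrogen i is covalently bound to donor i); an acceptor
#' identical to the donor is skipped.
#'
#' @param frame a [coordinate_frame()]
#' @param donors,hydrogens parallel integer row indices
#' @param acceptors integer row indices of acceptor atoms
#' @param criteria a [hbond_criteria()]
#' @return list(count, pairs): pairs is a data.frame with donor,
#'   hydrogen, acceptor indices, da_distance and deviation_angle
#' @export
count_hbonds <- function(frame, donors, hydrogens, acceptors,
                         criteria = hbond_criteria()) {
  stopifnot(inherits(frame, "coordinate_frame"),
            length(donors) == length(hydrogens))
  co <- frame$coords
  rows <- list()
  for (i in seq_along(donors)) {
    d <- co[donors[i], ]; h <- co[hydrogens[i], ]
    if (sqrt(sum((h - d)^2)) > 0.15)
      stop("hydrogen ", hydrogens[i], " is not bound to donor ", donors[i],
           " (D-H distance > 0.15 nm)")
    for (a in acceptors) {
      if (a == donors[i]) next
      acc <- co[a, ]
      rda <- sqrt(sum(.min_image(acc - d, frame$box_edge)^2))
      if (rda > criteria$max_da_distance) next
      v1 <- d - h; v2 <- acc - h
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      dev <- 180 - ang
      if (dev > criteria$max_deviation_angle) next
      rows[[length(rows) + 1]] <- data.frame(
        donor = donors[i], hydrogen = hydrogens[i], acceptor = a,
        da_distance = rda, deviation_angle = dev)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = integer(), hydrogen = integer(),
               acceptor = integer(), da_distance = numeric(),
               deviation_angle = numeric())
  list(count = nrow(pairs), pairs = pairs)
}

#' Radial distribution function
#'
#' Pair-distance histogram between a reference and a target selection
#' under the minimum-image convention, normalized by the ideal-gas
#' expectation at the target number density so that uncorrelated
#' particles give g(r) = 1, averaged over frames. Defined for
#' r < box_edge/2 only.
#'
#' @param frames a [coordinate_frame_set()]
#' @param reference,target integer row indices (may coincide)
#' @param box_edge cubic box edge, nm
#' @param bin_width nm
#' @param r_max maximum distance, nm (<= box_edge/2)
#' @return an `rdf_curve`: data.frame-like list with r (bin centers),
#'   g, counts, bin_width
#' @export
rdf <- function(frames, reference, target, box_edge = frames$box_edge,
                bin_width = 0.05, r_max = box_edge / 2) {
  stopifnot(inherits(frames, "coordinate_frame_set"),
            length(reference) >= 1, length(target) >= 1,
            !is.null(box_edge), bin_width > 0)
  if (r_max > box_edge / 2 + 1e-9)
    stop("r_max must not exceed box_edge/2")
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  n_overlap <- length(intersect(reference, target))
  n_frames <- length(frames$frames)
  for (fr in frames$frames) {
    co <- fr$coords
    ref <- co[reference, , drop = FALSE]
    tar <- co[target, , drop = FALSE]
    dx <- .min_image(outer(ref[, 1], tar[, 1], "-"), box_edge)
    dy <- .min_image(outer(ref[, 2], tar[, 2], "-"), box_edge)
    dz <- .min_image(outer(ref[, 3], tar[, 3], "-"), box_edge)
    dd <- sqrt(dx^2 + dy^2 + dz^2)
    if (n_overlap > 0) dd[dd == 0] <- NA # drop self pairs
    dd <- dd[!is.na(dd) & dd < r_max & dd > 0]
    idx <- findInterval(dd, breaks, all.inside = TRUE)
    counts <- counts + tabulate(idx, nbins = nb)
  }
  volume <- box_edge^3
  n_pairs <- length(reference) * length(target) - n_overlap
  shell <- 4 / 3 * pi * diff(breaks^3)
  expected <- n_frames * n_pairs * shell / volume
  g <- counts / expected
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 g = g, counts = counts, bin_width = bin_width,
                 breaks = breaks, box_edge = box_edge),
            class = "rdf_curve")
}

#' @export
print.rdf_curve <- function(x, ...) {
  cat(sprintf("RDF: %d bins of %.3g nm up to %.3g nm, %d pair counts\n",
              length(x$r), x$bin_width, max(x$breaks), sum(x$counts)))
  invisible(x)
}
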