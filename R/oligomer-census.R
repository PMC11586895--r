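#' Theoretical m/z of a peptide oligomer charge state
#'
#' m/z = (order * neutral monomer mass + adduct mass + z * proton) / z.
#' The neutral monomer mass is the residue-mass sum plus one water;
#' C-terminal amidation replaces the terminal -OH by -NH2 (-0.98402 Da
#' per monomer). Monoisotopic masses are the default; `mass_type =
#' "average"` matches low-resolution peak labels.
#'
#' @param sequence one-letter amino-acid sequence of the monomer
#' @param oligomer_order number of monomers in the species, >= 1
#' @param charge positive charge state, >= 1
#' @param c_terminal_amide is the C-terminus amidated?
#' @param adduct_mass extra neutral adduct mass, Da (e.g. 75.068 for a
#'   bound trimethylamine N-oxide)
#' @param mass_type "monoisotopic" or "average"
#' @return m/z
#' @examples
#' # substance P, amidated undecapeptide; its 2+ TMAO complex sits near
#' # m/z 711.9
#' theoretical_mz("RPKPQQFFGLM", 1, 2, c_terminal_amide = TRUE,
#'                adduct_mass = 75.068)
#' @export
theoretical_mz <- function(sequence, oligomer_order = 1, charge = 1,
                           c_terminal_amide = TRUE, adduct_mass = 0,
                           mass_type = c("monoisotopic", "average")) {
  mass_type <- match.arg(mass_type)
  stopifnot(oligomer_order >= 1, charge >= 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  tbl <- if (mass_type == "monoisotopic") .residue_mono else .residue_avg
  unknown <- setdiff(aa, names(tbl))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  water <- if (mass_type == "monoisotopic") peptherm_constants$water_mono
           else peptherm_constants$water_avg
  monomer <- sum(tbl[aa]) + water +
    if (c_terminal_amide) peptherm_constants$amide_correction else 0
  (oligomer_order * monomer + adduct_mass +
      charge * peptherm_constants$proton_mass) / charge
}

#' Peak list constructor
#'
#' @param x data.frame with columns mz (increasing) and intensity (>= 0)
#' @export
peak_list <- function(x) {
  stopifnot(is.data.frame(x), all(c("mz", "intensity") %in% names(x)))
  if (is.unsorted(x$mz)) x <- x[order(x$mz), ]
  if (any(x$intensity < 0)) stop("intensities must be non-negative")
  rownames(x) <- NULL
  class(x) <- c("peak_list", "data.frame")
  x
}

#' Species table for oligomer assignment
#'
#' Computes the theoretical m/z for each (sequence, order, charge)
#' species and returns the annotated table used by [assign_peaks()].
#'
#' @param species data.frame with columns sequence, oligomer_order,
#'   charge and optionally c_terminal_amide (default TRUE), adduct_mass
#'   (default 0), label
#' @param mass_type passed to [theoretical_mz()]
#' @return the data.frame with a theoretical_mz column appended
#' @export
species_table <- function(species, mass_type = "monoisotopic") {
  stopifnot(is.data.frame(species),
            all(c("sequence", "oligomer_order", "charge") %in%
                  names(species)))
  if (is.null(species$c_terminal_amide)) species$c_terminal_amide <- TRUE
  if (is.null(species$adduct_mass)) species$adduct_mass <- 0
  species$theoretical_mz <- mapply(
    theoretical_mz, species$sequence, species$oligomer_order,
    species$charge, species$c_terminal_amide, species$adduct_mass,
    MoreArgs = list(mass_type = mass_type))
  if (is.null(species$label))
    species$label <- sprintf("%s_n%d_z%d", species$sequence,
                             species$oligomer_order, species$charge)
  species
}

#' Assign peaks to theoretical species
#'
#' Each peak is matched to the species within `tolerance` of its m/z.
#' A unique match takes the full peak intensity; when several species
#' fall within tolerance the intensity is split by inverse-distance
#' weights (an exact-distance match takes everything) and the peak is
#' flagged ambiguous. Peaks with no species in tolerance stay
#' unassigned. Total intensity is conserved: assigned + unassigned
#' equals the peak-list total.
#'
#' @param peaks a [peak_list()]
#' @param species a [species_table()] (or data.frame accepted by it)
#' @param tolerance m/z tolerance, > 0
#' @return a `peak_assignment`: list with per-species aggregate
#'   intensities (`by_species`), peak-level assignments (`detail`),
#'   `unassigned` intensity and `ambiguous` peak count
#' @export
assign_peaks <- function(peaks, species, tolerance = 0.5) {
  stopifnot(inherits(peaks, "peak_list") || is.data.frame(peaks),
            tolerance > 0)
  if (is.null(species$theoretical_mz)) species <- species_table(species)
  sp_mz <- species$theoretical_mz
  n_sp <- length(sp_mz)
  agg <- numeric(n_sp)
  unassigned <- 0
  ambiguous <- 0L
  det <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    dist <- abs(peaks$mz[i] - sp_mz)
    within <- which(dist <= tolerance)
    inten <- peaks$intensity[i]
    if (length(within) == 0) {
      unassigned <- unassigned + inten
      next
    }
    if (length(within) == 1) {
      w <- 1
    } else {
      ambiguous <- ambiguous + 1L
      d <- dist[within]
      if (any(d == 0)) {
        w <- as.numeric(d == 0) / sum(d == 0)
      } else {
        w <- (1 / d) / sum(1 / d)
      }
    }
    agg[within] <- agg[within] + inten * w
    det[[i]] <- data.frame(peak_mz = peaks$mz[i], intensity = inten,
                           species = within, weight = w,
                           flagged = length(within) > 1)
  }
  detail <- if (any(!vapply(det, is.null, logical(1))))
    do.call(rbind, det) else
    data.frame(peak_mz = numeric(), intensity = numeric(),
               species = integer(), weight = numeric(), flagged = logical())
  by_species <- data.frame(label = species$label,
                           oligomer_order = species$oligomer_order,
                           charge = species$charge,
                           theoretical_mz = sp_mz,
                           assigned_intensity = agg)
  structure(list(by_species = by_species, detail = detail,
                 unassigned = unassigned, ambiguous = ambiguous,
                 total = sum(peaks$intensity)),
            class = "peak_assignment")
}

#' Oligomer abundances and degree of oligomerization
#'
#' Sums assigned intensity per oligomer order (across charge states) up
#' to `max_order` (default 3, mirroring software that quantifies up to
#' the trimer). The degree of oligomerization is, by default, the
#' monomer-equivalent mass fraction residing in oligomers,
#' sum_\{n>=2\} n I_n / sum_\{n>=1\} n I_n; `method = "signal_fraction"`
#' uses the plain signal share sum_\{n>=2\} I_n / sum I_n instead.
#'
#' @param assignment a `peak_assignment` from [assign_peaks()]
#' @param max_order highest oligomer order quantified
#' @param method "mass_fraction" (default) or "signal_fraction"
#' @return an `oligomer_abundances` list: per-order intensities,
#'   degree_of_oligomerization in [0, 1], unassigned fraction
#' @export
oligomer_abundances <- function(assignment, max_order = 3,
                                method = c("mass_fraction",
                                           "signal_fraction")) {
  method <- match.arg(method)
  stopifnot(inherits(assignment, "peak_assignment"))
  bys <- assignment$by_species
  bys <- bys[bys$oligomer_order <= max_order, ]
  if (nrow(bys) == 0 || sum(bys$assigned_intensity) == 0)
    stop("nothing assigned at or below the requested oligomer order")
  orders <- seq_len(max_order)
  per_order <- vapply(orders, function(n)
    sum(bys$assigned_intensity[bys$oligomer_order == n]), numeric(1))
  names(per_order) <- paste0("order_", orders)
  w <- if (method == "mass_fraction") orders else rep(1, max_order)
  degree <- sum(w[-1] * per_order[-1]) / sum(w * per_order)
  structure(list(per_order = per_order,
                 degree_of_oligomerization = degree,
                 method = method,
                 unassigned_fraction =
                   assignment$unassigned / max(assignment$total, 1e-300)),
            class = "oligomer_abundances")
}

#' @export
print.oligomer_abundances <- function(x, ...) {
  cat("Oligomer abundances (", x$method, "):\n", sep = "")
  for (n in seq_along(x$per_order))
    cat(sprintf("  order %d: %.4g\n", n, x$per_order[n]))
  cat(sprintf("  degree of oligomerization: %.4f\n",
              x$degree_of_oligomerization))
  invisible(x)
}

#' Compare degree of oligomerization between two conditions
#'
#' Mean and standard deviation of replicate degree-of-oligomerization
#' values per condition (e.g. with and without osmolyte for one mutant)
#' and the difference of means (condition_b minus condition_a).
#'
#' @param degrees_a,degrees_b numeric replicate degrees (>= 2 each)
#' @param labels length-2 character vector naming the conditions
#' @return data.frame with one row per condition plus a `difference`
#'   attribute
#' @export
compare_conditions <- function(degrees_a, degrees_b,
                               labels = c("condition_a", "condition_b")) {
  stopifnot(length(degrees_a) >= 2, length(degrees_b) >= 2,
            length(labels) == 2)
  out <- data.frame(
    condition = labels,
    n = c(length(degrees_a), length(degrees_b)),
    mean = c(mean(degrees_a), mean(degrees_b)),
    sd = c(stats::sd(degrees_a), stats::sd(degrees_b)))
  attr(out, "difference") <- mean(degrees_b) - mean(degrees_a)
  out
}
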