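#' Intensity table constructor
#'
#' Long-format table of per-temperature, per-replicate ion intensities
#' for the species monomer, dimer and sp_tmao_complex. The monomer row
#' must be present for every (temperature, replicate) pair because both
#' apparent association constants normalize by it.
#'
#' @param x data.frame with columns temperature_K, replicate, species,
#'   intensity
#' @return the validated data.frame with class `intensity_table`
#' @export
intensity_table <- function(x) {
  need <- c("temperature_K", "replicate", "species", "intensity")
  if (!all(need %in% names(x)))
    stop("intensity table needs columns: ", paste(need, collapse = ", "))
  if (any(x$intensity < 0)) stop("intensities must be non-negative")
  bad <- !x$species %in% c("monomer", "dimer", "sp_tmao_complex")
  if (any(bad))
    stop("unknown species: ", paste(unique(x$species[bad]), collapse = ", "))
  key <- interaction(x$temperature_K, x$replicate, drop = TRUE)
  has_mono <- tapply(x$species == "monomer", key, any)
  if (!all(has_mono))
    stop("every (temperature, replicate) pair needs a monomer row")
  class(x) <- c("intensity_table", "data.frame")
  x
}

#' Apparent dimerization constant from ion intensities
#'
#' Ka = I_dimer / I_monomer^2. The monomer intensity is squared because
#' the free ligand of the self-assembly reaction is the monomer itself.
#' The result carries inverse-intensity units; the constant unit factor
#' shifts the van't Hoff intercept but leaves the slope (and hence the
#' enthalpy) untouched.
#'
#' @param i_dimer dimer ion intensity, counts (>= 0)
#' @param i_monomer monomer ion intensity, counts (> 0)
#' @return apparent Ka, 1/intensity units
#' @export
compute_ka_dimer <- function(i_dimer, i_monomer) {
  if (any(i_monomer <= 0)) stop("monomer intensity must be positive")
  if (any(i_dimer < 0)) stop("dimer intensity must be non-negative")
  i_dimer / i_monomer^2
}

#' Apparent peptide-osmolyte association constant
#'
#' Ka = I_complex / (I_monomer * [TMAO]); the osmolyte is in vast excess
#' so its free concentration is taken as the nominal one.
#'
#' @param i_complex complex ion intensity, counts (>= 0)
#' @param i_monomer monomer ion intensity, counts (> 0)
#' @param tmao_concentration osmolyte concentration, mol/L (> 0)
#' @return apparent Ka, 1/(intensity * M) units
#' @export
compute_ka_complex <- function(i_complex, i_monomer, tmao_concentration) {
  if (any(i_monomer <= 0)) stop("monomer intensity must be positive")
  if (any(tmao_concentration <= 0)) stop("tmao concentration must be positive")
  if (any(i_complex < 0)) stop("complex intensity must be non-negative")
  i_complex / (i_monomer * tmao_concentration)
}

#' Build a van't Hoff series from an intensity table
#'
#' Computes ln Ka per replicate at each temperature, then averages
#' across replicates on the log scale (matching the multiplicative
#' noise model; set `average = "linear"` to average Ka before taking
#' logs). Replicates whose product intensity is zero are dropped;
#' temperatures losing all replicates are excluded. Drop counts are
#' recorded in the `dropped` attribute and reported via `message()`.
#'
#' @param table an [intensity_table()]
#' @param reaction "dimerization" or "tmao_binding"
#' @param tmao_concentration required for `tmao_binding`, mol/L
#' @param average "log" (default) or "linear" replicate averaging
#' @return a `vant_hoff_series` data.frame with columns
#'   inverse_temperature, ln_ka, ln_ka_sd, n_replicates, temperature_K,
#'   sorted by inverse temperature
#' @export
build_vant_hoff_series <- function(table,
                                   reaction = c("dimerization",
                                                "tmao_binding"),
                                   tmao_concentration = NULL,
                                   average = c("log", "linear")) {
  reaction <- match.arg(reaction)
  average <- match.arg(average)
  stopifnot(inherits(table, "intensity_table"))
  product <- switch(reaction, dimerization = "dimer",
                    tmao_binding = "sp_tmao_complex")
  if (reaction == "tmao_binding" && is.null(tmao_concentration))
    stop("tmao_concentration is required for the tmao_binding reaction")
  mono <- table[table$species == "monomer", ]
  prod <- table[table$species == product, ]
  m <- merge(mono[, c("temperature_K", "replicate", "intensity")],
             prod[, c("temperature_K", "replicate", "intensity")],
             by = c("temperature_K", "replicate"),
             suffixes = c("_monomer", "_product"))
  ka <- if (reaction == "dimerization")
    compute_ka_dimer(m$intensity_product, m$intensity_monomer)
  else
    compute_ka_complex(m$intensity_product, m$intensity_monomer,
                       tmao_concentration)
  keep <- ka > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " replicate measurement(s) with zero product ",
            "intensity dropped")
  m <- m[keep, ]; ka <- ka[keep]
  if (length(unique(m$temperature_K)) < 2)
    stop("fewer than 2 usable temperatures after dropping zero-product rows")
  ln_ka_rep <- log(ka)
  sp <- split(seq_along(ln_ka_rep), m$temperature_K)
  rows <- lapply(sp, function(idx) {
    lk <- ln_ka_rep[idx]
    mean_lk <- if (average == "log") mean(lk) else log(mean(exp(lk)))
    data.frame(
      temperature_K = m$temperature_K[idx[1]],
      inverse_temperature = 1 / m$temperature_K[idx[1]],
      ln_ka = mean_lk,
      ln_ka_sd = if (length(lk) >= 2) stats::sd(lk) else NA_real_,
      n_replicates = length(lk))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$inverse_temperature), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- n_dropped
  attr(out, "reaction") <- reaction
  class(out) <- c("vant_hoff_series", "data.frame")
  out
}

#' Ordinary least squares van't Hoff fit over one regime
#'
#' Fits ln Ka = slope * (1/T) + intercept by OLS over the points whose
#' temperature lies in `temperature_range` (all points by default).
#'
#' @param series a `vant_hoff_series`
#' @param temperature_range optional c(min, max) in K (inclusive)
#' @return a `regime_fit` with slope (K), intercept, their standard
#'   errors, n_points and the fitted temperature range
#' @export
fit_single_regime <- function(series, temperature_range = NULL) {
  stopifnot(inherits(series, "vant_hoff_series"))
  s <- series
  if (!is.null(temperature_range)) {
    stopifnot(length(temperature_range) == 2)
    s <- s[s$temperature_K >= min(temperature_range) &
             s$temperature_K <= max(temperature_range), ]
  }
  if (nrow(s) < 2) stop("need at least 2 points in the temperature range")
  if (length(unique(s$temperature_K)) < 2)
    stop("singular design: all temperatures equal")
  fit <- stats::lm(ln_ka ~ inverse_temperature, data = s)
  # noiseless generated series fit exactly; summary.lm warns about that
  cf <- suppressWarnings(summary(fit))$coefficients
  # with 2 points the fit is exact and OLS standard errors are 0/NaN
  se <- if (nrow(s) > 2) cf[, "Std. Error"] else c(0, 0)
  structure(list(
    slope = unname(cf["inverse_temperature", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope_sd = unname(se[2]), intercept_sd = unname(se[1]),
    rss = sum(stats::resid(fit)^2),
    n_points = nrow(s),
    temperature_range = range(s$temperature_K)
  ), class = "regime_fit")
}

#' @export
print.regime_fit <- function(x, ...) {
  cat(sprintf("van't Hoff regime fit over %.0f-%.0f K (%d points)\n",
              x$temperature_range[1], x$temperature_range[2], x$n_points))
  cat(sprintf("  slope = %.4g K (dH = %.4g kJ/mol), intercept = %.4g\n",
              x$slope, -peptherm_constants$R_kJ * x$slope, x$intercept))
  invisible(x)
}

#' Two-regime (segmented) van't Hoff fit with breakpoint search
#'
#' Splits the series at a breakpoint temperature into a low-temperature
#' regime (T <= breakpoint) and a high-temperature regime
#' (T > breakpoint) and fits each by OLS. With
#' `candidate_breakpoints = "auto"` every interior measured temperature
#' leaving at least 3 points on each side is tried and the breakpoint
#' minimizing the total residual sum of squares wins; exact ties are
#' broken toward the candidate closest to the median temperature. A
#' fixed breakpoint (or an explicit candidate list) can be supplied
#' instead. The fit is flagged degenerate when the two slopes differ by
#' no more than their pooled standard error, i.e. when a single line
#' explains the data as well.
#'
#' @param series a `vant_hoff_series`
#' @param candidate_breakpoints "auto", or numeric candidate
#'   temperatures in K
#' @return a `two_regime_fit`: breakpoint (K), low_regime and
#'   high_regime [fit_single_regime()] results, rss, degenerate_flag
#' @export
fit_two_regime <- function(series, candidate_breakpoints = "auto") {
  stopifnot(inherits(series, "vant_hoff_series"))
  temps <- sort(unique(series$temperature_K))
  admissible <- function(bp)
    sum(temps <= bp) >= 3 && sum(temps > bp) >= 3
  cands <- if (identical(candidate_breakpoints, "auto")) {
    Filter(admissible, temps)
  } else {
    stopifnot(is.numeric(candidate_breakpoints))
    keep <- vapply(candidate_breakpoints, admissible, logical(1))
    if (!any(keep)) stop("no admissible breakpoint")
    if (any(!keep))
      warning(sum(!keep), " candidate breakpoint(s) without 3 points on ",
              "each side discarded")
    candidate_breakpoints[keep]
  }
  cands <- unlist(cands)
  if (length(cands) == 0) stop("no admissible breakpoint")
  fits <- lapply(cands, function(bp) {
    lo <- fit_single_regime(series, c(-Inf, bp))
    hi <- fit_single_regime(series, c(bp + 1e-9, Inf))
    list(bp = bp, low = lo, high = hi, rss = lo$rss + hi$rss)
  })
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best_rss <- min(rss)
  tied <- which(rss <= best_rss + 1e-12 * max(best_rss, 1))
  if (length(tied) > 1) {
    med <- stats::median(series$temperature_K)
    tied <- tied[order(abs(cands[tied] - med))]
  }
  best <- fits[[tied[1]]]
  pooled_sd <- sqrt(best$low$slope_sd^2 + best$high$slope_sd^2)
  # the floor keeps exact (noiseless) fits with equal slopes, where the
  # OLS standard errors collapse to ~0, on the degenerate side
  slope_scale <- max(abs(best$low$slope), abs(best$high$slope), 1)
  degenerate <- is.finite(pooled_sd) &&
    abs(best$low$slope - best$high$slope) <= pooled_sd + 1e-8 * slope_scale
  structure(list(
    breakpoint = best$bp,
    low_regime = best$low, high_regime = best$high,
    rss = best$rss, degenerate_flag = degenerate,
    candidates = cands
  ), class = "two_regime_fit")
}

#' @export
print.two_regime_fit <- function(x, ...) {
  cat(sprintf("Two-regime van't Hoff fit: breakpoint %.1f K (RSS %.3g)%s\n",
              x$breakpoint, x$rss,
              if (x$degenerate_flag) " [degenerate: slopes indistinguishable]"
              else ""))
  cat("low regime:  "); print(x$low_regime)
  cat("high regime: "); print(x$high_regime)
  invisible(x)
}

#' Thermodynamic quantities from a van't Hoff fit
#'
#' Under ln Ka = -dH/(R T) + dS/R: dH = -R * slope, dS = R * intercept,
#' -TdS = -T_ref * dS and dG = dH - T_ref * dS, with standard errors
#' propagated linearly from the slope/intercept standard errors
#' (slope and intercept treated as independent; replicate-level
#' resampling via [replicate_uncertainty()] is the primary uncertainty
#' channel).
#'
#' @param fit a `regime_fit`
#' @param reference_temperature temperature at which -TdS and dG are
#'   evaluated, K
#' @return a `thermo_quantities` list: dH, dS, mTdS_at_ref, dG_at_ref
#'   (kJ/mol; dS in kJ/mol/K), their sds, and reference_temperature
#' @export
thermo_from_fit <- function(fit, reference_temperature = 293) {
  stopifnot(inherits(fit, "regime_fit"), reference_temperature > 0,
            is.finite(fit$slope), is.finite(fit$intercept))
  R <- peptherm_constants$R_kJ
  dH <- -R * fit$slope
  dS <- R * fit$intercept
  mTdS <- -reference_temperature * dS
  dH_sd <- R * fit$slope_sd
  dS_sd <- R * fit$intercept_sd
  mTdS_sd <- reference_temperature * dS_sd
  structure(list(
    dH = dH, dS = dS, mTdS_at_ref = mTdS, dG_at_ref = dH + mTdS,
    dH_sd = dH_sd, dS_sd = dS_sd, mTdS_sd = mTdS_sd,
    dG_sd = sqrt(dH_sd^2 + mTdS_sd^2),
    reference_temperature = reference_temperature
  ), class = "thermo_quantities")
}

#' @export
print.thermo_quantities <- function(x, ...) {
  cat(sprintf(
    "dH = %.1f kJ/mol, -TdS(%.0f K) = %.1f kJ/mol, dG = %.1f kJ/mol\n",
    x$dH, x$reference_temperature, x$mTdS_at_ref, x$dG_at_ref))
  invisible(x)
}

#' Replicate-level uncertainty of derived thermodynamic quantities
#'
#' Refits each replicate-resampled table (or accepts a list of fits /
#' thermo_quantities) and returns the sample standard deviation of each
#' derived quantity, mirroring the triplicate error-bar convention.
#'
#' @param fits list of `regime_fit` or `thermo_quantities` objects
#' @param reference_temperature used when converting fits, K
#' @return named numeric vector of sds for dH, dS, mTdS_at_ref,
#'   dG_at_ref
#' @export
replicate_uncertainty <- function(fits, reference_temperature = 293) {
  stopifnot(length(fits) >= 2)
  tq <- lapply(fits, function(f) {
    if (inherits(f, "regime_fit")) thermo_from_fit(f, reference_temperature)
    else if (inherits(f, "thermo_quantities")) f
    else stop("fits must be regime_fit or thermo_quantities objects")
  })
  qty <- c("dH", "dS", "mTdS_at_ref", "dG_at_ref")
  vapply(qty, function(q)
    stats::sd(vapply(tq, `[[`, numeric(1), q)), numeric(1))
}
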