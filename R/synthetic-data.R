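#' Two-regime van't Hoff thermodynamic model
#'
#' Describes the equilibrium constant of an association reaction whose
#' van't Hoff plot (ln Ka against 1/T) is piecewise linear with a single
#' breakpoint: a low-temperature regime and a high-temperature regime
#' with different enthalpies. Enthalpy-entropy compensation keeps the
#' free energy nearly constant across such a break, so the model pins
#' ln Ka to be continuous at the breakpoint: the high-temperature
#' regime is anchored by its (dH, -TdS) pair and the low-temperature
#' regime inherits its intercept from continuity, differing in slope
#' only. The `mTdS_ref_low` argument is therefore advisory: the implied
#' low-regime -TdS is returned alongside it so callers can check that
#' the two agree to within rounding.
#'
#' @param breakpoint_temperature breakpoint between the regimes, K
#' @param dH_low,dH_high regime enthalpies, kJ/mol
#' @param mTdS_ref_high -T*dS of the high-temperature regime evaluated
#'   at `reference_temperature_high`, kJ/mol
#' @param reference_temperature_high,reference_temperature_low reference
#'   temperatures for the -TdS values, K
#' @param mTdS_ref_low optional stated low-regime -TdS at
#'   `reference_temperature_low`, kJ/mol (checked, not imposed)
#' @return an object of class `two_regime_thermo` with the regime
#'   slopes/intercepts of ln Ka = slope * (1/T) + intercept
#' @examples
#' th <- two_regime_thermo(293, dH_low = -26.4, dH_high = -71.1,
#'                         mTdS_ref_high = 53.6)
#' ln_ka_model(th, c(278, 293, 358))
#' @export
two_regime_thermo <- function(breakpoint_temperature,
                              dH_low, dH_high,
                              mTdS_ref_high,
                              reference_temperature_high = 293,
                              reference_temperature_low = reference_temperature_high,
                              mTdS_ref_low = NULL) {
  stopifnot(is.finite(breakpoint_temperature), breakpoint_temperature > 0,
            is.finite(dH_low), is.finite(dH_high), is.finite(mTdS_ref_high),
            reference_temperature_high > 0, reference_temperature_low > 0)
  R <- peptherm_constants$R_kJ
  dS_high <- -mTdS_ref_high / reference_temperature_high # kJ/mol/K
  slope_high <- -dH_high / R
  intercept_high <- dS_high / R
  tb <- breakpoint_temperature
  ln_ka_tb <- slope_high / tb + intercept_high
  slope_low <- -dH_low / R
  intercept_low <- ln_ka_tb - slope_low / tb # continuity at the breakpoint
  implied_mTdS_low <- -reference_temperature_low * (R * intercept_low)
  structure(list(
    breakpoint_temperature = breakpoint_temperature,
    dH_low = dH_low, dH_high = dH_high,
    mTdS_ref_low = mTdS_ref_low, mTdS_ref_high = mTdS_ref_high,
    reference_temperature_low = reference_temperature_low,
    reference_temperature_high = reference_temperature_high,
    slope_low = slope_low, intercept_low = intercept_low,
    slope_high = slope_high, intercept_high = intercept_high,
    implied_mTdS_low = implied_mTdS_low
  ), class = "two_regime_thermo")
}

#' Single-regime van't Hoff model
#'
#' Convenience constructor for a thermodynamic model whose van't Hoff
#' plot is one straight line (both regimes identical).
#'
#' @inheritParams two_regime_thermo
#' @param dH enthalpy, kJ/mol
#' @param mTdS_ref -T*dS at `reference_temperature`, kJ/mol
#' @param reference_temperature reference temperature, K
#' @export
single_regime_thermo <- function(dH, mTdS_ref, reference_temperature = 293) {
  two_regime_thermo(breakpoint_temperature = reference_temperature,
                    dH_low = dH, dH_high = dH,
                    mTdS_ref_high = mTdS_ref,
                    reference_temperature_high = reference_temperature)
}

#' Model ln Ka at given temperatures
#'
#' @param thermo a [two_regime_thermo()] object
#' @param temperatures temperatures, K
#' @return numeric vector of ln Ka
#' @export
ln_ka_model <- function(thermo, temperatures) {
  stopifnot(inherits(thermo, "two_regime_thermo"))
  tb <- thermo$breakpoint_temperature
  ifelse(temperatures <= tb,
         thermo$slope_low / temperatures + thermo$intercept_low,
         thermo$slope_high / temperatures + thermo$intercept_high)
}

#' @export
print.two_regime_thermo <- function(x, ...) {
  cat("Two-regime van't Hoff model\n")
  cat(sprintf("  breakpoint: %.1f K\n", x$breakpoint_temperature))
  cat(sprintf("  low  regime: dH = %.2f kJ/mol (implied -TdS at %.0f K = %.2f)\n",
              x$dH_low, x$reference_temperature_low, x$implied_mTdS_low))
  cat(sprintf("  high regime: dH = %.2f kJ/mol, -TdS at %.0f K = %.2f\n",
              x$dH_high, x$reference_temperature_high, x$mTdS_ref_high))
  invisible(x)
}

#' Replicate noise specification
#'
#' Triplicate acquisition with scale-proportional (multiplicative
#' log-normal) intensity error is the default experimental design
#' emulated by the intensity generator.
#'
#' @param replicates number of replicate acquisitions, >= 1
#' @param cv coefficient of variation of the multiplicative noise on the
#'   linear intensity scale, >= 0
#' @param seed integer RNG seed
#' @export
noise_spec <- function(replicates = 3, cv = 0.05, seed = 1) {
  stopifnot(replicates >= 1, cv >= 0)
  structure(list(replicates = as.integer(replicates), cv = cv,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Synthetic variable-temperature ESI intensity table
#'
#' Emits monomer, dimer and peptide-osmolyte-complex ion intensities at
#' each requested solution temperature such that, in the noiseless
#' limit, the intensity ratios of [compute_ka_dimer()] and
#' [compute_ka_complex()] reproduce the two-regime ln Ka model exactly.
#' The monomer intensity is held constant across temperature (only the
#' intensity ratios carry thermodynamic information); noise is
#' multiplicative log-normal with unit mean and the stated linear-scale
#' coefficient of variation, applied independently per row.
#'
#' @param thermo a [two_regime_thermo()] model for the reaction
#' @param temperatures solution temperatures, K (270-370 K accepted)
#' @param monomer_intensity noiseless monomer ion intensity, counts
#' @param tmao_concentration osmolyte concentration, mol/L, used for the
#'   complex channel
#' @param noise a [noise_spec()]
#' @return an `intensity_table` data.frame with columns temperature_K,
#'   replicate, species, intensity
#' @examples
#' th <- single_regime_thermo(dH = -71.1, mTdS_ref = 53.6)
#' tab <- generate_vant_hoff_intensities(th, seq(298, 358, 5),
#'          noise = noise_spec(replicates = 1, cv = 0))
#' @export
generate_vant_hoff_intensities <- function(thermo, temperatures,
                                           monomer_intensity = 1000,
                                           tmao_concentration = 5e-4,
                                           noise = noise_spec()) {
  stopifnot(inherits(thermo, "two_regime_thermo"),
            inherits(noise, "noise_spec"),
            monomer_intensity > 0, tmao_concentration > 0)
  if (any(temperatures < 270 | temperatures > 370))
    stop("temperatures must lie within 270-370 K")
  ln_ka <- ln_ka_model(thermo, temperatures)
  ka <- exp(ln_ka)
  i_dim <- ka * monomer_intensity^2
  i_cpx <- ka * monomer_intensity * tmao_concentration
  grid <- expand.grid(replicate = seq_len(noise$replicates),
                      temperature_K = temperatures)
  base <- data.frame(
    temperature_K = rep(grid$temperature_K, each = 3L),
    replicate = rep(grid$replicate, each = 3L),
    species = rep(c("monomer", "dimer", "sp_tmao_complex"), nrow(grid)),
    intensity = as.vector(rbind(
      rep(monomer_intensity, nrow(grid)),
      i_dim[match(grid$temperature_K, temperatures)],
      i_cpx[match(grid$temperature_K, temperatures)]))
  )
  if (noise$cv > 0) {
    sdlog <- sqrt(log1p(noise$cv^2))
    fac <- with_seed(noise$seed,
                     stats::rlnorm(nrow(base), meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog))
    base$intensity <- base$intensity * fac
  }
  base <- base[order(base$temperature_K, base$replicate, base$species), ]
  rownames(base) <- NULL
  intensity_table(base)
}

#' One-dimensional potential specification
#'
#' Functional forms for the synthetic free-energy landscape along the
#' interchain centre-of-mass coordinate: `flat`, `harmonic` (one well),
#' `double_well` (quartic with two minima and a central barrier) or
#' `tabulated` (values on a grid, interpolated).
#'
#' @param form one of "flat", "harmonic", "double_well", "tabulated"
#' @param domain c(min, max) coordinate bounds, nm
#' @param center harmonic well position, nm
#' @param stiffness harmonic stiffness, kJ/mol/nm^2
#' @param wells positions of the two minima of the double well, nm
#' @param barrier_height central barrier height above the minima, kJ/mol
#' @param x,U grids for the tabulated form (U in kJ/mol)
#' @export
potential_spec <- function(form = c("flat", "harmonic", "double_well",
                                    "tabulated"),
                           domain = c(0, 4),
                           center = mean(domain), stiffness = 100,
                           wells = c(1, 3), barrier_height = 5,
                           x = NULL, U = NULL) {
  form <- match.arg(form)
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  if (form == "tabulated") {
    stopifnot(!is.null(x), !is.null(U), length(x) == length(U),
              all(is.finite(U)))
  }
  if (form == "double_well") stopifnot(length(wells) == 2, wells[1] < wells[2],
                                       barrier_height >= 0)
  structure(list(form = form, domain = domain, center = center,
                 stiffness = stiffness, wells = sort(wells),
                 barrier_height = barrier_height, x = x, U = U),
            class = "potential_spec")
}

#' Evaluate a potential on coordinates
#'
#' @param potential a [potential_spec()]
#' @param x coordinates, nm
#' @return potential energy, kJ/mol
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "potential_spec"))
  switch(potential$form,
    flat = rep(0, length(x)),
    harmonic = 0.5 * potential$stiffness * (x - potential$center)^2,
    double_well = {
      c0 <- mean(potential$wells)
      w <- diff(potential$wells) / 2
      potential$barrier_height * (((x - c0) / w)^2 - 1)^2
    },
    tabulated = stats::approx(potential$x, potential$U, xout = x,
                              rule = 2)$y
  )
}

#' Overdamped Langevin trajectory on a one-dimensional potential
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' dx = -(D / kB T) U'(x) dt + sqrt(2 D dt) xi, with reflecting
#' boundaries at the domain bounds (the centre-of-mass distance is
#' non-negative and bounded by the box, so reflection rather than
#' wrapping is the physical choice). The long-time stationary law is
#' Boltzmann, p(x) proportional to exp(-U(x)/RT), which is what the
#' free-energy-profile estimator downstream inverts. Forces are
#' pre-tabulated on a fine grid and looked up per step, keeping the R
#' loop cheap.
#'
#' @param potential a [potential_spec()]
#' @param temperature temperature, K
#' @param dt time step, ns
#' @param n_steps number of stored steps
#' @param diffusion_coefficient D, nm^2/ns
#' @param seed integer RNG seed
#' @param x0 initial coordinate, nm (default: domain midpoint)
#' @return a [com_trajectory()]
#' @export
generate_langevin_com_trajectory <- function(potential, temperature = 300,
                                             dt = 0.01, n_steps = 1e5,
                                             diffusion_coefficient = 1,
                                             seed = 1, x0 = NULL) {
  stopifnot(inherits(potential, "potential_spec"), dt > 0, n_steps >= 1,
            diffusion_coefficient > 0, temperature > 0)
  lo <- potential$domain[1]; hi <- potential$domain[2]
  RT <- peptherm_constants$R_kJ * temperature
  ngrid <- 4096L
  xg <- seq(lo, hi, length.out = ngrid)
  Ug <- potential_energy(potential, xg)
  if (any(!is.finite(Ug))) stop("potential is not finite on its domain")
  # centred finite-difference force on the grid, kJ/mol/nm
  Fg <- -c(diff(Ug[1:2]), diff(Ug, lag = 2) / 2, diff(Ug[(ngrid - 1):ngrid])) /
    (xg[2] - xg[1])
  mob <- diffusion_coefficient * dt / RT
  max_drift <- max(abs(Fg)) * mob
  if (max_drift > 0.1 * (hi - lo))
    warning("dt too large: per-step drift exceeds 10% of the domain")
  sig <- sqrt(2 * diffusion_coefficient * dt)
  if (is.null(x0)) x0 <- (lo + hi) / 2
  stopifnot(x0 >= lo, x0 <= hi)
  scale <- (ngrid - 1L) / (hi - lo)
  x <- with_seed(seed, {
    xi <- stats::rnorm(n_steps, sd = sig)
    out <- numeric(n_steps)
    xc <- x0
    width2 <- 2 * (hi - lo)
    for (i in seq_len(n_steps)) {
      idx <- floor((xc - lo) * scale + 0.5) + 1
      xc <- xc + mob * Fg[idx] + xi[i]
      # reflecting boundaries (handles multiple bounces)
      y <- (xc - lo) %% width2
      xc <- lo + ifelse(y > (hi - lo), width2 - y, y)
      out[i] <- xc
    }
    out
  })
  com_trajectory(times = seq_len(n_steps) * dt, distances = x,
                 temperature = temperature,
                 box_edge = NULL, frame_interval = dt)
}

#' Construct a donor-hydrogen-acceptor micro-geometry
#'
#' Places a donor at the origin, its hydrogen 0.1 nm along +x, and an
#' acceptor such that the donor-acceptor distance and the deviation of
#' the D-H-A angle from linearity match the request exactly. Used as a
#' fixture for the geometric hydrogen-bond counter.
#'
#' @param donor_acceptor_distance D-A distance, nm
#' @param donor_hydrogen_acceptor_angle deviation of the D-H-A angle
#'   from linear, degrees (0 = perfectly linear bond)
#' @param dh_bond donor-hydrogen covalent bond length, nm
#' @return a `coordinate_frame` with rows donor, hydrogen, acceptor
#' @export
generate_hbond_geometry <- function(donor_acceptor_distance,
                                    donor_hydrogen_acceptor_angle,
                                    dh_bond = 0.1) {
  r <- donor_acceptor_distance
  th <- donor_hydrogen_acceptor_angle
  stopifnot(r > 0, th >= 0, th <= 180, dh_bond > 0)
  d <- dh_bond
  tr <- th * pi / 180
  disc <- d^2 * cos(tr)^2 - d^2 + r^2
  if (disc < 0)
    stop("geometrically impossible: acceptor cannot realize the ",
         "requested distance/angle with a ", d, " nm D-H bond")
  t <- -d * cos(tr) + sqrt(disc)
  if (t <= 0)
    stop("geometrically impossible: requested D-A distance shorter than ",
         "the D-H bond allows at this angle")
  donor <- c(0, 0, 0)
  hydrogen <- c(d, 0, 0)
  acceptor <- hydrogen + t * c(cos(tr), sin(tr), 0)
  coords <- rbind(donor = donor, hydrogen = hydrogen, acceptor = acceptor)
  colnames(coords) <- c("x", "y", "z")
  coordinate_frame(coords, box_edge = NULL)
}

#' Ideal-gas coordinate frames in a periodic cube
#'
#' Uniform, uncorrelated particle positions: the null model for which
#' the radial distribution function is exactly 1 at all separations.
#'
#' @param n_particles particles per frame, >= 2
#' @param box_edge cubic box edge, nm
#' @param n_frames number of independent frames
#' @param seed integer RNG seed
#' @return a `coordinate_frame_set`
#' @export
generate_ideal_gas_coordinates <- function(n_particles, box_edge,
                                           n_frames = 1, seed = 1) {
  stopifnot(n_particles >= 2, box_edge > 0, n_frames >= 1)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    m <- matrix(stats::runif(3 * n_particles, 0, box_edge),
                ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
    coordinate_frame(m, box_edge = box_edge)
  }))
  coordinate_frame_set(frames, box_edge = box_edge)
}

#' Synthetic centroid-free peak list with Gaussian peaks
#'
#' Profile-mode peak list sampled on a regular m/z grid: one Gaussian
#' per species, centred at its theoretical m/z, with integrated area
#' proportional to its abundance, plus an additive uniform noise floor.
#' Species closer together than fwhm/2 are reported in a warning since
#' nearest-peak assignment cannot fully separate them.
#'
#' @param species data.frame with columns sequence, oligomer_order,
#'   charge, abundance and optionally c_terminal_amide (default TRUE)
#'   and adduct_mass (default 0)
#' @param peak_fwhm full width at half maximum of each peak, m/z units
#' @param mz_range c(min, max) of the sampled grid; default covers all
#'   species with a 5-fwhm margin
#' @param mz_step grid spacing; default fwhm/10
#' @param noise_floor maximum of the additive uniform noise, counts
#' @param seed integer RNG seed
#' @return a `peak_list` data.frame (mz, intensity)
#' @export
generate_peak_list <- function(species, peak_fwhm = 0.5, mz_range = NULL,
                               mz_step = peak_fwhm / 10, noise_floor = 0,
                               seed = 1) {
  stopifnot(is.data.frame(species), peak_fwhm > 0, noise_floor >= 0,
            all(species$abundance >= 0))
  if (is.null(species$c_terminal_amide)) species$c_terminal_amide <- TRUE
  if (is.null(species$adduct_mass)) species$adduct_mass <- 0
  mz0 <- mapply(theoretical_mz, species$sequence, species$oligomer_order,
                species$charge, species$c_terminal_amide,
                species$adduct_mass)
  if (is.null(mz_range))
    mz_range <- range(mz0) + c(-5, 5) * peak_fwhm
  live <- mz0[species$abundance > 0]
  if (length(live) > 1) {
    gaps <- diff(sort(live))
    if (any(gaps < peak_fwhm / 2))
      warning(sum(gaps < peak_fwhm / 2),
              " species pair(s) closer than fwhm/2: peaks overlap")
  }
  grid <- seq(mz_range[1], mz_range[2], by = mz_step)
  sigma <- peak_fwhm / (2 * sqrt(2 * log(2)))
  intensity <- rep(0, length(grid))
  for (i in seq_along(mz0)) {
    if (species$abundance[i] <= 0) next
    intensity <- intensity + species$abundance[i] *
      stats::dnorm(grid, mean = mz0[i], sd = sigma)
  }
  if (noise_floor > 0)
    intensity <- intensity +
      with_seed(seed, stats::runif(length(grid), 0, noise_floor))
  peak_list(data.frame(mz = grid, intensity = intensity))
}
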