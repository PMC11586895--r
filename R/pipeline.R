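#' Validate a pipeline configuration
#'
#' Checks a YAML configuration (or an already-parsed list) against the
#' pipeline schema and collects every problem rather than stopping at
#' the first. Scenarios: `vtesi_thermo` (intensity generation + van't
#' Hoff analysis), `trajectory` (Langevin trajectory + state/FEP
#' analysis), `census` (peak-list generation + oligomer census) and
#' `full` (all three).
#'
#' @param config path to a YAML file, or a list
#' @return a list with elements `valid` (logical), `errors` (character
#'   vector, empty when valid) and `config` (the parsed list)
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e)
                         stop("unparseable config file: ",
                              conditionMessage(e)))
  }
  errors <- character()
  scenarios <- c("vtesi_thermo", "trajectory", "census", "full")
  if (is.null(config$scenario)) {
    errors <- c(errors, "missing field: scenario")
  } else if (!config$scenario %in% scenarios) {
    errors <- c(errors, paste0("unknown scenario '", config$scenario,
                               "'; allowed: ",
                               paste(scenarios, collapse = ", ")))
  }
  if (is.null(config$seed)) errors <- c(errors, "missing field: seed")
  wants <- function(block)
    !is.null(config$scenario) &&
      config$scenario %in% c(block, "full")
  if (wants("vtesi_thermo")) {
    v <- config$vtesi
    if (is.null(v)) errors <- c(errors, "missing block: vtesi")
    else {
      if (is.null(v$thermo)) errors <- c(errors, "missing field: vtesi.thermo")
      if (is.null(v$temperatures))
        errors <- c(errors, "missing field: vtesi.temperatures")
    }
  }
  if (wants("trajectory")) {
    tr <- config$trajectory
    if (is.null(tr)) errors <- c(errors, "missing block: trajectory")
    else {
      if (is.null(tr$temperature))
        errors <- c(errors, "missing field: trajectory.temperature")
      if (is.null(tr$potential))
        errors <- c(errors, "missing field: trajectory.potential")
    }
  }
  if (wants("census")) {
    cs <- config$census
    if (is.null(cs)) errors <- c(errors, "missing block: census")
    else if (is.null(cs$species))
      errors <- c(errors, "missing field: census.species")
  }
  list(valid = length(errors) == 0, errors = errors, config = config)
}

.expand_temperatures <- function(spec) {
  if (is.list(spec)) seq(spec$from, spec$to, by = spec$by)
  else as.numeric(spec)
}

.potential_from_config <- function(p) {
  do.call(potential_spec, p)
}

#' Run an end-to-end pipeline scenario
#'
#' Executes the stages requested by the configuration in dependency
#' order (simulate, then analyze), writes every intermediate table as
#' CSV into the output directory alongside a resolved copy of the
#' configuration, and aggregates the headline quantities (per-regime
#' dH / -TdS / dG, state occupancies, FEP barrier, degree of
#' oligomerization) into `summary.json`. Every output records the seed
#' and the MD5 hash of the resolved configuration, and a rerun with the
#' same configuration and seed is bit-reproducible.
#'
#' @param config path to a YAML configuration, or a list
#' @param seed optional override of the configured seed
#' @param out_dir optional override of the configured output directory
#' @return the summary list, invisibly; side effect: files in `out_dir`
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  val <- validate_config(config)
  if (!val$valid)
    stop("invalid configuration:\n  ",
         paste(val$errors, collapse = "\n  "))
  cfg <- val$config
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$output_dir <- out_dir
  if (is.null(cfg$output_dir)) cfg$output_dir <- "peptherm_out"
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- file.path(cfg$output_dir, "resolved_config.yaml")
  yaml::write_yaml(cfg, resolved)
  # hash the scientific content only: the output path must not change
  # the provenance fingerprint
  hashable <- cfg
  hashable$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hashable, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  seed0 <- as.integer(cfg$seed)
  summary <- list(scenario = cfg$scenario, seed = seed0,
                  config_hash = cfg_hash)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (cfg$scenario %in% c("vtesi_thermo", "full")) {
    summary$vtesi <- run_stage("vtesi_thermo", function() {
      v <- cfg$vtesi
      thermo <- do.call(two_regime_thermo, v$thermo)
      noise <- do.call(noise_spec, c(v$noise %||% list(cv = 0,
                                                       replicates = 1),
                                     list()))
      noise$seed <- seed0 + 101L
      tab <- generate_vant_hoff_intensities(
        thermo, .expand_temperatures(v$temperatures),
        monomer_intensity = v$monomer_intensity %||% 1000,
        tmao_concentration = v$tmao_concentration %||% 5e-4,
        noise = noise)
      write_intensity_csv(tab, file.path(cfg$output_dir,
                                         "intensity_table.csv"))
      reaction <- v$reaction %||% "dimerization"
      series <- build_vant_hoff_series(
        tab, reaction,
        tmao_concentration = v$tmao_concentration %||% 5e-4)
      bp <- v$breakpoint %||% "auto"
      fit <- fit_two_regime(series, if (identical(bp, "auto")) "auto"
                            else as.numeric(bp))
      tref <- v$reference_temperature %||% 293
      write_thermo_csv(fit, file.path(cfg$output_dir, "thermo_report.csv"),
                       reference_temperature = tref, reaction = reaction)
      lo <- thermo_from_fit(fit$low_regime, tref)
      hi <- thermo_from_fit(fit$high_regime, tref)
      list(reaction = reaction, breakpoint_K = fit$breakpoint,
           degenerate = fit$degenerate_flag,
           low = list(dH_kJmol = lo$dH, mTdS_kJmol = lo$mTdS_at_ref,
                      dG_kJmol = lo$dG_at_ref),
           high = list(dH_kJmol = hi$dH, mTdS_kJmol = hi$mTdS_at_ref,
                       dG_kJmol = hi$dG_at_ref),
           reference_temperature_K = tref)
    })
  }

  if (cfg$scenario %in% c("trajectory", "full")) {
    summary$trajectory <- run_stage("trajectory", function() {
      tr <- cfg$trajectory
      pot <- .potential_from_config(tr$potential)
      traj <- generate_langevin_com_trajectory(
        pot, temperature = tr$temperature,
        dt = tr$dt %||% 0.01, n_steps = tr$n_steps %||% 1e5,
        diffusion_coefficient = tr$diffusion_coefficient %||% 1,
        seed = seed0 + 202L)
      write_com_csv(traj, file.path(cfg$output_dir, "com_trajectory.csv"))
      labels <- classify_states(traj,
                                tr$dimer_threshold %||% 2.0,
                                tr$monomer_threshold %||% 3.5)
      occ <- state_occupancy(labels)
      utils::write.csv(data.frame(state = names(occ), probability = occ),
                       file.path(cfg$output_dir, "state_occupancy.csv"),
                       row.names = FALSE)
      fep <- bootstrap_fep(normalize_coordinate(traj),
                           temperature = tr$temperature,
                           n_bins = tr$n_bins %||% 50,
                           min_count = tr$min_count %||% 10,
                           n_boot = tr$n_boot %||% 50,
                           block_length = tr$block_length %||% 100,
                           seed = seed0 + 203L)
      write_fep_csv(fep, file.path(cfg$output_dir, "fep.csv"))
      list(occupancy = as.list(occ),
           fep_barrier_kJmol = fep_barrier(fep),
           temperature_K = tr$temperature)
    })
  }

  if (cfg$scenario %in% c("census", "full")) {
    summary$census <- run_stage("census", function() {
      cs <- cfg$census
      species <- do.call(rbind, lapply(cs$species, as.data.frame))
      peaks <- generate_peak_list(species,
                                  peak_fwhm = cs$peak_fwhm %||% 0.5,
                                  noise_floor = cs$noise_floor %||% 0,
                                  seed = seed0 + 303L)
      write_peak_csv(peaks, file.path(cfg$output_dir, "peaks.csv"))
      asg <- assign_peaks(peaks, species_table(species),
                          tolerance = cs$tolerance %||% 0.5)
      ab <- oligomer_abundances(asg, max_order = cs$max_order %||% 3)
      utils::write.csv(
        data.frame(order = seq_along(ab$per_order),
                   intensity = ab$per_order),
        file.path(cfg$output_dir, "oligomer_abundances.csv"),
        row.names = FALSE)
      list(degree_of_oligomerization = ab$degree_of_oligomerization,
           per_order = as.list(ab$per_order),
           unassigned_fraction = ab$unassigned_fraction)
    })
  }

  jsonlite::write_json(summary,
                       file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Barrier height of a free-energy profile
#'
#' Height of the highest free energy encountered between the two
#' deepest local minima of the profile, measured above the shallower of
#' the two minima; NA when fewer than two local minima exist.
#'
#' @param fep a `free_energy_profile`
#' @return barrier height, kJ/mol
#' @export
fep_barrier <- function(fep) {
  f <- fep$free_energy
  ok <- which(!is.na(f))
  if (length(ok) < 3) return(NA_real_)
  v <- f[ok]
  n <- length(v)
  is_min <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) v[i - 1] else Inf
    right <- if (i < n) v[i + 1] else Inf
    v[i] <= left && v[i] <= right && (v[i] < left || v[i] < right)
  }, logical(1))
  mins <- which(is_min)
  if (length(mins) < 2) return(NA_real_)
  deepest <- mins[order(v[mins])][1:2]
  span <- seq(min(deepest), max(deepest))
  max(v[span]) - max(v[deepest])
}
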