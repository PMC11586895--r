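# shared fixtures, built in code at test time

R_KJ <- peptherm_constants$R_kJ

# hand-built van't Hoff series (bypasses the intensity path)
make_series <- function(inverse_temperature, ln_ka) {
  out <- data.frame(
    temperature_K = 1 / inverse_temperature,
    inverse_temperature = inverse_temperature,
    ln_ka = ln_ka, ln_ka_sd = NA_real_, n_replicates = 1L)
  out <- out[order(out$inverse_temperature), ]
  class(out) <- c("vant_hoff_series", "data.frame")
  out
}

# the two published dimerization regimes with their 293 K breakpoint
paper_thermo <- function() {
  two_regime_thermo(breakpoint_temperature = 293,
                    dH_low = -26.4, dH_high = -71.1,
                    mTdS_ref_high = 53.6,
                    reference_temperature_high = 293,
                    mTdS_ref_low = 8.8)
}

noiseless <- function(replicates = 1) noise_spec(replicates, cv = 0, seed = 1)

# iid rejection sampler from exp(-U/RT) on a tabulated potential:
# the independent oracle for the Boltzmann-inversion estimator
sample_boltzmann <- function(potential, temperature, n, seed) {
  RT <- R_KJ * temperature
  lo <- potential$domain[1]; hi <- potential$domain[2]
  withr::with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- runif(2 * n, lo, hi)
      u <- runif(2 * n)
      keep <- u < exp(-potential_energy(potential, x) / RT)
      out <- c(out, x[keep])
    }
    out[seq_len(n)]
  })
}

# measured D-A distance and D-H-A deviation of a 3-atom frame
hb_roundtrip <- function(frame) {
  co <- frame$coords
  d <- co[1, ]; h <- co[2, ]; a <- co[3, ]
  v1 <- d - h; v2 <- a - h
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  c(distance = sqrt(sum((a - d)^2)), deviation = 180 - ang)
}

minimal_species <- function() {
  data.frame(sequence = "RPKPQQFFGLM",
             oligomer_order = c(1, 2, 3),
             charge = c(2, 2, 4), # distinct m/z: 674.4, 1347.7, 1011.3
             abundance = c(100, 50, 10))
}
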