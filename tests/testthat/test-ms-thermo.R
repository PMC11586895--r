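test_that("apparent Ka formulas match hand arithmetic", {
  expect_equal(compute_ka_dimer(100, 1000), 1e-4)
  expect_equal(compute_ka_dimer(0, 500), 0)
  expect_equal(compute_ka_dimer(50, 50), 0.02) # 50/2500
  expect_error(compute_ka_dimer(10, 0), "positive")
  expect_error(compute_ka_dimer(-1, 10), "non-negative")

  expect_equal(compute_ka_complex(10, 100, 5e-4), 200)
  expect_equal(compute_ka_complex(0, 100, 1), 0)
  expect_equal(compute_ka_complex(5, 5, 1), 1)
  expect_error(compute_ka_complex(1, 0, 1), "positive")
  expect_error(compute_ka_complex(1, 1, 0), "positive")
})

test_that("van't Hoff series: averaging, sds, dropout", {
  th <- single_regime_thermo(dH = -50, mTdS_ref = 40)
  tab <- generate_vant_hoff_intensities(th, seq(298, 338, 10),
                                        noise = noiseless(1))
  s <- build_vant_hoff_series(tab, "dimerization")
  # noiseless single regime: points exactly collinear in 1/T
  fitted <- lm(ln_ka ~ inverse_temperature, data = s)
  expect_lt(max(abs(resid(fitted))), 1e-10)
  expect_true(all(is.na(s$ln_ka_sd))) # n = 1, no sds
  expect_false(is.unsorted(s$inverse_temperature))

  tab3 <- generate_vant_hoff_intensities(th, seq(298, 338, 10),
                                         noise = noise_spec(3, 0.05, 7))
  s3 <- build_vant_hoff_series(tab3, "dimerization")
  expect_true(all(s3$n_replicates == 3))
  expect_true(all(is.finite(s3$ln_ka_sd)))

  # zero product intensity at one temperature in all replicates:
  # that temperature is excluded, with a message
  tab0 <- as.data.frame(tab)
  tab0$intensity[tab0$temperature_K == 318 & tab0$species == "dimer"] <- 0
  expect_message(s0 <- build_vant_hoff_series(intensity_table(tab0),
                                              "dimerization"),
                 "dropped")
  expect_false(318 %in% s0$temperature_K)
  expect_identical(attr(s0, "dropped"), 1L)

  # tmao_binding requires the concentration
  expect_error(build_vant_hoff_series(tab, "tmao_binding"), "required")
})

test_that("single-regime OLS fit recovers slopes", {
  s <- make_series(c(0.0030, 0.0035), c(0, 1))
  f <- fit_single_regime(s)
  expect_equal(f$slope, 2000) # two-point slope
  expect_equal(f$slope_sd, 0) # exact two-point fit

  # collinear points with known slope are recovered exactly
  invT <- 1 / seq(280, 350, 10)
  f2 <- fit_single_regime(make_series(invT, 5000 * invT + 3))
  expect_equal(f2$slope, 5000, tolerance = 1e-9)
  expect_equal(f2$intercept, 3, tolerance = 1e-9)

  # constant ln Ka: flat line
  f3 <- fit_single_regime(make_series(invT, rep(2, length(invT))))
  expect_equal(f3$slope, 0, tolerance = 1e-9)

  expect_error(fit_single_regime(make_series(c(1 / 300, 1 / 300), c(1, 2))),
               "singular|2 points")
})

test_that("two-regime fit recovers breakpoint and enthalpies", {
  th <- paper_thermo()
  tab <- generate_vant_hoff_intensities(th, seq(278, 358, 5),
                                        noise = noiseless(1))
  s <- build_vant_hoff_series(tab, "dimerization")
  fit <- fit_two_regime(s)
  expect_equal(fit$breakpoint, 293)
  expect_false(fit$degenerate_flag)
  expect_equal(thermo_from_fit(fit$low_regime)$dH, -26.4,
               tolerance = 0.1 / 26.4)
  expect_equal(thermo_from_fit(fit$high_regime)$dH, -71.1,
               tolerance = 1e-6)

  # single-regime data: degenerate flag raised
  tab1 <- generate_vant_hoff_intensities(
    single_regime_thermo(-50, 40), seq(278, 358, 5), noise = noiseless(1))
  fit1 <- fit_two_regime(build_vant_hoff_series(tab1, "dimerization"))
  expect_true(fit1$degenerate_flag)

  # fixed breakpoint mode
  fitb <- fit_two_regime(s, 293)
  expect_equal(fitb$breakpoint, 293)
  expect_error(fit_two_regime(s, 279), "no admissible breakpoint")
})

test_that("two-regime RSS never exceeds single-regime RSS", {
  for (seed in 1:5) {
    tab <- generate_vant_hoff_intensities(
      paper_thermo(), seq(278, 358, 5),
      noise = noise_spec(3, 0.05, seed))
    s <- build_vant_hoff_series(tab, "dimerization")
    expect_lte(fit_two_regime(s)$rss, fit_single_regime(s)$rss)
  }
})

test_that("thermo_from_fit derives dH, dS, -TdS, dG consistently", {
  # slope/intercept chosen to give the published high-regime pair
  R <- R_KJ
  f <- structure(list(slope = 71.1 / R, intercept = -53.6 / (293 * R),
                      slope_sd = 10, intercept_sd = 0.1,
                      temperature_range = c(298, 358)),
                 class = "regime_fit")
  tq <- thermo_from_fit(f, 293)
  expect_equal(tq$dH, -71.1)
  expect_equal(tq$mTdS_at_ref, 53.6)
  expect_equal(tq$dG_at_ref, -17.5)
  # identity holds to machine precision
  expect_identical(tq$dG_at_ref, tq$dH + tq$mTdS_at_ref)
  expect_equal(tq$mTdS_at_ref, -293 * tq$dS)
  # propagated sds
  expect_equal(tq$dH_sd, R * 10)
  expect_equal(tq$mTdS_sd, 293 * R * 0.1)

  null <- structure(list(slope = 0, intercept = 0, slope_sd = 0,
                         intercept_sd = 0, temperature_range = c(280, 360)),
                    class = "regime_fit")
  tq0 <- thermo_from_fit(null, 293)
  expect_equal(unlist(tq0[c("dH", "dS", "mTdS_at_ref", "dG_at_ref")]),
               c(dH = 0, dS = 0, mTdS_at_ref = 0, dG_at_ref = 0))

  # slope 0, intercept 1: dG = -R*T*ln K with ln K = 1
  unit <- structure(list(slope = 0, intercept = 1, slope_sd = 0,
                         intercept_sd = 0, temperature_range = c(280, 360)),
                    class = "regime_fit")
  expect_equal(thermo_from_fit(unit, 293)$dG_at_ref, -R_KJ * 293,
               tolerance = 1e-9)
  expect_equal(thermo_from_fit(unit, 293)$dG_at_ref, -2.436,
               tolerance = 2e-4)
})

test_that("replicate_uncertainty is a sample sd, order-invariant", {
  mk <- function(dH) structure(
    list(slope = -dH / R_KJ, intercept = 0, slope_sd = 0, intercept_sd = 0,
         temperature_range = c(280, 360)), class = "regime_fit")
  fits <- list(mk(-70), mk(-72))
  u <- replicate_uncertainty(fits)
  expect_equal(unname(u["dH"]), sqrt(2), tolerance = 1e-9)
  expect_equal(replicate_uncertainty(rev(fits)), u)
  expect_equal(unname(replicate_uncertainty(list(mk(-70), mk(-70)))["dH"]), 0)
  expect_error(replicate_uncertainty(list(mk(-70))), ">= 2")
})

test_that("noiseless round trip recovers dH and -TdS to 6 sig figs", {
  for (pars in list(c(-71.1, 53.6), c(-26.4, 8.8), c(-10, -5))) {
    th <- single_regime_thermo(pars[1], pars[2], 293)
    tab <- generate_vant_hoff_intensities(th, seq(278, 358, 5),
                                          noise = noiseless(1))
    tq <- thermo_from_fit(
      fit_single_regime(build_vant_hoff_series(tab, "dimerization")), 293)
    expect_equal(tq$dH, pars[1], tolerance = 1e-7)
    expect_equal(tq$mTdS_at_ref, pars[2], tolerance = 1e-7)
  }
})

test_that("noisy recovery: median |dH error| below 5 kJ/mol over 100 seeds", {
  th <- single_regime_thermo(-71.1, 53.6, 293)
  errs <- vapply(1:100, function(seed) {
    tab <- generate_vant_hoff_intensities(th, seq(298, 358, 5),
                                          noise = noise_spec(3, 0.05, seed))
    f <- fit_single_regime(build_vant_hoff_series(tab, "dimerization"))
    abs(thermo_from_fit(f)$dH - (-71.1))
  }, numeric(1))
  expect_lt(median(errs), 5)
})

test_that("within a regime with dH < 0, fitted Ka decreases with T", {
  th <- single_regime_thermo(-40, 20, 293)
  tab <- generate_vant_hoff_intensities(th, seq(280, 360, 10),
                                        noise = noiseless(1))
  s <- build_vant_hoff_series(tab, "dimerization")
  f <- fit_single_regime(s)
  temps <- seq(280, 360, 1)
  ka_hat <- exp(f$slope / temps + f$intercept)
  expect_true(all(diff(ka_hat) < 0))
})
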