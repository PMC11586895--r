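test_that("COM distance honors masses and the minimum image", {
  fr <- coordinate_frame(rbind(c(0, 0, 0), c(2, 0, 0)), box_edge = 8)
  fs <- coordinate_frame_set(list(fr), box_edge = 8)
  traj <- com_distance_series(fs, 1, 2)
  expect_equal(traj$distances, 2.0)

  # wrapped pair: 0.5 and 7.5 along x in an 8 nm box are 1 nm apart
  frw <- coordinate_frame(rbind(c(0.5, 0, 0), c(7.5, 0, 0)), box_edge = 8)
  expect_equal(com_distance_series(coordinate_frame_set(list(frw), 8),
                                   1, 2)$distances, 1.0)

  # identical chains coincide
  fr2 <- coordinate_frame(rbind(c(1, 1, 1), c(3, 2, 1)), box_edge = 8)
  expect_equal(com_distance_series(coordinate_frame_set(list(fr2), 8),
                                   c(1, 2), c(1, 2))$distances, 0)

  # mass weighting: COM of (0 with m=3, 4 with m=1) is at 1
  fr3 <- coordinate_frame(rbind(c(0, 0, 0), c(4, 0, 0), c(6, 0, 0)),
                          box_edge = 20)
  traj3 <- com_distance_series(coordinate_frame_set(list(fr3), 20),
                               c(1, 2), 3, masses_a = c(3, 1))
  expect_equal(traj3$distances, 5)
})

test_that("state classification uses strict thresholds", {
  d <- c(1.9, 2.0, 2.7, 3.5, 3.6)
  lab <- classify_states(com_trajectory(1:5, d, 300))
  expect_equal(as.character(lab$labels),
               c("dimer", "transition", "transition", "transition",
                 "monomer"))
  expect_error(classify_states(d, 3.5, 2.0), "below")
})

test_that("state occupancy is a normalized frame count", {
  lab <- classify_states(c(rep(1, 500), rep(2.5, 1500)))
  occ <- state_occupancy(lab)
  expect_identical(unname(occ["dimer"]), 0.25)
  expect_equal(sum(occ), 1)

  occ2 <- state_occupancy(classify_states(rep(4, 10)))
  expect_identical(unname(occ2["monomer"]), 1)

  d <- c(rep(1, 394), rep(2.5, 207), rep(4, 399))
  occ3 <- state_occupancy(classify_states(d))
  expect_equal(unname(occ3), c(0.394, 0.207, 0.399))
  expect_equal(sum(occ3), 1)
  expect_error(state_occupancy(classify_states(numeric(0))), "empty")
})

test_that("occupancies sum to 1 for arbitrary trajectories", {
  for (seed in 1:10) {
    d <- withr::with_seed(seed, runif(200, 0, 5))
    expect_equal(sum(state_occupancy(classify_states(d))), 1)
  }
})

test_that("coordinate normalization is a monotone min-max map", {
  expect_equal(normalize_coordinate(c(1, 2, 3)), c(0, 0.5, 1))
  d <- withr::with_seed(1, runif(100, 1, 4))
  z <- normalize_coordinate(d)
  expect_equal(order(z), order(d)) # order preserved
  # normalized < 0.3 iff distance < d_min + 0.3 * range
  thr <- min(d) + 0.3 * diff(range(d))
  expect_identical(z < 0.3, d < thr)
  # fixed-range option
  expect_equal(normalize_coordinate(c(1, 3), range = c(0, 4)),
               c(0.25, 0.75))
  expect_error(normalize_coordinate(rep(2, 5)), "constant")
})

test_that("free-energy profile: flat law, two-bin ratio, masking", {
  # uniform occupancy: all unmasked bins at 0
  x <- rep(seq(0.05, 0.95, 0.1), each = 50)
  fp <- free_energy_profile(x, 300, n_bins = 10, min_count = 10,
                            breaks = seq(0, 1, 0.1))
  expect_true(all(abs(fp$free_energy) < 1e-9))

  # closed-form Boltzmann ratio: P = 0.25 / 0.75 at 300 K
  x2 <- c(rep(0.25, 250), rep(0.75, 750))
  fp2 <- free_energy_profile(x2, 300, n_bins = 2, min_count = 1)
  expect_equal(max(fp2$free_energy), R_KJ * 300 * log(3),
               tolerance = 1e-9)
  expect_equal(min(fp2$free_energy), 0)

  # sparse bins are masked, and masked bins never enter the min
  x3 <- c(rep(0.1, 100), rep(0.9, 3))
  fp3 <- free_energy_profile(x3, 300, n_bins = 5, min_count = 10,
                             breaks = seq(0, 1, 0.2))
  expect_true(is.na(fp3$free_energy[5]))
  expect_equal(min(fp3$free_energy, na.rm = TRUE), 0)
  expect_error(free_energy_profile(x3, 300, min_count = 1e6), "min_count")
})

test_that("Boltzmann inversion recovers a tabulated potential (iid oracle)", {
  xg <- seq(0, 2, length.out = 201)
  pot <- potential_spec("tabulated", domain = c(0, 2), x = xg,
                        U = 3 * sin(2 * pi * xg) + 3)
  temp <- 320
  x <- sample_boltzmann(pot, temp, 6e4, seed = 21)
  fp <- free_energy_profile(x, temp, n_bins = 25, min_count = 200,
                            breaks = seq(0, 2, length.out = 26))
  U <- potential_energy(pot, fp$bin_center)
  ok <- !is.na(fp$free_energy)
  Uref <- U - min(U[ok])
  expect_lt(max(abs(fp$free_energy - Uref)[ok]), 0.5 * R_KJ * temp)
})

test_that("harmonic Boltzmann samples give a quadratic profile", {
  k <- 40; temp <- 300
  pot <- potential_spec("harmonic", domain = c(0, 4), center = 2,
                        stiffness = k)
  x <- sample_boltzmann(pot, temp, 5e4, seed = 31)
  fp <- free_energy_profile(x, temp, n_bins = 30, min_count = 200)
  ok <- !is.na(fp$free_energy)
  # fit curvature: F = 0.5 k (x - c)^2 + const
  q <- lm(fp$free_energy[ok] ~ I((fp$bin_center[ok] - 2)^2))
  expect_equal(unname(coef(q)[2]), k / 2, tolerance = 0.1)
})

test_that("state-level free energies follow the occupancy ratio", {
  occ <- c(dimer = 0.25, transition = 0.25, monomer = 0.5)
  f <- state_free_energy(occ, 300)
  expect_equal(unname(f["monomer"]), 0)
  expect_equal(unname(f["dimer"]), R_KJ * 300 * log(2), tolerance = 1e-9)
})

test_that("block bootstrap: zero variance, determinism, shrinkage", {
  # constant series: its single occupied bin has no variability
  x <- rep(0.25, 1000)
  bb <- bootstrap_fep(x, 300, n_bins = 2, min_count = 1, n_boot = 20,
                      block_length = 10, seed = 3,
                      breaks = c(0, 0.5, 1))
  expect_identical(bb$variance[1], 0)
  expect_true(is.na(bb$variance[2]))

  xr <- withr::with_seed(8, runif(500))
  b1 <- bootstrap_fep(xr, 300, n_bins = 5, min_count = 5,
                      n_boot = 10, block_length = 20, seed = 11)
  b2 <- bootstrap_fep(xr, 300, n_bins = 5, min_count = 5,
                      n_boot = 10, block_length = 20, seed = 11)
  expect_identical(b1$variance, b2$variance)

  # bands shrink when the series is 4x longer
  pot <- potential_spec("double_well", domain = c(0, 4), wells = c(1, 3),
                        barrier_height = 3)
  tr_s <- generate_langevin_com_trajectory(pot, 300, dt = 0.005,
                                           n_steps = 2e4, seed = 13)
  tr_l <- generate_langevin_com_trajectory(pot, 300, dt = 0.005,
                                           n_steps = 8e4, seed = 13)
  brk <- seq(0, 4, length.out = 21)
  bs <- bootstrap_fep(tr_s$distances, 300, min_count = 50, n_boot = 40,
                      block_length = 100, seed = 17, breaks = brk)
  bl <- bootstrap_fep(tr_l$distances, 300, min_count = 50, n_boot = 40,
                      block_length = 100, seed = 17, breaks = brk)
  both <- !is.na(bs$variance) & !is.na(bl$variance) & bs$variance > 0
  expect_lt(median(bl$variance[both] / bs$variance[both]), 1)

  expect_error(bootstrap_fep(runif(50), 300, block_length = 50), "below")
})

test_that("hydrogen-bond counting applies both criteria", {
  good <- generate_hbond_geometry(0.30, 10)
  expect_identical(count_hbonds(good, 1, 2, 3)$count, 1L)
  expect_identical(count_hbonds(generate_hbond_geometry(0.40, 10),
                                1, 2, 3)$count, 0L)
  expect_identical(count_hbonds(generate_hbond_geometry(0.30, 45),
                                1, 2, 3)$count, 0L)
  # custom criteria flip the verdicts
  loose <- hbond_criteria(max_da_distance = 0.45, max_deviation_angle = 60)
  expect_identical(count_hbonds(generate_hbond_geometry(0.40, 45),
                                1, 2, 3, loose)$count, 1L)
  # hydrogen must sit on its donor
  stray <- coordinate_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 0, 0)))
  expect_error(count_hbonds(stray, 1, 2, 3), "not bound")
  expect_error(hbond_criteria(max_deviation_angle = 120), "max_deviation")
})

test_that("RDF: delta pair, count conservation, normalization", {
  # two particles at fixed separation: one nonzero bin at r0
  fr <- coordinate_frame(rbind(c(1, 1, 1), c(2.2, 1, 1)), box_edge = 6)
  g <- rdf(coordinate_frame_set(list(fr), 6), 1, 2, bin_width = 0.1,
           r_max = 3)
  hot <- which(g$counts > 0)
  expect_length(hot, 1)
  expect_lt(abs(g$r[hot] - 1.2), 0.1)

  # doubling the bin width preserves the total pair count
  fs <- generate_ideal_gas_coordinates(64, 6, n_frames = 5, seed = 2)
  g1 <- rdf(fs, 1:64, 1:64, bin_width = 0.05, r_max = 3)
  g2 <- rdf(fs, 1:64, 1:64, bin_width = 0.10, r_max = 3)
  expect_identical(sum(g1$counts), sum(g2$counts))

  expect_error(rdf(fs, 1:64, 1:64, bin_width = 0.05, r_max = 4),
               "box_edge/2")
  expect_true(all(g1$g >= 0))
})

test_that("end-to-end: double-well occupancies match Boltzmann weights", {
  pot <- potential_spec("double_well", domain = c(0, 4), wells = c(1, 3),
                        barrier_height = 4)
  temp <- 300
  traj <- generate_langevin_com_trajectory(pot, temp, dt = 0.002,
                                           n_steps = 3e5, seed = 23)
  x <- traj$distances
  xg <- seq(0, 4, length.out = 8001)
  w <- exp(-potential_energy(pot, xg) / (R_KJ * temp))
  p_theory <- sum(w[xg < 2]) / sum(w)
  left <- x < 2
  blocks <- vapply(split(left, rep(1:20, each = length(left) / 20)),
                   mean, numeric(1))
  se <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(left) - p_theory), 3 * se)
})
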