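# Synthetic observers: latent space calibration, SDT behaviour, cohort and
# rating generation.

test_that("latent spans keep the 4:2:1 ratio and unit procrustes scale", {
  sp <- dissim_spans()
  expect_equal(unname(sp["spectral"] / sp["temporal"]), 4, tolerance = 1e-9)
  expect_equal(unname(sp["intensity"] / sp["temporal"]), 2, tolerance = 1e-9)
  # self-consistency: the ideal latent configuration aligns to the physical
  # reference with (near) unit scale, so recovered and generated
  # dissimilarities share units
  set15 <- make_stimulus_set(5)
  xyz <- latent_coords15(latent_space(), set15)
  pa <- procrustes_align(xyz, physical_reference(set15))
  expect_equal(pa$scale, 1, tolerance = 0.05)
})

test_that("ladder endpoints span the calibrated dissimilarities", {
  space <- latent_space()
  lads <- make_ladders()
  for (f in FEATURES) {
    expect_equal(true_dissimilarity(space, f, lads[[f]]$values[20]), 0,
                 tolerance = 1e-12)
    expect_equal(true_dissimilarity(space, f, lads[[f]]$values[1]),
                 unname(space$spans[f]), tolerance = 1e-9)
  }
  # dissimilarity decreases monotonically toward the target
  for (f in FEATURES)
    expect_true(all(diff(true_dissimilarity(space, f,
                                            lads[[f]]$values)) < 0))
})

test_that("observer profiles validate their parameters", {
  expect_error(observer_profile("X", msi = 60, dprime = flat_dprime(1)),
               "msi")
  expect_error(observer_profile("X", dprime = flat_dprime(1),
                                lapse_rate = 0.5), "lapse")
  bad <- flat_dprime(1)
  bad$temporal <- seq(0, 2, length.out = 20)  # increasing in difficulty
  expect_error(observer_profile("X", dprime = bad), "non-increasing")
})

test_that("simulated hit and false-alarm rates follow the SDT model", {
  prof <- observer_profile("T", dprime = flat_dprime(2), criterion = 0,
                           lapse_rate = 0)
  hits <- dev <- fa <- opp <- 0
  for (s in 1:15) {
    b <- simulate_block(prof, make_intensity_ladder(), "decreasing",
                        seed = 100 + s)
    cts <- b$counts
    hits <- hits + sum(cts$n_hits)
    dev <- dev + sum(cts$n_deviants)
    fa <- fa + sum(cts$n_fa)
    opp <- opp + sum(cts$n_cycles - cts$n_deviants)
  }
  p_hit <- stats::pnorm(1)   # d'/2 - c = 1
  p_fa <- stats::pnorm(-1)   # -d'/2 - c = -1
  expect_lt(abs(hits / dev - p_hit), 3 * sqrt(p_hit * (1 - p_hit) / dev))
  expect_lt(abs(fa / opp - p_fa), 3 * sqrt(p_fa * (1 - p_fa) / opp))
})

test_that("a fully lapsed observer never hits and stops early", {
  prof <- observer_profile("T", dprime = flat_dprime(3), criterion = 0,
                           lapse_rate = 1)
  b <- simulate_block(prof, make_log_ladder("spectral"), "increasing",
                      seed = 2)
  expect_equal(sum(b$counts$n_hits), 0)
  expect_equal(b$termination_reason, "no_hits_three_levels")
  expect_lte(max(b$counts$difficulty), 3)
})

test_that("event materialization leaves the outcome stream unchanged", {
  dp <- stats::setNames(rep(list(seq(3, 0.2, length.out = 20)), 3), FEATURES)
  prof <- observer_profile("T", dprime = dp)
  b1 <- simulate_block(prof, make_log_ladder("temporal"), "increasing",
                       seed = 11)
  b2 <- simulate_block(prof, make_log_ladder("temporal"), "increasing",
                       seed = 11, events = TRUE)
  expect_equal(b2$counts, b1$counts)
  expect_equal(b2$termination_reason, b1$termination_reason)
  # the materialized sequence matches the per-cycle stream
  expect_equal(nrow(b2$events), 8 * b1$n_cycles)
  expect_equal(sum(b2$scored_counts$n_deviants), sum(b1$counts$n_deviants))
})

test_that("true d' maps add covariate effects on top of dissimilarity", {
  spec <- effect_spec(msi_slope = 0.05,
                      age_offsets = c(intensity = -0.3, spectral = 0,
                                      temporal = 0),
                      pta_slope = -0.01, beta_dissim = 1.33)
  base <- true_dprime_map(28, 10, "younger", 0, spec)
  shifted <- true_dprime_map(38, 10, "younger", 0, spec)
  expect_equal(shifted$spectral - base$spectral, rep(0.5, 20))
  older <- true_dprime_map(28, 10, "older", 0, spec)
  expect_equal(older$intensity - base$intensity, rep(-0.3, 20))
  expect_equal(older$temporal, base$temporal)
  # difficulty 20 at reference covariates is exactly 0
  expect_equal(base$intensity[20], 0, tolerance = 1e-12)
  expect_equal(base$intensity[1],
               1.33 * unname(latent_space()$spans["intensity"]),
               tolerance = 1e-9)
})

test_that("cohorts match the demographic targets on average", {
  cells <- c(younger_musician = 14, younger_nonmusician = 14,
             older_musician = 12, older_nonmusician = 13)
  targets <- c(younger_musician = 38.9, younger_nonmusician = 12.9,
               older_musician = 35.9, older_nonmusician = 14.8)
  sums <- stats::setNames(numeric(4), names(cells))
  for (s in 1:4) {
    co <- simulate_cohort(400 + s)
    expect_equal(nrow(co$profiles), 53)
    expect_true(all(vapply(co$blocks, length, 0L) == 6))
    expect_true(all(co$profiles$msi >= 7 & co$profiles$msi <= 49))
    # musicians sit above the musician boundary, non-musicians below
    expect_true(all(co$profiles$msi[grepl("_musician",
                                          co$profiles$cell)] >= 25))
    expect_true(all(co$profiles$msi[grepl("nonmusician",
                                          co$profiles$cell)] <= 25))
    m <- tapply(co$profiles$msi, co$profiles$cell, mean)
    sums <- sums + m[names(cells)]
  }
  expect_true(all(abs(sums / 4 - targets) < 2.5))
})

test_that("cohort simulation is deterministic in the seed", {
  a <- simulate_cohort(31, n_per_cell = c(younger_musician = 2))
  b <- simulate_cohort(31, n_per_cell = c(younger_musician = 2))
  expect_equal(a$profiles, b$profiles)
  expect_equal(a$blocks$P01$intensity_increasing$counts,
               b$blocks$P01$intensity_increasing$counts)
})

test_that("noise-free ratings are monotone in latent distance", {
  set15 <- make_stimulus_set(4)
  space <- latent_space()
  prof <- observer_profile("R", dprime = flat_dprime(0),
                           rating_gain = 150, rating_noise_sd = 0)
  r <- simulate_ratings(prof, set15, space, seed = 9)
  expect_equal(nrow(r), 105)
  expect_true(all(r$rating >= 0 & r$rating <= 128))
  d <- as.matrix(stats::dist(latent_coords15(space, set15)))[cbind(r$i, r$j)]
  expect_true(all(diff(r$rating[order(d)]) >= 0))
  expect_gt(stats::cor(d, r$rating, method = "spearman"), 0.999)
  # identical stimuli rate 0 (dissimilarity coding)
  dup <- set15
  dup[2, c("intensity_level", "spectral_level", "temporal_level")] <-
    dup[1, c("intensity_level", "spectral_level", "temporal_level")]
  r2 <- simulate_ratings(prof, dup, space, seed = 9)
  expect_equal(r2$rating[r2$i == 1 & r2$j == 2], 0)
  # the slider clamps at 128
  loud <- observer_profile("L", dprime = flat_dprime(0), rating_gain = 1e4,
                           rating_noise_sd = 0)
  expect_true(all(simulate_ratings(loud, set15, space, 9)$rating <= 128))
})

test_that("Experiment-2 cohorts are reproducible with 105 rows each", {
  a <- simulate_exp2_cohort(71)
  b <- simulate_exp2_cohort(71)
  expect_equal(nrow(a$profiles), 12)
  expect_equal(a$profiles$age_group, rep(c("younger", "older"), each = 6))
  expect_true(all(vapply(a$ratings, nrow, 0L) == 105))
  expect_true(all(a$profiles$rating_gain >= 40))
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$set15, b$set15)
})
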