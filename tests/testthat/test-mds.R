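# MDS core: SMACOF, procrustes alignment, bootstrap ensembles and the group
# comparison.

test_that("SMACOF recovers a known 3-D configuration exactly", {
  set.seed(21)
  X <- matrix(stats::rnorm(45), 15, 3)
  delta <- as.matrix(stats::dist(X))
  fit <- smacof_mds(delta, ndim = 3, n_starts = 4)
  expect_lt(fit$stress, 1e-6)
  expect_equal(as.matrix(stats::dist(fit$conf)), delta, tolerance = 1e-4)
})

test_that("stress is non-increasing across iterations on random inputs", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    fit <- smacof_mds(m, ndim = sample(1:3, 1), n_starts = 2, max_iter = 80)
    expect_true(all(diff(fit$stress_trace) <= 1e-10))
  }
})

test_that("SMACOF handles degenerate and invalid inputs", {
  z <- smacof_mds(matrix(0, 6, 6))
  expect_equal(z$conf, matrix(0, 6, 3))
  expect_equal(z$stress, 0)
  bad <- matrix(stats::runif(16), 4, 4)
  expect_error(smacof_mds(bad), "symmetric")
  neg <- matrix(-1, 4, 4)
  diag(neg) <- 0
  expect_error(smacof_mds(neg), "non-negative")
})

test_that("procrustes removes rotation, reflection, scale and translation", {
  set.seed(23)
  X <- matrix(stats::rnorm(45), 15, 3)
  for (reflect in c(FALSE, TRUE)) {
    Q <- random_rotation(reflect)
    Y <- 2.5 * X %*% Q + matrix(rep(c(1, -2, 0.5), each = 15), 15)
    pa <- procrustes_align(Y, X)
    expect_lt(pa$rss, 1e-12)
    expect_equal(pa$scale, 1 / 2.5, tolerance = 1e-9)
    expect_equal(pa$rotation, t(Q), tolerance = 1e-8)
    expect_equal(unname(pa$aligned), unname(X), tolerance = 1e-8)
  }
})

test_that("rigid alignment preserves interpoint distances exactly", {
  set.seed(25)
  X <- matrix(stats::rnorm(30), 10, 3)
  Y <- matrix(stats::rnorm(30), 10, 3)
  pr <- procrustes_align(Y, X, scale = FALSE)
  expect_equal(pr$scale, 1)
  expect_equal(as.matrix(stats::dist(pr$aligned)),
               as.matrix(stats::dist(Y)), tolerance = 1e-9)
  # with scaling, distances change only by the uniform factor
  ps <- procrustes_align(Y, X, scale = TRUE)
  expect_equal(as.matrix(stats::dist(ps$aligned)),
               ps$scale * as.matrix(stats::dist(Y)), tolerance = 1e-9)
})

test_that("procrustes agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(24)
  X <- matrix(stats::rnorm(36), 12, 3)
  Y <- 1.7 * X %*% random_rotation() + matrix(stats::rnorm(36, 0, 0.3), 12, 3)
  ours <- procrustes_align(Y, X)
  vg <- vegan::procrustes(X, Y, symmetric = FALSE)
  # vegan keeps Yrot centered; ours adds back the reference centroid
  expect_equal(unname(sweep(ours$aligned, 2, colMeans(ours$aligned))),
               unname(vg$Yrot), tolerance = 1e-8)
  expect_equal(ours$rss, sum(stats::residuals(vg)^2), tolerance = 1e-8)
  expect_equal(ours$scale, vg$scale, tolerance = 1e-8)
})

test_that("the physical reference is standardized as documented", {
  set15 <- make_stimulus_set(6)
  ref <- physical_reference(set15)
  expect_equal(colnames(ref), c("temporal", "spectral", "intensity"))
  expect_equal(colMeans(ref), stats::setNames(rep(0, 3), colnames(ref)),
               tolerance = 1e-12)
  expect_equal(sum(ref^2), 1, tolerance = 1e-12)
  phys <- stimulus_physical(set15)
  expect_equal(abs(stats::cor(ref[, "intensity"], phys[, "intensity"])), 1,
               tolerance = 1e-9)
  expect_equal(abs(stats::cor(ref[, "temporal"], log(phys[, "temporal"]))), 1,
               tolerance = 1e-9)
})

test_that("rating tables convert to symmetric dissimilarity matrices", {
  r <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), rating = c(100, 20, 60))
  m <- ratings_to_dissim(r, n = 3, invert = FALSE)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 3))
  expect_equal(m[1, 2], 100)
  mi <- ratings_to_dissim(r, n = 3, invert = TRUE)
  expect_equal(mi[1, 2], 28)    # 128 - 100, slider similarity coding
})

test_that("bootstrap ensembles have the requested geometry", {
  set15 <- make_stimulus_set(6)
  space <- latent_space()
  ref <- physical_reference(set15)
  d <- as.matrix(stats::dist(latent_coords15(space, set15)))
  tables <- rep(list(150 * d), 5)   # five identical noise-free raters
  ens <- bootstrap_mds(tables, ref, n_boot = 15, k = 4, seed = 3)
  expect_equal(dim(ens$boot), c(15, 15, 3))
  expect_length(ens$volumes, 15)
  # identical raters: every resample is the same, volumes collapse to 0
  expect_true(all(ens$volumes < 1e-8))
  expect_lt(ens$pooled_fit$stress, 1e-5)
  # unit-scale calibration: aligned distances reproduce the generating ones
  expect_equal(as.matrix(stats::dist(ens$pooled)), d, tolerance = 0.05)
})

test_that("group comparison declares identical ensembles similar", {
  set15 <- make_stimulus_set(9)
  ref <- physical_reference(set15)
  d <- as.matrix(stats::dist(latent_coords15(latent_space(), set15)))
  ens <- bootstrap_mds(rep(list(140 * d), 4), ref, n_boot = 10, k = 3,
                       seed = 2)
  out <- compare_groups(ens, ens, 6, 6)
  expect_equal(attr(out, "verdict"), "similar")
  expect_true(all(out$p_adj == 1))
  expect_true(all(out$p_adj >= out$p))
})

test_that("group comparison separates shifted clouds but not noise", {
  mk_ens <- function(shift, sd, seed) {
    set.seed(seed)
    boot <- array(stats::rnorm(60 * 15 * 3, sd = sd), c(60, 15, 3))
    boot[, 1, 1] <- boot[, 1, 1] + shift
    structure(list(boot = boot, centers = apply(boot, c(2, 3), mean),
                   reference = matrix(0, 15, 3)),
              class = "mds_ensemble")
  }
  a <- mk_ens(0, 0.01, 1)
  diff_b <- mk_ens(0.2, 0.01, 2)
  out <- compare_groups(a, diff_b, 6, 6)
  expect_equal(attr(out, "verdict"), "different")
  expect_equal(which(out$p_adj < 0.01), 1L)
  expect_gt(out$distance[1], 0.15)
  same_b <- mk_ens(0, 0.01, 3)
  out0 <- compare_groups(a, same_b, 6, 6)
  expect_equal(attr(out0, "verdict"), "similar")
})

test_that("ellipsoids cover the generating positions on low-noise data", {
  co <- simulate_exp2_cohort(77, rating_noise_sd = 4)
  ref <- physical_reference(co$set15)
  ens <- bootstrap_mds(co$ratings, ref, n_boot = 40, k = 6, seed = 5,
                       invert = FALSE)
  truth <- procrustes_align(latent_coords15(co$space, co$set15), ref)$aligned
  expect_gte(sum(ellipsoid_contains(ens, truth)), 10)
  expect_lt(ens$pooled_fit$stress, 0.1)
})
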