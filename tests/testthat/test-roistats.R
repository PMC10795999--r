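# HRF kernels, GLM recovery, voxel clusters, cross-validated readout,
# ANOVA, corrections, and robust outlier filtering.

test_that("HRF kernels have the expected timing", {
  can <- hrf_kernel("canonical_double_gamma", dt = 0.05)
  fast <- hrf_kernel("subcortical_fast", dt = 0.05)
  expect_identical(can$kernel[1], 0)
  peak_can <- can$time[which.max(can$kernel)]
  peak_fast <- fast$time[which.max(fast$kernel)]
  expect_gt(peak_can, 4.5); expect_lt(peak_can, 6.5)
  expect_lt(peak_fast, peak_can)
  expect_equal(max(can$kernel), 1)
})

test_that("GLM recovers amplitudes exactly from noiseless forward simulations", {
  onsets <- c(10, 30, 48, 70, 92, 110)
  amps <- c(1.2, 0.4, 0.9, 1.5, 0.2, 0.8)
  cfg <- cohort_config(bold = list(noise_sd = 0, drift = 0))
  sim <- gen_bold(onsets, amps, config = cfg, seed = 1)
  fit <- glm_fit(sim$y, onsets, hrf = hrf_kernel(), tr = sim$tr,
                 per_trial = TRUE)
  expect_equal(unname(fit$betas), amps, tolerance = 1e-8)

  ## zero signal -> zero betas
  fit0 <- glm_fit(rep(0, length(sim$y)), onsets, tr = 2, per_trial = TRUE)
  expect_equal(max(abs(fit0$betas)), 0, tolerance = 1e-12)

  ## a nuisance regressor orthogonal to the design leaves condition betas
  ## unchanged (projection property)
  sim2 <- gen_bold(onsets, amps, config = cfg, seed = 2)
  f_no <- glm_fit(sim2$y, onsets, conditions = rep(c("h", "m"), 3), tr = 2)
  set.seed(31)
  raw <- rnorm(length(sim2$y))
  orth <- raw - f_no$design %*% qr.solve(f_no$design, raw)
  f_nu <- glm_fit(sim2$y, onsets, conditions = rep(c("h", "m"), 3), tr = 2,
                  nuisance = orth)
  expect_equal(f_no$betas, f_nu$betas, tolerance = 1e-8)

  ## rank deficiency is reported with the offending columns
  dup <- cbind(a = rep(1, length(sim$y)))
  expect_error(glm_fit(sim$y, onsets, tr = 2, nuisance = dup), "collinear")
})

test_that("percent signal change scales per run", {
  x <- c(100, 102, 98, 100)
  expect_equal(percent_signal_change(x), c(0, 2, -2, 0))
  expect_error(percent_signal_change(c(-1, 1)), "zero")
})

test_that("connected components respect the configured connectivity", {
  dims <- c(4, 4, 4)
  ## two voxels touching only at a corner: separate under 6, joined under 26
  idx <- c(1 + 0 * 4 + 0 * 16, 2 + 1 * 4 + 1 * 16)  # (1,1,1) and (2,2,2)
  lab6 <- loomsight:::label_components_3d(idx, dims, 6)
  lab26 <- loomsight:::label_components_3d(idx, dims, 26)
  expect_identical(length(unique(lab6)), 2L)
  expect_identical(length(unique(lab26)), 1L)
  ## a face-connected bar is one component
  bar <- c(1, 2, 3) + 0 * 4 + 0 * 16
  expect_identical(length(unique(loomsight:::label_components_3d(bar, dims, 6))), 1L)
})

test_that("cluster-mass SVC detects injected clusters and nothing when conditions match", {
  cfg <- cohort_config(voxel = list(dims = c(10, 10, 10), center = c(5, 5, 5),
                                    radius = 1.5, effect_d = 1.2))
  coh <- gen_voxel_cohort(cfg, seed = 3, n_subjects = 16)
  res <- cluster_mass_permutation_svc(coh$diff, n_permutations = 500,
                                      seed = 1)
  expect_gt(length(res$cluster_p), 0)
  expect_lt(res$cluster_p[1], 0.05)
  ## the top cluster overlaps the injected one
  expect_gt(length(intersect(res$clusters[[1]], which(coh$cluster_mask))), 0)

  ## identical hit and miss maps -> zero difference -> no clusters
  zero <- coh$diff * 0
  rz <- cluster_mass_permutation_svc(zero, n_permutations = 100, seed = 1)
  expect_identical(length(rz$cluster_mass), 0L)

  ## same seed -> bit-identical null distribution
  res2 <- cluster_mass_permutation_svc(coh$diff, n_permutations = 500,
                                       seed = 1)
  expect_identical(res$null_max_mass, res2$null_max_mass)

  ## axis permutation of the grid leaves cluster masses unchanged
  resT <- cluster_mass_permutation_svc(aperm(coh$diff, c(2, 1, 3, 4)),
                                       n_permutations = 100, seed = 1)
  expect_equal(sort(resT$cluster_mass), sort(res$cluster_mass),
               tolerance = 1e-10)
})

test_that("LOSO selection never uses the held-out subject", {
  cfg <- cohort_config(voxel = list(dims = c(8, 8, 8), center = c(4, 4, 4),
                                    radius = 1.5, effect_d = 1.0))
  coh <- gen_voxel_cohort(cfg, seed = 9, n_subjects = 12)
  X <- loomsight:::as_subject_matrix(coh$diff)
  r1 <- loso_roi_effect(X)
  expect_lt(r1$p, 0.05)
  expect_gt(mean(r1$effects, na.rm = TRUE), 0)

  ## corrupting subject 1's own map does not change subject 1's ROI
  ## (selection provably excludes it), only its readout
  X2 <- X; X2[1, ] <- X2[1, ] * 100
  r2 <- suppressWarnings(loso_roi_effect(X2))  # other folds may go empty
  expect_identical(r1$roi_sizes[1], r2$roi_sizes[1])
  expect_equal(r2$effects[1], 100 * r1$effects[1], tolerance = 1e-10)

  ## identical subject maps -> every fold selects the same ROI
  Xs <- matrix(rep(X[1, ], 6), nrow = 6, byrow = TRUE)
  rs <- loso_roi_effect(Xs)
  expect_identical(length(unique(rs$roi_sizes)), 1L)
})

test_that("LORO with identical runs equals the plain ROI mean", {
  set.seed(12)
  run <- rnorm(60)
  runs <- matrix(rep(run, 4), nrow = 4, byrow = TRUE)
  cv <- loro_roi_effect(runs, k_top = 5)
  plain <- loro_roi_effect(runs, k_top = 5, cross_validated = FALSE)
  expect_equal(cv$estimate, plain$estimate, tolerance = 1e-12)
  expect_error(loro_roi_effect(runs[1, , drop = FALSE]), "runs")
})

test_that("rmANOVA matches the paired-t algebra of 2x2 within designs", {
  set.seed(21)
  n <- 14
  y <- array(rnorm(n * 4), c(n, 2, 2))
  y[, 2, 2] <- y[, 2, 2] + 1.2  # interaction + main effects
  res <- rm_anova_2x2(y)
  expect_identical(nrow(res$effects), 3L)
  expect_true(all(res$effects$partial_eta_sq >= 0 &
                    res$effects$partial_eta_sq <= 1))

  ## interaction F equals the squared paired t on difference-of-differences
  dI <- (y[, 2, 2] - y[, 1, 2]) - (y[, 2, 1] - y[, 1, 1])
  tt <- t.test(dI)
  FI <- res$effects$F[res$effects$effect == "A:B"]
  expect_equal(FI, unname(tt$statistic)^2, tolerance = 1e-8)

  ## post hoc computed only for significant effects, with Cohen's d
  if (res$effects$p[3] < 0.05) {
    expect_equal(res$post_hoc$`A:B`$cohens_d, mean(dI) / sd(dI),
                 tolerance = 1e-12)
  }
  expect_equal(paired_t_d(c(1, 2, 3))$cohens_d, 2)
  expect_error(rm_anova_2x2(array(rnorm(8), c(2, 2, 2))[, , c(1, 1)] * NA),
               "missing|balanced|2 x 2")
})

test_that("Holm and BH adjustments match hand computation and stay monotone", {
  expect_equal(holm_sequential(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_identical(holm_sequential(0.03), 0.03)
  expect_equal(holm_sequential(rep(0.02, 4)), rep(0.08, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2); p <- runif(20)
  q <- bh_fdr(p); h <- holm_sequential(p)
  expect_true(all(q >= p) && all(h >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(diff(h[ord]) >= -1e-12))
  expect_error(holm_sequential(c(0.5, 1.2)), "0, 1")
})

test_that("robust Mahalanobis filter keeps clean clouds and flags gross outliers", {
  kept_frac <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(100), 50, 2)
    mean(!robust_outlier_filter(x)$outlier)
  }, numeric(1))
  expect_gt(mean(kept_frac), 0.95)

  set.seed(1)
  x <- matrix(rnorm(60), 30, 2)
  x[1, ] <- c(10, -10)
  expect_true(robust_outlier_filter(x)$outlier[1])
  expect_error(robust_outlier_filter(matrix(rnorm(8), 4, 2)), "samples")
})
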