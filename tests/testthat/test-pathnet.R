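# Beta series, model-space enumeration, ML path fitting and selection.

test_that("beta series are recovered exactly from noiseless ROI series", {
  onsets <- seq(8, 160, by = 10)
  amps <- sin(seq_along(onsets)) + 1.5
  cfg <- cohort_config(bold = list(noise_sd = 0, drift = 0))
  sim <- gen_bold(onsets, amps, hrf = hrf_kernel("subcortical_fast"),
                  config = cfg, seed = 1)
  b <- beta_series_extract(sim$y, onsets, hrf = hrf_kernel("subcortical_fast"),
                           tr = sim$tr)
  expect_identical(length(b), length(onsets))
  expect_equal(b, amps, tolerance = 1e-8)

  ## permuting trial order permutes betas identically
  ord <- sample(length(onsets))
  b2 <- beta_series_extract(sim$y, onsets[ord],
                            hrf = hrf_kernel("subcortical_fast"),
                            tr = sim$tr)
  expect_equal(b2, amps[ord], tolerance = 1e-8)
})

test_that("condition z-scoring standardizes within condition", {
  set.seed(5)
  betas <- rnorm(40, mean = rep(c(2, 5), each = 20), sd = rep(c(1, 3), each = 20))
  cond <- rep(c("hit", "miss"), each = 20)
  z <- zscore_by_condition(betas, cond)
  for (lev in c("hit", "miss")) {
    expect_equal(mean(z[cond == lev]), 0, tolerance = 1e-12)
    expect_equal(sd(z[cond == lev]), 1, tolerance = 1e-12)
  }
  ## affine-transformed input gives identical output
  expect_equal(zscore_by_condition(3 * betas + 7, cond), z, tolerance = 1e-12)
  ## single condition equals the global z-score
  expect_equal(zscore_by_condition(betas, rep("all", 40)),
               as.numeric(scale(betas)), tolerance = 1e-12)
  expect_error(zscore_by_condition(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               "zero variance")
})

test_that("beta connectivity is the regression slope, equal to r for z-scores", {
  set.seed(6)
  a <- as.numeric(scale(rnorm(50)))
  expect_equal(suppressWarnings(beta_connectivity(a, a)$coefficient), 1,
               tolerance = 1e-10)
  b <- as.numeric(scale(0.6 * a + rnorm(50)))
  bc <- beta_connectivity(a, b)
  expect_equal(bc$coefficient, cor(a, b) * sd(b) / sd(a), tolerance = 1e-10)
  expect_error(beta_connectivity(a, b[-1]), "length")
})

test_that("model-space enumeration has the product cardinality", {
  models <- enumerate_model_space(default_model_space())
  expect_identical(length(models), 216L)
  ids <- vapply(models, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
  n_cyc <- attr(models, "n_cyclic")
  expect_identical(length(enumerate_model_space(default_model_space(),
                                                drop_cyclic = TRUE)),
                   216L - n_cyc)

  one_slot <- model_space_spec(c("A", "B"), two_option_slots = list(c("A", "B")))
  expect_identical(length(enumerate_model_space(one_slot)), 2L)
  empty <- model_space_spec(c("A", "B"), common_edges = list(c("A", "B")))
  expect_identical(length(enumerate_model_space(empty)), 1L)
})

test_that("saturated models fit perfectly and F vanishes at Sigma = S", {
  set.seed(7)
  X <- matrix(rnorm(300), 100, 3)
  colnames(X) <- c("A", "B", "C")
  sat <- path_model(c("A", "B", "C"),
                    list(c("A", "B"), c("A", "C"), c("B", "C")))
  fit <- fit_path_model(sat, data = X)
  expect_equal(fit$fit_indices$chi2, 0, tolerance = 1e-6)
  expect_equal(fit$fit_indices$df, 0)
  ## discrepancy identity: F(S, S) = 0
  expect_equal(loomsight:::fml_discrepancy(cov(X), cov(X)), 0,
               tolerance = 1e-10)
})

test_that("generating coefficients are recovered at N = 2000", {
  tr <- selection_demo_truth()
  X <- gen_beta_series(seed = 31, B = tr$B, psi = tr$psi, n_trials = 2000,
                       variables = rownames(tr$B))
  m <- path_model(rownames(tr$B), list(
    c("SC", "vmPul"), c("SC", "VTA"), c("SC", "VC"), c("VTA", "VC"),
    c("vmPul", "VC"), c("vmPul", "AttNet"), c("VTA", "AttNet"),
    c("VC", "AttNet")))
  fit <- fit_path_model(m, data = X)
  for (k in seq_len(nrow(fit$coefficients))) {
    true_b <- tr$B[fit$coefficients$to[k], fit$coefficients$from[k]]
    expect_lt(abs(fit$coefficients$estimate[k] - true_b),
              4 * fit$coefficients$se[k] + 0.02)
  }
})

test_that("ML fits agree with the closed-form recursive oracle on random models", {
  n_models <- 20
  worst <- 0
  for (s in seq_len(n_models)) {
    rm <- random_recursive_model(4, density = 0.5, seed = s)
    X <- gen_beta_series(seed = 100 + s, B = rm$B, psi = rm$psi,
                         n_trials = 400, variables = rm$variables)
    m <- path_model(rm$variables, rm$edges)
    fit <- fit_path_model(m, data = X)
    or <- oracle_path_fit(rm$variables, m$edges, cov(X), nrow(X))
    worst <- max(worst,
                 abs(fit$fit_indices$chi2 - or$chi2) / max(1, or$chi2),
                 abs(fit$fit_indices$GFI - or$GFI),
                 abs(fit$fit_indices$RMR - or$RMR),
                 abs(fit$fit_indices$RMSEA - or$RMSEA),
                 if (is.na(or$AGFI)) 0 else
                   abs(fit$fit_indices$AGFI - or$AGFI),
                 max(abs(fit$B - or$B)))
    expect_equal(fit$fit_indices$df, or$df)
  }
  expect_lt(worst, 1e-3)
})

test_that("chi-square is invariant to variable order and monotone under nesting", {
  tr <- selection_demo_truth()
  X <- gen_beta_series(seed = 41, B = tr$B, psi = tr$psi, n_trials = 500,
                       variables = rownames(tr$B))
  vars <- rownames(tr$B)
  edges <- list(c("SC", "vmPul"), c("SC", "VTA"), c("SC", "VC"),
                c("VTA", "VC"), c("vmPul", "VC"), c("vmPul", "AttNet"),
                c("VTA", "AttNet"), c("VC", "AttNet"))
  f1 <- fit_path_model(path_model(vars, edges), data = X)
  perm <- c("AttNet", "VC", "SC", "VTA", "vmPul")
  f2 <- fit_path_model(path_model(perm, edges), data = X[, perm])
  expect_equal(f1$fit_indices$chi2, f2$fit_indices$chi2, tolerance = 1e-5)

  ## freeing a parameter can only lower chi-square
  nested <- edges[-8]
  fn <- fit_path_model(path_model(vars, nested), data = X)
  expect_gte(fn$fit_indices$chi2 + 1e-6, f1$fit_indices$chi2)
})

test_that("model selection filters by PGFI, ranks by AGFI and breaks ties", {
  tr <- selection_demo_truth()
  X <- gen_beta_series(seed = 51, B = tr$B, psi = tr$psi, n_trials = 800,
                       variables = rownames(tr$B))
  models <- enumerate_model_space(selection_demo_space())
  fits <- lapply(models, fit_path_model, data = X)
  sel <- select_best_model(fits, pgfi_max = 0.15)
  expect_s3_class(sel$best, "fitted_path_model")
  expect_true(all(sel$ranking$PGFI <= 0.15))
  expect_gt(sel$n_excluded, 0)
  expect_true(all(diff(sel$ranking$AGFI[sel$ranking$converged]) <= 1e-12))

  ## duplicated fits tie and the tie is flagged
  two <- select_best_model(list(fits[[1]], fits[[1]]), pgfi_max = 0.15)
  expect_true(two$tie)

  ## an unsatisfiable threshold errors with guidance
  expect_error(select_best_model(fits, pgfi_max = 1e-6), "PGFI")
})

test_that("correlation FWE uses the max-|r| null and dominates uncorrected p", {
  set.seed(61)
  X <- matrix(rnorm(20 * 4), 20, 4)
  X[, 2] <- X[, 1]  # a duplicated column has r = 1 with its source
  res <- correlation_matrix_fwe(X, n_permutations = 300, seed = 3,
                                outlier_filter = FALSE)
  expect_equal(res$r[1, 2], 1, tolerance = 1e-12)
  ut <- upper.tri(res$r)
  expect_true(all(res$p_fwe[ut] >= res$p_uncorrected[ut]))
  expect_true(isSymmetric(res$r))
  expect_error(correlation_matrix_fwe(cbind(X[, 1], 1)), "constant|subjects")
})
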