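# Beta-series connectivity: per-trial GLM amplitudes per ROI, condition
# z-scoring, second-level regression, and max-statistic FWE for
# across-subject correlation matrices.

#' Per-trial beta series from an ROI time series
#'
#' Estimates one amplitude per trial by fitting a GLM with a separate
#' HRF-convolved regressor for every trial (plus intercept and optional
#' nuisance regressors). Betas are returned in trial order.
#'
#' @param roi_timeseries Numeric BOLD series of the ROI.
#' @param trial_onsets Trial onsets in seconds.
#' @param hrf An `hrf_model`.
#' @param tr Repetition time in seconds.
#' @param durations Event duration(s) in seconds.
#' @param nuisance Optional nuisance regressor matrix.
#' @return Numeric vector of per-trial betas (one per onset).
#' @export
beta_series_extract <- function(roi_timeseries, trial_onsets,
                                hrf = hrf_kernel("subcortical_fast"),
                                tr = 2, durations = 0.33, nuisance = NULL) {
  fit <- glm_fit(roi_timeseries, trial_onsets, durations = durations,
                 hrf = hrf, tr = tr, nuisance = nuisance, per_trial = TRUE)
  unname(fit$betas)
}

#' Z-score a beta series within each condition
#'
#' Per condition, subtracts the condition mean and divides by the condition
#' SD, removing mean-amplitude differences between trajectory conditions
#' before connectivity analysis.
#'
#' @param betas Numeric vector of per-trial betas.
#' @param conditions Condition label per trial (>= 2 trials per condition).
#' @return Z-scored betas, same order.
#' @export
zscore_by_condition <- function(betas, conditions) {
  stopifnot(length(betas) == length(conditions))
  out <- numeric(length(betas))
  for (lev in unique(conditions)) {
    i <- conditions == lev
    if (sum(i) < 2) stop_domain("condition '", lev, "' has < 2 trials")
    s <- sd(betas[i])
    if (s == 0) stop_domain("condition '", lev, "' has zero variance")
    out[i] <- (betas[i] - mean(betas[i])) / s
  }
  out
}

#' Second-level beta-series connectivity between two ROIs
#'
#' Slope (with its p-value) of the linear regression of one ROI's
#' (z-scored) beta series on another's; for z-scored inputs the slope
#' equals the Pearson correlation.
#'
#' @param series_a,series_b Numeric beta series of equal length.
#' @return List with `coefficient`, `p`, `t`, `df`.
#' @export
beta_connectivity <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop_domain("series must have equal length")
  }
  fit <- summary(lm(series_b ~ series_a))
  co <- fit$coefficients["series_a", ]
  list(coefficient = unname(co["Estimate"]), p = unname(co["Pr(>|t|)"]),
       t = unname(co["t value"]), df = fit$df[2])
}

#' Across-subject correlation matrix with max-statistic FWE correction
#'
#' Pearson correlations between all column pairs (per pair optionally after
#' robust Mahalanobis outlier removal). The family-wise null records, for
#' each permutation in which the subject correspondence of every column is
#' independently shuffled, the largest |r| over the matrix; corrected
#' p-values are read off that null (and floored at the uncorrected p).
#'
#' @param subject_effect_table Numeric matrix, subjects x variables
#'   (>= 5 subjects, >= 2 variables).
#' @param n_permutations Number of permutations.
#' @param seed Seed for the shuffles.
#' @param outlier_filter Apply [robust_outlier_filter()] per pair before
#'   the observed correlation (default TRUE).
#' @return An object of class `correlation_fwe_result`: `r`, `p_uncorrected`,
#'   `p_fwe` (symmetric matrices), `null_max_r`, `n_permutations`, `seed`.
#' @export
correlation_matrix_fwe <- function(subject_effect_table,
                                   n_permutations = 10000, seed = NULL,
                                   outlier_filter = TRUE) {
  X <- as.matrix(subject_effect_table)
  n <- nrow(X); k <- ncol(X)
  if (n < 5) stop_domain("need >= 5 subjects")
  if (k < 2) stop_domain("need >= 2 variables")
  if (any(col_sds(X) == 0)) stop_domain("constant column in the table")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(k))

  r <- diag(1, k); p_un <- matrix(0, k, k)
  dimnames(r) <- dimnames(p_un) <- list(colnames(X), colnames(X))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xy <- X[, c(i, j)]
      if (outlier_filter) {
        flt <- robust_outlier_filter(xy)
        xy <- flt$kept
      }
      ct <- cor.test(xy[, 1], xy[, 2])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p_un[i, j] <- p_un[j, i] <- ct$p.value
    }
  }

  ut <- upper.tri(r)
  null_max <- with_seed(seed %||% 1L, {
    vapply(seq_len(n_permutations), function(p) {
      Xp <- apply(X, 2, sample)
      max(abs(cor(Xp)[ut]))
    }, numeric(1))
  })
  p_fwe <- matrix(0, k, k, dimnames = dimnames(r))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pf <- (1 + sum(null_max >= abs(r[i, j]))) / (1 + n_permutations)
      p_fwe[i, j] <- p_fwe[j, i] <- max(pf, p_un[i, j])
    }
  }
  structure(list(r = r, p_uncorrected = p_un, p_fwe = p_fwe,
                 null_max_r = null_max, n_permutations = n_permutations,
                 seed = seed),
            class = "correlation_fwe_result")
}
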