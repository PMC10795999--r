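# Cross-validated ROI readout: leave-one-subject-out voxel selection at the
# group level and leave-one-run-out selection within subject. Both exist to
# decouple the voxels used for selection from the data used for readout, so
# the reported effect is free of selection bias.

#' Leave-one-subject-out ROI effect estimates
#'
#' For each held-out subject, voxels with significant positive group-level
#' collision sensitivity (`hit - miss`, two-sided uncorrected
#' `p < group_alpha` with t > 0) among the remaining subjects define the
#' ROI; the held-out subject's mean difference over that ROI is the
#' cross-validated effect. A group-level paired t test is run on the n
#' estimates.
#'
#' @param subject_diff_maps Subjects-by-voxels matrix of hit-minus-miss
#'   maps (>= 3 subjects), or a 4D array `x*y*z*subject`.
#' @param group_alpha Uncorrected voxel alpha for selection.
#' @return A list of class `loso_result`: `effects` (per subject; `NA` for
#'   folds with an empty ROI, excluded with a warning), `roi_sizes`,
#'   `t`, `p`, `df`.
#' @export
loso_roi_effect <- function(subject_diff_maps, group_alpha = 0.05) {
  X <- as_subject_matrix(subject_diff_maps)
  n <- nrow(X)
  if (n < 3) stop_domain("need >= 3 subjects")
  tcrit <- qt(1 - group_alpha / 2, df = n - 2)
  effects <- numeric(n)
  sizes <- integer(n)
  for (s in seq_len(n)) {
    t_rest <- as.numeric(signflip_t_matrix(matrix(1, 1, n - 1),
                                           X[-s, , drop = FALSE]))
    roi <- which(t_rest > tcrit)
    sizes[s] <- length(roi)
    effects[s] <- if (length(roi)) mean(X[s, roi]) else NA_real_
  }
  if (anyNA(effects)) {
    warning(sum(is.na(effects)), " fold(s) had an empty ROI; excluded")
  }
  ok <- !is.na(effects)
  tt <- if (sum(ok) >= 2) {
    tryCatch(t.test(effects[ok]), error = function(e) NULL)  # constant data
  }
  if (!is.null(tt)) {
    gt <- unname(tt$statistic); gp <- tt$p.value; gdf <- unname(tt$parameter)
  } else {
    gt <- gp <- gdf <- NA_real_
  }
  structure(list(effects = effects, roi_sizes = sizes,
                 t = gt, p = gp, df = gdf),
            class = "loso_result")
}

as_subject_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  t(matrix(x, prod(d[-length(d)]), d[length(d)]))
}

#' Leave-one-run-out cross-validated ROI response (one subject)
#'
#' Per fold, voxels are selected on all runs but one — either the
#' `k_top` voxels with the strongest mean difference (`selector =
#' "top_k"`) or voxels whose mean sum response exceeds an uncorrected
#' significance criterion (`selector = "responsive"`, requires
#' `run_sum_maps`) — and the effect is read out from the left-out run over
#' those voxels. Fold results are averaged. `cross_validated = FALSE`
#' deliberately performs selection and readout on all runs together; that
#' biased variant exists only as a negative control for regression tests.
#'
#' @param run_diff_maps Runs-by-voxels matrix of per-run difference maps
#'   (>= 2 runs).
#' @param k_top Number of voxels selected per fold (`"top_k"`).
#' @param selector `"top_k"` or `"responsive"`.
#' @param run_sum_maps Runs-by-voxels matrix of per-run summed (hit + miss)
#'   responses, for `selector = "responsive"`.
#' @param alpha Uncorrected alpha for the responsive selector.
#' @param cross_validated Set `FALSE` for the biased non-CV variant.
#' @return A list of class `loro_result`: `estimate` (averaged across
#'   folds), `fold_estimates`, `selector`, `k_top`.
#' @export
loro_roi_effect <- function(run_diff_maps, k_top = 10,
                            selector = c("top_k", "responsive"),
                            run_sum_maps = NULL, alpha = 0.05,
                            cross_validated = TRUE) {
  selector <- match.arg(selector)
  stopifnot(is.matrix(run_diff_maps))
  R <- nrow(run_diff_maps)
  if (R < 2) stop_domain("need >= 2 runs")
  if (selector == "responsive" && is.null(run_sum_maps)) {
    stop_domain("`run_sum_maps` required for the responsive selector")
  }

  select_voxels <- function(rows) {
    if (selector == "top_k") {
      score <- colMeans(run_diff_maps[rows, , drop = FALSE])
      order(score, decreasing = TRUE)[seq_len(min(k_top,
                                                  ncol(run_diff_maps)))]
    } else {
      m <- length(rows)
      tv <- as.numeric(signflip_t_matrix(matrix(1, 1, m),
                                         run_sum_maps[rows, , drop = FALSE]))
      tcrit <- qt(1 - alpha / 2, df = m - 1)
      which(tv > tcrit)
    }
  }

  if (!cross_validated) {
    vox <- select_voxels(seq_len(R))
    if (!length(vox)) return(structure(list(estimate = NA_real_,
                                            fold_estimates = NA_real_,
                                            selector = selector,
                                            k_top = k_top),
                                       class = "loro_result"))
    est <- mean(colMeans(run_diff_maps[, vox, drop = FALSE]))
    return(structure(list(estimate = est, fold_estimates = est,
                          selector = selector, k_top = k_top),
                     class = "loro_result"))
  }

  folds <- vapply(seq_len(R), function(r) {
    vox <- select_voxels(setdiff(seq_len(R), r))
    if (!length(vox)) return(NA_real_)
    mean(run_diff_maps[r, vox])
  }, numeric(1))
  if (anyNA(folds)) warning(sum(is.na(folds)), " fold(s) selected no voxels")
  structure(list(estimate = mean(folds, na.rm = TRUE),
                 fold_estimates = folds, selector = selector, k_top = k_top),
            class = "loro_result")
}
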