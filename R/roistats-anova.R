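# Repeated-measures ANOVA with effect sizes, multiple-testing corrections,
# and robust bivariate outlier filtering.

#' Two-way repeated-measures ANOVA (2x2 within design)
#'
#' Classical within-subject ANOVA via [stats::aov()] with
#' `Error(subject/(A*B))` strata. Reports F, df, p and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) for both main effects and the
#' interaction. Post-hoc paired t tests (with Cohen's d = mean of paired
#' differences / SD of paired differences) are computed only for effects
#' significant at `alpha`, following the Fisher-protected logic.
#'
#' @param responses 3D array `subject x levels(A) x levels(B)` (2 x 2), or
#'   a data frame with columns `subject`, `A`, `B`, `y` (complete balanced).
#' @param alpha Significance level gating the post-hoc tests.
#' @return An object of class `anova_result`: `effects` (data frame with
#'   F, df1, df2, p, partial eta squared per effect) and `post_hoc` (list
#'   of paired t results with Cohen's d, only for significant effects).
#' @export
rm_anova_2x2 <- function(responses, alpha = 0.05) {
  if (is.array(responses) && length(dim(responses)) == 3) {
    d <- dim(responses)
    if (d[2] != 2 || d[3] != 2) stop_domain("expected a subject x 2 x 2 array")
    df <- expand.grid(subject = seq_len(d[1]), A = c("a1", "a2"),
                      B = c("b1", "b2"))
    df$y <- as.vector(responses)
  } else {
    df <- as.data.frame(responses)
    stopifnot(all(c("subject", "A", "B", "y") %in% names(df)))
  }
  if (anyNA(df$y)) stop_domain("missing cells in the design")
  tab <- table(df$subject, df$A, df$B)
  if (any(tab != 1)) stop_domain("design must be complete and balanced")
  df$subject <- factor(df$subject)
  df$A <- factor(df$A)
  df$B <- factor(df$B)

  fit <- aov(y ~ A * B + Error(subject / (A * B)), data = df)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    s <- sm[[paste0("Error: ", stratum)]][[1]]
    rn <- trimws(rownames(s))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    c(F = s[i, "F value"], df1 = s[i, "Df"], df2 = s[j, "Df"],
      p = s[i, "Pr(>F)"],
      pes = s[i, "Sum Sq"] / (s[i, "Sum Sq"] + s[j, "Sum Sq"]))
  }
  eff <- rbind(A = pull("subject:A", "A"),
               B = pull("subject:B", "B"),
               `A:B` = pull("subject:A:B", "A:B"))
  eff <- data.frame(effect = rownames(eff), eff, row.names = NULL)
  names(eff)[6] <- "partial_eta_sq"

  ## condition means per subject, in a fixed layout
  wide <- tapply(df$y, list(df$subject, df$A, df$B), mean)
  post <- list()
  if (eff$p[eff$effect == "A"] < alpha) {
    dA <- rowMeans(wide[, 2, ]) - rowMeans(wide[, 1, ])
    post$A <- paired_t_d(dA)
  }
  if (eff$p[eff$effect == "B"] < alpha) {
    dB <- rowMeans(wide[, , 2]) - rowMeans(wide[, , 1])
    post$B <- paired_t_d(dB)
  }
  if (eff$p[eff$effect == "A:B"] < alpha) {
    dI <- (wide[, 2, 2] - wide[, 1, 2]) - (wide[, 2, 1] - wide[, 1, 1])
    post$`A:B` <- paired_t_d(dI)
  }
  structure(list(effects = eff, post_hoc = post, alpha = alpha),
            class = "anova_result")
}

#' Paired t test with Cohen's d
#'
#' @param paired_differences Vector of paired differences.
#' @return List with `t`, `df`, `p`, `cohens_d` (= mean / SD of the paired
#'   differences), `mean_diff`.
#' @export
paired_t_d <- function(paired_differences) {
  d <- as.numeric(paired_differences)
  tt <- t.test(d)
  sdd <- sd(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohens_d = if (sdd > 0) mean(d) / sdd else NA_real_,
       mean_diff = mean(d))
}

#' Holm-Bonferroni step-down adjusted p-values
#'
#' Sequential (step-down) Holm adjustment, monotonized and capped at 1.
#' Thin, named wrapper over [stats::p.adjust()].
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
holm_sequential <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' Benjamini-Hochberg FDR-adjusted q-values
#'
#' Standard step-up BH adjustment with monotonization, via
#' [stats::p.adjust()].
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Robust Mahalanobis outlier filter (FAST-MCD)
#'
#' Robust location and scatter by minimum covariance determinant
#' ([MASS::cov.rob()], FAST-MCD); points whose robust Mahalanobis distance
#' falls outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the distance
#' distribution are flagged as outliers.
#'
#' @param x Numeric matrix (n x d) of samples, typically bivariate;
#'   requires `n > d + 2`.
#' @param seed Seed for the (randomized) MCD subset search; fixed default
#'   so results are reproducible.
#' @return A list of class `outlier_filter`: `kept` (matrix of retained
#'   rows), `outlier` (logical per row), `distances`.
#' @export
robust_outlier_filter <- function(x, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n <= d + 2) stop_domain("need n > dimension + 2 samples")
  rob <- with_seed(seed,
    tryCatch(MASS::cov.rob(x, method = "mcd"),
             error = function(e) stop_domain("degenerate scatter: ",
                                             conditionMessage(e))))
  if (any(!is.finite(rob$cov)) || det(rob$cov) <= 0) {
    stop_domain("degenerate robust scatter")
  }
  dist <- sqrt(mahalanobis(x, rob$center, rob$cov))
  q <- quantile(dist, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  out <- dist < q[1] - 1.5 * iqr | dist > q[2] + 1.5 * iqr
  structure(list(kept = x[!out, , drop = FALSE], outlier = out,
                 distances = dist),
            class = "outlier_filter")
}
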