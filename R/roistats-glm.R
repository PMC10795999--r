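# Hemodynamic response kernels and GLM amplitude estimation.

#' Sampled hemodynamic response kernel
#'
#' Double-gamma HRF, peak-normalized to 1. The `canonical_double_gamma`
#' family has the familiar ~5 s peak and late undershoot used for cortical
#' BOLD; `subcortical_fast` is a faster, narrower variant (earlier peak,
#' tighter dispersion) suited to subcortical nuclei, parameterized rather
#' than fixed since published subcortical kernels vary.
#'
#' @param family `"canonical_double_gamma"` or `"subcortical_fast"`.
#' @param dt Sampling interval in seconds.
#' @param duration Kernel support duration in seconds.
#' @param parameters Optional named list overriding `peak_delay`,
#'   `peak_dispersion`, `undershoot_delay`, `undershoot_dispersion`,
#'   `undershoot_ratio` (all in seconds except the ratio).
#' @return An object of class `hrf_model`: `time`, `kernel` (max 1),
#'   `family`, `parameters`, `dt`.
#' @export
hrf_kernel <- function(family = c("canonical_double_gamma",
                                  "subcortical_fast"),
                       dt = 0.1, duration = 32, parameters = list()) {
  family <- match.arg(family)
  defaults <- switch(family,
    canonical_double_gamma = list(peak_delay = 6, peak_dispersion = 1,
                                  undershoot_delay = 16,
                                  undershoot_dispersion = 1,
                                  undershoot_ratio = 1 / 6),
    subcortical_fast = list(peak_delay = 4, peak_dispersion = 0.9,
                            undershoot_delay = 8,
                            undershoot_dispersion = 0.9,
                            undershoot_ratio = 0.35))
  p <- utils::modifyList(defaults, parameters)
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = p$peak_delay / p$peak_dispersion,
              scale = p$peak_dispersion) -
    p$undershoot_ratio *
      dgamma(t, shape = p$undershoot_delay / p$undershoot_dispersion,
             scale = p$undershoot_dispersion)
  h <- h / max(h)
  structure(list(time = t, kernel = h, family = family, parameters = p,
                 dt = dt), class = "hrf_model")
}

## Build one HRF-convolved regressor per event set on a fine grid, sampled
## at the scan times. `events` is a list of onset vectors (one regressor per
## element); boxcars of `durations` seconds are convolved with the kernel.
build_design <- function(events, durations, hrf, n_scans, tr) {
  dt <- hrf$dt
  n_fine <- ceiling(n_scans * tr / dt) + length(hrf$kernel)
  scan_idx <- round((seq_len(n_scans) - 1) * tr / dt) + 1
  X <- vapply(seq_along(events), function(j) {
    on <- events[[j]]
    dur <- if (length(durations) == 1) rep(durations, length(on)) else durations
    s <- numeric(n_fine)
    for (i in seq_along(on)) {
      a <- floor(on[i] / dt) + 1
      b <- max(a, ceiling((on[i] + dur[i]) / dt))
      s[a:min(b, n_fine)] <- 1
    }
    r <- convolve(s, rev(hrf$kernel), type = "open")[seq_len(n_fine)]
    r[scan_idx]
  }, numeric(n_scans))
  X / max(abs(X))  # common scale so betas are in response units
}

#' Percent-signal-change scaling of a run
#'
#' `100 * (x - mean(x)) / mean(x)`, applied per run before GLM fitting.
#'
#' @param x Numeric BOLD time series of one run.
#' @return Scaled series in percent signal change.
#' @export
percent_signal_change <- function(x) {
  m <- mean(x)
  if (m == 0) stop_domain("run mean is zero; cannot scale")
  100 * (x - m) / m
}

#' Ordinary-least-squares GLM amplitudes for event conditions
#'
#' Fits `y` with one HRF-convolved regressor per condition (or per trial
#' when `per_trial = TRUE`), an intercept, and optional nuisance regressors.
#'
#' @param bold Numeric BOLD time series (one run or concatenation), sampled
#'   at `tr` seconds.
#' @param onsets Event onsets in seconds.
#' @param conditions Condition label per onset; ignored when `per_trial`.
#' @param durations Event duration(s) in seconds.
#' @param hrf An `hrf_model` from [hrf_kernel()].
#' @param tr Repetition time in seconds.
#' @param nuisance Optional matrix of nuisance regressors (rows = scans).
#' @param per_trial Estimate one beta per trial (beta-series mode).
#' @return A list of class `glm_fit`: `betas` (named per condition, or per
#'   trial in trial order), `residual_variance`, `design`, `df_residual`.
#' @export
glm_fit <- function(bold, onsets, conditions = NULL, durations = 0.33,
                    hrf = hrf_kernel(), tr = 2, nuisance = NULL,
                    per_trial = FALSE) {
  n_scans <- length(bold)
  if (per_trial) {
    events <- as.list(onsets)
    labels <- paste0("trial_", seq_along(onsets))
  } else {
    if (is.null(conditions)) conditions <- rep("stim", length(onsets))
    labels <- unique(conditions)
    events <- lapply(labels, function(l) onsets[conditions == l])
  }
  X <- build_design(events, durations, hrf, n_scans, tr)
  colnames(X) <- labels
  Xfull <- cbind(intercept = 1, X)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    }
    Xfull <- cbind(Xfull, nuisance)
  }
  qrX <- qr(Xfull)
  if (qrX$rank < ncol(Xfull)) {
    bad <- colnames(Xfull)[qrX$pivot[(qrX$rank + 1):ncol(Xfull)]]
    stop_domain("design matrix is rank deficient; collinear columns: ",
                paste(bad, collapse = ", "))
  }
  fit <- lm.fit(Xfull, bold)
  df_res <- n_scans - ncol(Xfull)
  structure(list(betas = fit$coefficients[labels],
                 residual_variance = sum(fit$residuals^2) / max(df_res, 1),
                 design = Xfull, df_residual = df_res),
            class = "glm_fit")
}
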