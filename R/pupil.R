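# Pupil-trace preprocessing and cluster-length permutation inference over
# time between trajectory conditions.

#' Preprocess a pupil trace
#'
#' Fixed order: linear interpolation of missing samples (blinks), zero-phase
#' low-pass filtering (4th-order Butterworth, forward-backward), baseline
#' subtraction, and SD normalization. A trace whose baseline window is
#' entirely missing is returned flagged invalid.
#'
#' @param time_ms Sample times in ms relative to stimulus onset (uniform).
#' @param diameter Pupil diameter samples; missing samples as `NA`.
#' @param sampling_rate Sampling rate in Hz (must exceed `2 * lowpass_cutoff`).
#' @param lowpass_cutoff Low-pass cutoff in Hz (e.g. 40 Hz to suppress
#'   shutter-glass artifacts).
#' @param baseline_window `c(start, end)` in ms, preceding onset; default
#'   -200 to 0 ms.
#' @param normalization `"sd_normalized"` (baseline-subtracted then divided
#'   by the trace SD), `"baseline_subtracted"`, or `"raw"`.
#' @param sd_window SD used for normalization: `"trace"` (whole trace,
#'   default) or `"baseline"`.
#' @return An object of class `pupil_trace` with fields `time`, `diameter`,
#'   `sampling_rate`, `baseline_window`, `normalization`, `valid`.
#' @export
preprocess_pupil <- function(time_ms, diameter, sampling_rate,
                             lowpass_cutoff = 40,
                             baseline_window = c(-200, 0),
                             normalization = c("sd_normalized",
                                               "baseline_subtracted", "raw"),
                             sd_window = c("trace", "baseline")) {
  normalization <- match.arg(normalization)
  sd_window <- match.arg(sd_window)
  stopifnot(length(time_ms) == length(diameter))
  if (sampling_rate <= 2 * lowpass_cutoff) {
    stop_domain("`sampling_rate` must exceed twice the low-pass cutoff")
  }
  if (baseline_window[2] > 0 || baseline_window[1] >= baseline_window[2]) {
    stop_domain("baseline window must precede stimulus onset")
  }
  bl_idx <- time_ms >= baseline_window[1] & time_ms <= baseline_window[2]
  if (!any(bl_idx)) stop_domain("baseline window contains no samples")
  valid <- !all(is.na(diameter[bl_idx]))

  y <- diameter
  if (anyNA(y)) {
    ok <- !is.na(y)
    if (sum(ok) < 2) stop_domain("trace has fewer than 2 observed samples")
    y <- approx(time_ms[ok], y[ok], xout = time_ms, rule = 2)$y
  }
  ## zero-phase 4th-order Butterworth low-pass; odd-reflection padding
  ## suppresses the filter's start-up transients at the trace edges
  bf <- signal::butter(4, lowpass_cutoff / (sampling_rate / 2), type = "low")
  n <- length(y)
  mu_y <- mean(y)
  yc <- y - mu_y
  pad <- min(n - 1, ceiling(3 * sampling_rate / lowpass_cutoff))
  ypad <- c(2 * yc[1] - yc[(pad + 1):2], yc,
            2 * yc[n] - yc[(n - 1):(n - pad)])
  yf <- as.numeric(signal::filtfilt(bf, ypad))
  y <- yf[(pad + 1):(pad + n)] + mu_y

  if (normalization != "raw") {
    y <- y - mean(y[bl_idx])
    if (normalization == "sd_normalized") {
      s <- if (sd_window == "trace") sd(y) else sd(y[bl_idx])
      ## leave (numerically) constant traces at zero rather than amplifying
      ## round-off
      if (is.finite(s) && s > 1e-10 * max(1, max(abs(y)))) y <- y / s
    }
  }
  structure(list(time = time_ms, diameter = y, sampling_rate = sampling_rate,
                 baseline_window = baseline_window,
                 normalization = normalization, valid = valid),
            class = "pupil_trace")
}

#' Windowed mean of a trace
#'
#' Mean of `diameter` over a time window (used e.g. to summarize the late
#' looming component of the pupil response).
#'
#' @param trace A `pupil_trace`, or a list with `time` and `diameter`.
#' @param window_ms `c(start, end)` in ms.
#' @return Scalar mean.
#' @export
windowed_mean <- function(trace, window_ms = c(1000, 1364)) {
  idx <- trace$time >= window_ms[1] & trace$time <= window_ms[2]
  if (!any(idx)) stop_domain("window contains no samples")
  mean(trace$diameter[idx])
}

## maximal runs of TRUE in a logical vector -> data.frame(start, end, length)
runs_of <- function(sig) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

## max run length of TRUE per row of a logical matrix
max_run_rows <- function(m) {
  apply(m, 1, function(row) {
    r <- rle(row)
    len <- r$lengths[r$values]
    if (length(len)) max(len) else 0L
  })
}

## per-permutation paired t statistics for sign-flipped rows of D (n x T):
## sign flips leave sum(x^2) unchanged, so only the mean changes.
signflip_t_matrix <- function(S, D) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ss <- colSums(D^2)
  v <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  M / sqrt(v / n)
}

#' Cluster-length permutation test between paired trace conditions
#'
#' Pointwise paired t tests at each time sample define clusters as maximal
#' runs of samples with `p < point_alpha`; the family-wise null is the
#' maximum cluster length under within-subject condition-label permutation
#' (sign flips of the paired difference). Each observed cluster gets
#' `cluster_p` = proportion of the null at or above its length.
#'
#' @param cond_a_traces,cond_b_traces Matrices (subjects x time) of paired
#'   per-subject traces, equal shapes, >= 2 subjects.
#' @param n_permutations Number of sign-flip permutations (default 10000).
#' @param point_alpha Pointwise (cluster-defining) alpha.
#' @param seed Seed for the permutation draw.
#' @param time_ms Optional sample times for reporting cluster bounds in ms.
#' @return An object of class `time_cluster_result`: `clusters` (data frame
#'   with start/end indices, ms bounds when `time_ms` given, length and
#'   `cluster_p`), `null_lengths`, `n_permutations`, `point_alpha`, `seed`.
#' @export
cluster_time_permutation <- function(cond_a_traces, cond_b_traces,
                                     n_permutations = 10000,
                                     point_alpha = 0.05, seed = NULL,
                                     time_ms = NULL) {
  stopifnot(is.matrix(cond_a_traces), is.matrix(cond_b_traces),
            identical(dim(cond_a_traces), dim(cond_b_traces)))
  n <- nrow(cond_a_traces)
  if (n < 2) stop_domain("need >= 2 subjects")
  D <- cond_a_traces - cond_b_traces
  tcrit <- qt(1 - point_alpha / 2, df = n - 1)

  t_obs <- as.numeric(signflip_t_matrix(matrix(1, 1, n), D))
  clusters <- runs_of(abs(t_obs) > tcrit)

  S <- with_seed(seed %||% 1L,
                 matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                        n_permutations, n))
  Tp <- signflip_t_matrix(S, D)
  null_lengths <- max_run_rows(abs(Tp) > tcrit)

  if (nrow(clusters)) {
    clusters$cluster_p <- vapply(clusters$length, function(L) {
      (1 + sum(null_lengths >= L)) / (1 + n_permutations)
    }, numeric(1))
    if (!is.null(time_ms)) {
      clusters$start_ms <- time_ms[clusters$start]
      clusters$end_ms <- time_ms[clusters$end]
    }
  }
  structure(list(clusters = clusters, null_lengths = null_lengths,
                 n_permutations = n_permutations, point_alpha = point_alpha,
                 seed = seed),
            class = "time_cluster_result")
}
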