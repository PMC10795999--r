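# Seeded synthetic-data generators. Every generator is a pure function of
# (config, seed) and produces inputs with the statistical structure the
# corresponding analysis stage assumes, at the scale of the emulated study
# (behavioral cohort n = 15, imaging cohort n = 20, 16 trials per cell,
# ISI in {8, 10, 12} s, TR 2 s, 1.5-mm voxels).

#' Cohort configuration for the synthetic generators
#'
#' Collects the ground-truth parameters shared by the generators. Defaults
#' mirror the emulated study scale; all fields can be overridden.
#'
#' @param n_subjects Number of subjects.
#' @param psychometric Truth for [gen_behavior()]: `mu` (cm),
#'   `sigma_upper`, `sigma_lower` (cm), between-subject SDs of `mu` and
#'   `log(sigma)`, impact points (cm) and trials per level per field.
#' @param pupil Truth for [gen_pupil()]: sampling rate (Hz), time span
#'   (ms), effect latency/width (ms), amplitude (SD units, negative =
#'   constriction in the hit condition), AR(1) coefficient.
#' @param voxel Truth for [gen_voxel_cohort()]: grid dims, voxel size (mm),
#'   effect-cluster centre/radius (voxels), effect size (Cohen's d of the
#'   voxelwise hit-miss difference), smoothing FWHM (voxels).
#' @param path Truth for [gen_beta_series()]: variables, edge list with
#'   coefficients, residual variances, trials per condition.
#' @param bold Truth for [gen_bold()]: TR (s), AR(1) coefficient, noise SD,
#'   drift amplitude.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20,
                          psychometric = list(),
                          pupil = list(),
                          voxel = list(),
                          path = list(),
                          bold = list()) {
  cfg <- list(
    n_subjects = n_subjects,
    psychometric = utils::modifyList(
      list(mu = 6, sigma_upper = 0.8, sigma_lower = 1.5,
           mu_sd = 0.5, log_sigma_sd = 0.15,
           impact_points = c(0, 3, 6, 12), trials_per_level = 50),
      psychometric),
    pupil = utils::modifyList(
      list(sampling_rate = 1000, time_range_ms = c(-200, 1500),
           latency_ms = 1100, width_ms = 150, amplitude = -0.8,
           ar1 = 0.95, noise_sd = 1, blink_rate = 0),
      pupil),
    voxel = utils::modifyList(
      list(dims = c(20, 20, 20), voxel_size_mm = 1.5,
           center = c(10, 10, 10), radius = 1.3, effect_d = 0.7,
           smooth_fwhm = 2),
      voxel),
    path = utils::modifyList(
      list(variables = c("SC", "vmPul", "VTA", "VC", "AttNet"),
           edges = list(c("SC", "vmPul", 0.6), c("SC", "VTA", 0.5),
                        c("SC", "VC", 0.4), c("vmPul", "VC", 0.3),
                        c("VTA", "VC", 0.2), c("VC", "AttNet", 0.5)),
           psi = c(1, 0.8, 0.8, 0.6, 0.7), trials_per_condition = 16),
      path),
    bold = utils::modifyList(
      list(tr = 2, ar1 = 0.3, noise_sd = 0.2, drift = 0.5), bold))
  class(cfg) <- "cohort_config"
  cfg
}

#' Synthetic hit/miss discrimination trials
#'
#' Bernoulli responses from the generating psychometric model
#' `P(hit | x) = 1 - Phi((x - mu) / sigma)` at the configured impact
#' points, with subject-level variation of `mu` and `log(sigma)` and a
#' field-specific `sigma` (finer discrimination in the upper field).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; same seed, same table.
#' @return Data frame with columns `subject`, `visual_field`,
#'   `impact_point_cm`, `response_hit`; per-subject truth in the
#'   `"truth"` attribute.
#' @export
gen_behavior <- function(config = cohort_config(n_subjects = 15), seed = 1) {
  ps <- config$psychometric
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (s in seq_len(config$n_subjects)) {
      mu_s <- ps$mu + rnorm(1, 0, ps$mu_sd)
      for (field in c("upper", "lower")) {
        sig0 <- if (field == "upper") ps$sigma_upper else ps$sigma_lower
        sig_s <- exp(log(sig0) + rnorm(1, 0, ps$log_sigma_sd))
        truth[[paste(s, field)]] <- c(mu = mu_s, sigma = sig_s)
        for (x in ps$impact_points) {
          p_hit <- 1 - pnorm((x - mu_s) / sig_s)
          rows[[length(rows) + 1]] <- data.frame(
            subject = s, visual_field = field, impact_point_cm = x,
            response_hit = rbinom(ps$trials_per_level, 1, p_hit))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

ar1_noise <- function(n, phi, sd) {
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(filter(innov, phi, method = "recursive"))
}

#' Synthetic per-subject pupil traces for two trajectory conditions
#'
#' Each subject-condition trace is AR(1) noise (emulating slow pupil
#' drift) plus, in the hit condition, a Gaussian-bump constriction of the
#' configured amplitude centred at the configured latency. Optional blink
#' gaps are injected as `NA` runs.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param n_subjects Override the config's subject count.
#' @return A list of class `pupil_cohort`: `hit` and `miss`
#'   (subjects-by-time matrices), `time` (ms).
#' @export
gen_pupil <- function(config = cohort_config(n_subjects = 15), seed = 1,
                      n_subjects = NULL) {
  pu <- config$pupil
  n <- n_subjects %||% config$n_subjects
  dt <- 1000 / pu$sampling_rate
  time <- seq(pu$time_range_ms[1], pu$time_range_ms[2], by = dt)
  TT <- length(time)
  bump <- exp(-(time - pu$latency_ms)^2 / (2 * pu$width_ms^2))
  with_seed(seed, {
    hit <- matrix(0, n, TT)
    miss <- matrix(0, n, TT)
    for (s in seq_len(n)) {
      hit[s, ] <- ar1_noise(TT, pu$ar1, pu$noise_sd) + pu$amplitude * bump
      miss[s, ] <- ar1_noise(TT, pu$ar1, pu$noise_sd)
      if (pu$blink_rate > 0) {
        for (cond in c("hit", "miss")) {
          n_blinks <- rpois(1, pu$blink_rate)
          if (n_blinks > 0) {
            starts <- sample(TT - 50, n_blinks)
            for (b in starts) {
              idx <- b:min(b + 49, TT)
              if (cond == "hit") hit[s, idx] <- NA else miss[s, idx] <- NA
            }
          }
        }
      }
    }
    structure(list(hit = hit, miss = miss, time = time),
              class = "pupil_cohort")
  })
}

## separable 3D Gaussian smoothing (FWHM in voxels), edge-renormalized
smooth_gaussian_3d <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  conv_along <- function(arr, axis) {
    ap <- aperm(arr, c(axis, setdiff(1:3, axis)))
    dm <- dim(ap)
    m <- matrix(ap, dm[1], dm[2] * dm[3])
    n <- dm[1]
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      okk <- src >= 1 & src <= n
      out[okk, ] <- out[okk, ] + k[j] * m[src[okk], , drop = FALSE]
      wt[okk] <- wt[okk] + k[j]
    }
    out <- out / wt
    ap <- array(out, dm)
    aperm(ap, order(c(axis, setdiff(1:3, axis))))
  }
  for (axis in 1:3) x <- conv_along(x, axis)
  x
}

## per-voxel variance of smooth_gaussian_3d applied to unit white noise:
## separable product of the 1D factors sum(k_valid^2) / sum(k_valid)^2
smooth_var_field <- function(dims, fwhm) {
  if (fwhm <= 0) return(array(1, dims))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  axis_factor <- function(n) {
    vapply(seq_len(n), function(i) {
      j <- seq(-half, half)
      ok <- i + j >= 1 & i + j <= n
      sum(k[ok]^2) / sum(k[ok])^2
    }, numeric(1))
  }
  f1 <- axis_factor(dims[1]); f2 <- axis_factor(dims[2])
  f3 <- axis_factor(dims[3])
  array(outer(outer(f1, f2), f3), dims)
}

#' Synthetic voxel cohort with a localized collision-sensitive cluster
#'
#' Per subject and condition, spatially smoothed Gaussian noise
#' (standardized to unit voxel variance); hit maps additionally receive
#' `+effect/2` and miss maps `-effect/2` inside a spherical cluster, with
#' `effect` scaled so the voxelwise hit-minus-miss difference has the
#' configured Cohen's d.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param n_subjects Override the config's subject count.
#' @return A list of class `voxel_cohort`: `hit`, `miss` (4D arrays
#'   `x*y*z*subject`), `diff`, `mask` (all TRUE), `cluster_mask` (the true
#'   effect cluster), `effect_d`.
#' @export
gen_voxel_cohort <- function(config = cohort_config(), seed = 1,
                             n_subjects = NULL) {
  vx <- config$voxel
  n <- n_subjects %||% config$n_subjects
  dims <- vx$dims
  if (any(vx$center - vx$radius < 1) || any(vx$center + vx$radius > dims)) {
    stop_domain("effect cluster must lie inside the grid")
  }
  coords <- arrayInd(seq_len(prod(dims)), dims)
  dist <- sqrt(colSums((t(coords) - vx$center)^2))
  cluster <- array(dist <= vx$radius, dims)
  effect <- vx$effect_d * sqrt(2)   # diff of two unit-variance conditions
  sd_field <- sqrt(smooth_var_field(dims, vx$smooth_fwhm))
  with_seed(seed, {
    hit <- array(0, c(dims, n))
    miss <- array(0, c(dims, n))
    for (s in seq_len(n)) {
      for (cond in c("hit", "miss")) {
        e <- smooth_gaussian_3d(array(rnorm(prod(dims)), dims),
                                vx$smooth_fwhm) / sd_field
        if (cond == "hit") {
          hit[, , , s] <- e + (effect / 2) * cluster
        } else {
          miss[, , , s] <- e - (effect / 2) * cluster
        }
      }
    }
    structure(list(hit = hit, miss = miss, diff = hit - miss,
                   mask = array(TRUE, dims), cluster_mask = cluster,
                   effect_d = vx$effect_d),
              class = "voxel_cohort")
  })
}

#' Synthetic multi-ROI beta series from a recursive path model
#'
#' Draws per-trial ROI vectors `x = (I - B)^-1 e`, `e ~ N(0, Psi)`, so the
#' population covariance is the model-implied `(I-B)^-1 Psi (I-B)^-T`.
#'
#' @param config A [cohort_config()] (uses its `path` truth), or pass `B`
#'   and `psi` directly.
#' @param seed Integer seed.
#' @param n_trials Total trials (rows); defaults to
#'   `2 * trials_per_condition`.
#' @param B Optional coefficient matrix (`B[to, from]`), overriding config.
#' @param psi Optional residual variances, overriding config.
#' @param variables Variable names when `B` is supplied.
#' @return Matrix `n_trials x p` with a `condition` column attribute
#'   (`"hit"`/`"miss"` alternating blocks) and the truth in attributes.
#' @export
gen_beta_series <- function(config = cohort_config(), seed = 1,
                            n_trials = NULL, B = NULL, psi = NULL,
                            variables = NULL) {
  if (is.null(B)) {
    pa <- config$path
    variables <- pa$variables
    p <- length(variables)
    B <- matrix(0, p, p, dimnames = list(variables, variables))
    for (e in pa$edges) B[e[2], e[1]] <- as.numeric(e[3])
    psi <- pa$psi
    if (is.null(n_trials)) n_trials <- 2 * pa$trials_per_condition
  } else {
    p <- nrow(B)
    if (is.null(variables)) variables <- colnames(B) %||%
        paste0("V", seq_len(p))
    if (is.null(n_trials)) n_trials <- 100
  }
  edges_df <- which(B != 0, arr.ind = TRUE)
  pm_edges <- lapply(seq_len(nrow(edges_df)), function(i)
    c(variables[edges_df[i, 2]], variables[edges_df[i, 1]]))
  if (!is_acyclic(variables, {
    e <- as.data.frame(do.call(rbind, pm_edges), stringsAsFactors = FALSE)
    if (nrow(e)) names(e) <- c("from", "to")
    e
  })) {
    stop_domain("generating coefficient matrix must be recursive (acyclic)")
  }
  IBinv <- solve(diag(p) - B)
  with_seed(seed, {
    E <- matrix(rnorm(n_trials * p), n_trials, p) %*% diag(sqrt(psi), p)
    X <- E %*% t(IBinv)
    colnames(X) <- variables
    attr(X, "condition") <- rep(c("hit", "miss"), length.out = n_trials)
    attr(X, "B") <- B
    attr(X, "psi") <- psi
    X
  })
}

#' Synthetic ROI BOLD time series with known trial amplitudes
#'
#' Per-trial amplitudes are convolved with the HRF and summed with AR(1)
#' noise and a slow cosine drift; the generating amplitudes are returned
#' alongside so GLM recovery can be checked.
#'
#' @param onsets Trial onsets in seconds.
#' @param amplitudes Per-trial response amplitudes (ground truth).
#' @param hrf An `hrf_model`.
#' @param config A [cohort_config()] (uses its `bold` noise settings).
#' @param seed Integer seed.
#' @param duration_s Total series duration; defaults to last onset + 20 s.
#' @param durations Event duration in seconds.
#' @return A list of class `bold_sim`: `y`, `onsets`, `amplitudes`, `tr`.
#' @export
gen_bold <- function(onsets, amplitudes, hrf = hrf_kernel(),
                     config = cohort_config(), seed = 1,
                     duration_s = NULL, durations = 0.33) {
  stopifnot(length(onsets) == length(amplitudes))
  bo <- config$bold
  if (is.null(duration_s)) duration_s <- max(onsets) + 20
  n_scans <- ceiling(duration_s / bo$tr)
  X <- build_design(as.list(onsets), durations, hrf, n_scans, bo$tr)
  signal <- as.numeric(X %*% amplitudes)
  t_scan <- (seq_len(n_scans) - 1) * bo$tr
  with_seed(seed, {
    noise <- if (bo$noise_sd > 0) ar1_noise(n_scans, bo$ar1, bo$noise_sd)
      else numeric(n_scans)
    drift <- bo$drift * cos(2 * pi * t_scan / (2 * duration_s))
    structure(list(y = signal + noise + drift, onsets = onsets,
                   amplitudes = amplitudes, tr = bo$tr),
              class = "bold_sim")
  })
}
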