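# Psychometric fitting of hit/miss discrimination and exact sign-flip
# permutation inference on paired sensitivities.

#' Maximum-likelihood psychometric fit (cumulative normal)
#'
#' Fits `P(hit | x) = 1 - Phi((x - mu) / sigma)` to binomial hit counts at
#' each impact-point offset by maximum likelihood: the probability of a
#' "hit" response falls from ~1 for impact points on the head to ~0 for
#' clear misses, with `mu` the offset at 50% hit responses and `sigma` the
#' discrimination spread. Optimization is bounded quasi-Newton on
#' `(mu, log sigma)` with multistart from moment estimates.
#'
#' @param impact_points Impact-point offsets in cm (>= 2 distinct values).
#' @param n_hit Hit-response counts per level.
#' @param n_total Trial counts per level (`n_hit <= n_total`).
#' @return An object of class `psychometric_fit`: `mu` (cm), `sigma` (cm),
#'   `sensitivity` = `log(1/sigma)`, `log_likelihood`, `n_trials`,
#'   `converged` and `identifiable`.
#' @export
fit_psychometric <- function(impact_points, n_hit, n_total) {
  stopifnot(length(impact_points) == length(n_hit),
            length(n_hit) == length(n_total))
  if (any(n_hit < 0) || any(n_total < n_hit)) {
    stop_domain("need 0 <= n_hit <= n_total")
  }
  ## merge duplicate levels so the fit is invariant to reordering/splitting
  key <- as.character(impact_points)
  x <- as.numeric(tapply(impact_points, key, `[`, 1))
  h <- as.numeric(tapply(n_hit, key, sum))
  n <- as.numeric(tapply(n_total, key, sum))
  ord <- order(x)
  x <- x[ord]; h <- h[ord]; n <- n[ord]
  if (length(unique(x)) < 2) stop_domain("need >= 2 distinct impact points")

  identifiable <- !(all(h == n) || all(h == 0))

  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- 1 - pnorm((x - mu) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(h * log(p) + (n - h) * log(1 - p))
  }

  span <- diff(range(x))
  lower <- c(min(x) - 2 * span, log(span * 1e-4))
  upper <- c(max(x) + 2 * span, log(span * 1e3))

  ## moment start: probit-scale linear fit of empirical proportions
  prop <- pmin(pmax((h + 0.5) / (n + 1), 0.01), 0.99)
  zq <- qnorm(1 - prop)
  cf <- tryCatch(coef(lm(zq ~ x)), error = function(e) c(0, 1 / span))
  sig0 <- if (is.finite(cf[2]) && cf[2] > 0) 1 / cf[2] else span / 2
  mu0 <- if (is.finite(cf[1])) -cf[1] * sig0 else mean(x)
  starts <- rbind(c(mu0, log(sig0)),
                  c(mean(x), log(span / 4)),
                  c(stats::weighted.mean(x, n), log(span)))
  starts[, 1] <- pmin(pmax(starts[, 1], lower[1]), upper[1])
  starts[, 2] <- pmin(pmax(starts[, 2], lower[2]), upper[2])

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], nll, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_domain("psychometric optimization failed")

  structure(
    list(mu = unname(best$par[1]), sigma = unname(exp(best$par[2])),
         sensitivity = unname(-best$par[2]),
         log_likelihood = -best$value,
         n_trials = setNames(n, x),
         converged = best$convergence == 0,
         identifiable = identifiable),
    class = "psychometric_fit")
}

#' Discrimination sensitivity of a psychometric fit
#'
#' The sensitivity statistic `log(1/sigma)`: larger values mean a steeper
#' psychometric function, i.e. finer discrimination of collision from
#' near-miss trajectories. (Sources sometimes typeset this as "ln(1 sigma)";
#' it is the natural log of the reciprocal standard deviation.)
#'
#' @param fit A `psychometric_fit`, or a positive numeric `sigma`.
#' @return `log(1/sigma)`, dimensionless.
#' @export
discrimination_sensitivity <- function(fit) {
  sigma <- if (inherits(fit, "psychometric_fit")) fit$sigma else fit
  if (any(sigma <= 0)) stop_domain("`sigma` must be > 0")
  log(1 / sigma)
}

## cache of {-1, +1}^(2^n x n) enumeration matrices, keyed by n
.perm_cache <- new.env(parent = emptyenv())

sign_matrix_exact <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  .perm_cache[[key]] <- m
  m
}

#' Exact (or Monte Carlo) sign-flip permutation test of paired differences
#'
#' Tests whether the mean of paired differences departs from zero by
#' building the permutation null over sign flips of each pair. When
#' `n <= max_exact_n` all `2^n` sign patterns are enumerated (exact test);
#' otherwise a seeded Monte Carlo sample of `n_draws` patterns is used.
#'
#' @param paired_differences Numeric vector of paired differences (n >= 2).
#' @param two_sided Two-sided test (default) or one-sided (upper).
#' @param max_exact_n Largest n for full enumeration.
#' @param n_draws Monte Carlo draws when enumeration is infeasible.
#' @param seed Seed for the Monte Carlo branch.
#' @return An object of class `permutation_test_result`: `observed_stat`
#'   (mean difference), `p_value`, `n_permutations`, `exact`, `seed`.
#' @export
exact_sign_permutation <- function(paired_differences, two_sided = TRUE,
                                   max_exact_n = 15, n_draws = 10000,
                                   seed = NULL) {
  d <- as.numeric(paired_differences)
  n <- length(d)
  if (n < 2) stop_domain("need n >= 2 paired differences")
  obs <- mean(d)
  exact <- n <= max_exact_n
  if (exact) {
    S <- sign_matrix_exact(n)
  } else {
    S <- with_seed(seed %||% 1L,
                   matrix(sample(c(-1, 1), n_draws * n, replace = TRUE),
                          n_draws, n))
  }
  null <- as.numeric(S %*% d) / n
  tol <- 1e-12 * max(1, abs(obs))
  p <- if (two_sided) {
    mean(abs(null) >= abs(obs) - tol)
  } else {
    mean(null >= obs - tol)
  }
  structure(list(observed_stat = obs, p_value = p,
                 n_permutations = nrow(S), exact = exact,
                 seed = if (exact) NULL else seed),
            class = "permutation_test_result")
}
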