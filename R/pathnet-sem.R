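# Path-model (SEM) machinery: model-space enumeration over alternative
# connections, maximum-likelihood fitting of recursive (and, where a
# combination closes a loop, nonrecursive) path models on observed beta
# series, fit indices, and the parsimony-filtered model selection rule.

#' Construct a path model
#'
#' A directed path model over observed variables: `x = B x + e`, with
#' `B[to, from]` the coefficient of the edge `from -> to`, diagonal
#' residual covariance for endogenous variables, and free covariances
#' among exogenous variables (those with no incoming edge).
#'
#' @param variables Character vector of variable (ROI) names.
#' @param edges Two-column matrix or list of `c(from, to)` directed edges.
#' @return An object of class `path_model` with `variables`, `edges`
#'   (data frame `from`, `to`), `recursive` flag, and a deterministic `id`.
#' @export
path_model <- function(variables, edges) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, edges)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) names(edges) <- c("from", "to")
  else edges <- data.frame(from = character(0), to = character(0))
  stopifnot(all(unlist(edges) %in% variables))
  key <- paste(edges$from, edges$to, sep = "->")
  if (anyDuplicated(key)) stop_domain("duplicate edges in model")
  id <- paste(sort(key), collapse = ";")
  if (id == "") id <- "(empty)"
  structure(list(variables = variables, edges = edges,
                 recursive = is_acyclic(variables, edges), id = id),
            class = "path_model")
}

is_acyclic <- function(variables, edges) {
  remaining <- variables
  e <- edges
  repeat {
    if (length(remaining) == 0) return(TRUE)
    sinks_ok <- setdiff(remaining, e$to)
    if (length(sinks_ok) == 0) return(FALSE)
    remaining <- setdiff(remaining, sinks_ok)
    e <- e[e$from %in% remaining & e$to %in% remaining, , drop = FALSE]
  }
}

#' Model-space specification over alternative connections
#'
#' Defines the candidate path-model space: `common_edges` appear in every
#' model; each two-option slot contributes a connection in one of its two
#' directions; each three-option slot contributes a connection in one of
#' its two directions or is absent.
#'
#' @param variables Character vector of variable names.
#' @param common_edges List of `c(from, to)` fixed edges.
#' @param two_option_slots List of `c(a, b)` pairs (direction free).
#' @param three_option_slots List of `c(a, b)` pairs (direction free or
#'   absent).
#' @return An object of class `model_space_spec`.
#' @export
model_space_spec <- function(variables, common_edges = list(),
                             two_option_slots = list(),
                             three_option_slots = list()) {
  all_pairs <- c(common_edges, two_option_slots, three_option_slots)
  stopifnot(all(unlist(all_pairs) %in% variables))
  unordered <- vapply(all_pairs, function(p) paste(sort(p), collapse = "~"),
                      character(1))
  if (anyDuplicated(unordered)) {
    stop_domain("a connection appears in more than one slot")
  }
  structure(list(variables = variables, common_edges = common_edges,
                 two_option_slots = two_option_slots,
                 three_option_slots = three_option_slots),
            class = "model_space_spec")
}

#' Default model space for the subcortical/cortical collision network
#'
#' Five ROIs — superior colliculus (SC), ventromedial pulvinar (vmPul),
#' ventral tegmental area (VTA), visual cortex (VC) and frontoparietal
#' attention network (AttNet) — with fixed tectofugal edges SC->vmPul and
#' SC->VTA, direction-free connections of SC/vmPul/VTA with VC, and
#' optional direction-free connections of vmPul/VTA/VC with AttNet. Three
#' two-option and three three-option slots give `2^3 * 3^3 = 216`
#' candidate models. The slot assignment is a reconstruction from the
#' anatomical candidate connections (tectocortical, pulvinocortical and
#' mesocortical projections are bidirectional candidates; attention-network
#' links may be absent) and is fully overridable.
#'
#' @return A `model_space_spec` with 216 combinations.
#' @export
default_model_space <- function() {
  model_space_spec(
    variables = c("SC", "vmPul", "VTA", "VC", "AttNet"),
    common_edges = list(c("SC", "vmPul"), c("SC", "VTA")),
    two_option_slots = list(c("SC", "VC"), c("vmPul", "VC"),
                            c("VTA", "VC")),
    three_option_slots = list(c("vmPul", "AttNet"), c("VTA", "AttNet"),
                              c("VC", "AttNet")))
}

#' Enumerate all models of a model space
#'
#' Cartesian product over the slots: every model contains all common edges
#' plus one choice per slot. Each model carries a `recursive` flag; models
#' that close a directed loop are kept by default (they are well-defined
#' ML problems) and counted in the `n_cyclic` attribute, or dropped with
#' `drop_cyclic = TRUE`.
#'
#' @param spec A `model_space_spec`.
#' @param drop_cyclic Drop non-recursive combinations.
#' @return List of `path_model`s; attributes `n_cyclic` (count of cyclic
#'   combinations found) and `n_total` (combinations before dropping).
#' @export
enumerate_model_space <- function(spec, drop_cyclic = FALSE) {
  stopifnot(inherits(spec, "model_space_spec"))
  slot_opts <- c(
    lapply(spec$two_option_slots,
           function(p) list(c(p[1], p[2]), c(p[2], p[1]))),
    lapply(spec$three_option_slots,
           function(p) list(c(p[1], p[2]), c(p[2], p[1]), NULL)))
  if (length(slot_opts) == 0) {
    grid <- matrix(integer(0), nrow = 1)
  } else {
    grid <- as.matrix(expand.grid(lapply(slot_opts, seq_along)))
  }
  models <- vector("list", nrow(grid))
  for (m in seq_len(nrow(grid))) {
    edges <- spec$common_edges
    for (s in seq_along(slot_opts)) {
      choice <- slot_opts[[s]][[grid[m, s]]]
      if (!is.null(choice)) edges <- c(edges, list(choice))
    }
    models[[m]] <- path_model(spec$variables, edges)
  }
  n_cyclic <- sum(!vapply(models, `[[`, logical(1), "recursive"))
  n_total <- length(models)
  if (drop_cyclic) models <- Filter(function(m) m$recursive, models)
  attr(models, "n_cyclic") <- n_cyclic
  attr(models, "n_total") <- n_total
  models
}

## internal parameter bookkeeping for one model
model_structure <- function(model) {
  vars <- model$variables
  p <- length(vars)
  e <- model$edges
  from_i <- match(e$from, vars)
  to_i <- match(e$to, vars)
  exog <- setdiff(seq_len(p), unique(to_i))
  exog_pairs <- if (length(exog) >= 2) t(combn(exog, 2)) else
    matrix(integer(0), 0, 2)
  list(p = p, n_edges = nrow(e), from_i = from_i, to_i = to_i,
       exog = exog, exog_pairs = exog_pairs,
       n_free = nrow(e) + p + nrow(exog_pairs))
}

theta_to_matrices <- function(theta, st) {
  B <- matrix(0, st$p, st$p)
  if (st$n_edges) {
    B[cbind(st$to_i, st$from_i)] <- theta[seq_len(st$n_edges)]
  }
  Psi <- diag(exp(theta[st$n_edges + seq_len(st$p)]), st$p)
  npair <- nrow(st$exog_pairs)
  if (npair) {
    off <- theta[st$n_edges + st$p + seq_len(npair)]
    for (k in seq_len(npair)) {
      i <- st$exog_pairs[k, 1]; j <- st$exog_pairs[k, 2]
      Psi[i, j] <- Psi[j, i] <- off[k]
    }
  }
  list(B = B, Psi = Psi)
}

implied_sigma <- function(B, Psi) {
  IB <- diag(nrow(B)) - B
  inv <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  inv %*% Psi %*% t(inv)
}

## ML discrepancy F = log det Sigma - log det S + tr(S Sigma^-1) - p
fml_discrepancy <- function(Sigma, S) {
  p <- nrow(S)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet_sigma <- 2 * sum(log(diag(ch)))
  inv <- chol2inv(ch)
  logdet_s <- determinant(S, logarithm = TRUE)$modulus
  as.numeric(logdet_sigma - logdet_s + sum(S * inv) - p)
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma| - log|S| + tr(S Sigma^-1) - p` over the free path
#' coefficients `B`, log residual variances, and exogenous covariances,
#' with implied covariance `Sigma = (I - B)^-1 Psi (I - B)^-T`. Quasi-Newton
#' (BFGS) from `B = 0`, `Psi = diag(S)`, with jittered restarts on failure.
#' At the optimum, `chi^2 = (N - 1) F` and the standard fit-index bundle is
#' computed (CFI against the independence baseline, GFI/AGFI/PGFI, RMSEA,
#' RMR over the lower triangle including the diagonal).
#'
#' @param model A `path_model`.
#' @param data Observations-by-variables matrix (column order matched to
#'   `model$variables` by name when named); or supply `S` and `n_obs`.
#' @param S Sample covariance (positive definite), if `data` is not given.
#' @param n_obs Number of observations N.
#' @param n_restarts Jittered restarts attempted after a failed start.
#' @return An object of class `fitted_path_model`: `model`, `B`, `Psi`,
#'   `coefficients` (from, to, estimate, se, z, p), `fit_indices` (chi2,
#'   df, CFI, GFI, AGFI, PGFI, RMSEA, RMR), `F_ml`, `converged`, `n_obs`.
#' @export
fit_path_model <- function(model, data = NULL, S = NULL, n_obs = NULL,
                           n_restarts = 5) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$variables
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (!is.null(colnames(data))) data <- data[, vars, drop = FALSE]
    S <- cov(data)
    n_obs <- nrow(data)
  }
  if (is.null(S) || is.null(n_obs)) stop_domain("supply `data` or `S`+`n_obs`")
  S <- unname(as.matrix(S))
  p <- length(vars)
  stopifnot(nrow(S) == p)
  if (inherits(tryCatch(chol(S), error = function(e) e), "error")) {
    stop_domain("sample covariance is not positive definite")
  }
  st <- model_structure(model)
  df <- p * (p + 1) / 2 - st$n_free
  if (df < 0) stop_domain("model has negative degrees of freedom")

  objective <- function(theta) {
    m <- theta_to_matrices(theta, st)
    Sigma <- implied_sigma(m$B, m$Psi)
    if (is.null(Sigma)) return(1e10)
    f <- fml_discrepancy(Sigma, S)
    if (!is.finite(f)) return(1e10)
    f
  }

  start0 <- c(rep(0, st$n_edges), log(diag(S)),
              if (nrow(st$exog_pairs)) S[st$exog_pairs] else numeric(0))
  best <- NULL
  set_jitter <- function(k) {
    if (k == 1) return(start0)
    start0 + rnorm(length(start0), sd = 0.2)
  }
  for (k in seq_len(n_restarts)) {
    th0 <- with_seed(if (k == 1) NULL else k, set_jitter(k))
    fit <- tryCatch(
      optim(th0, objective, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    if (!is.null(best) && best$convergence == 0 && best$value < 1e9) break
  }
  if (is.null(best)) stop_domain("path-model optimization failed")
  converged <- best$convergence == 0 && best$value < 1e9

  m <- theta_to_matrices(best$par, st)
  Sigma <- implied_sigma(m$B, m$Psi)
  F_ml <- max(0, best$value)
  chi2 <- (n_obs - 1) * F_ml

  ## standard errors from the observed information of (N-1)/2 * F
  se <- rep(NA_real_, st$n_free)
  H <- tryCatch(optimHess(best$par, function(th)
    (n_obs - 1) / 2 * objective(th)), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  est_b <- best$par[seq_len(st$n_edges)]
  se_b <- se[seq_len(st$n_edges)]
  coefs <- data.frame(from = model$edges$from, to = model$edges$to,
                      estimate = est_b, se = se_b, z = est_b / se_b,
                      p = 2 * pnorm(-abs(est_b / se_b)))

  fi <- fit_indices(chi2, df, S, Sigma, n_obs)
  structure(list(model = model, B = m$B, Psi = m$Psi,
                 coefficients = coefs, fit_indices = fi, F_ml = F_ml,
                 converged = converged, n_obs = n_obs, S = S,
                 Sigma = Sigma),
            class = "fitted_path_model")
}

#' Fit-index bundle for a fitted covariance structure
#'
#' Standard definitions: CFI against the independence (diagonal) baseline;
#' `GFI = 1 - tr((Sigma^-1 S - I)^2) / tr((Sigma^-1 S)^2)`;
#' `AGFI = 1 - [p(p+1)/(2 df)] (1 - GFI)`;
#' `PGFI = [df / (p(p+1)/2)] GFI`;
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (N-1)))`;
#' `RMR` = root mean square of the residual `S - Sigma` over the lower
#' triangle including the diagonal.
#'
#' @param chi2 Model chi-square.
#' @param df Model degrees of freedom.
#' @param S Sample covariance.
#' @param Sigma Implied covariance.
#' @param n_obs Number of observations.
#' @return List of class `fit_indices`: `chi2`, `df`, `CFI`, `GFI`,
#'   `AGFI`, `PGFI`, `RMSEA`, `RMR`.
#' @export
fit_indices <- function(chi2, df, S, Sigma, n_obs) {
  p <- nrow(S)
  ## independence baseline: diagonal Sigma
  f_base <- fml_discrepancy(diag(diag(S), p), S)
  chi2_b <- (n_obs - 1) * max(0, f_base)
  df_b <- p * (p - 1) / 2
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom > 0) 1 - max(chi2 - df, 0) / denom else 1
  cfi <- min(max(cfi, 0), 1)

  W <- solve(Sigma) %*% S
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) / sum(diag(W %*% W))
  gfi <- min(max(gfi, 0), 1)
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  pgfi <- df / (p * (p + 1) / 2) * gfi
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n_obs - 1))) else 0
  lt <- lower.tri(S, diag = TRUE)
  rmr <- sqrt(mean((S - Sigma)[lt]^2))
  structure(list(chi2 = chi2, df = df, CFI = cfi, GFI = gfi, AGFI = agfi,
                 PGFI = pgfi, RMSEA = rmsea, RMR = rmr),
            class = "fit_indices")
}

#' Select the best-fitting path model
#'
#' The selection rule: exclude models with `PGFI > pgfi_max` (parsimony
#' filter), rank the survivors by AGFI (descending), and pick the top
#' model. Alternate rankings (chi2, CFI, GFI, RMSEA, RMR) are also
#' computed and the result reports whether the winner is invariant to the
#' ranking method. Non-converged fits rank last; exact ties break
#' lexicographically on the model id and are flagged.
#'
#' @param fits List of `fitted_path_model`s.
#' @param pgfi_max PGFI exclusion threshold.
#' @return A list of class `model_selection`: `best` (fitted model),
#'   `ranking` (data frame over surviving models), `ranking_invariant`,
#'   `tie` flag, `n_excluded`.
#' @export
select_best_model <- function(fits, pgfi_max = 0.1) {
  if (length(fits) == 0) stop_domain("no fitted models supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "fitted_path_model")))
  tab <- do.call(rbind, lapply(fits, function(f) {
    fi <- f$fit_indices
    data.frame(id = f$model$id, chi2 = fi$chi2, df = fi$df, CFI = fi$CFI,
               GFI = fi$GFI, AGFI = fi$AGFI, PGFI = fi$PGFI,
               RMSEA = fi$RMSEA, RMR = fi$RMR, converged = f$converged)
  }))
  keep <- which(tab$PGFI <= pgfi_max)
  if (length(keep) == 0) {
    stop_domain("all models excluded by the PGFI filter; ",
                "review `pgfi_max` or the model space")
  }
  sub <- tab[keep, , drop = FALSE]
  sub_fits <- fits[keep]

  rank_key <- function(metric, decreasing) {
    v <- sub[[metric]]
    v[!sub$converged] <- if (decreasing) -Inf else Inf
    order(if (decreasing) -v else v, sub$id)
  }
  ord <- rank_key("AGFI", TRUE)
  best_i <- ord[1]
  tie <- sum(sub$AGFI == sub$AGFI[best_i] & sub$converged, na.rm = TRUE) > 1

  winners <- c(AGFI = sub$id[best_i],
               chi2 = sub$id[rank_key("chi2", FALSE)[1]],
               CFI = sub$id[rank_key("CFI", TRUE)[1]],
               GFI = sub$id[rank_key("GFI", TRUE)[1]],
               RMSEA = sub$id[rank_key("RMSEA", FALSE)[1]],
               RMR = sub$id[rank_key("RMR", FALSE)[1]])
  structure(list(best = sub_fits[[best_i]],
                 ranking = sub[ord, , drop = FALSE],
                 ranking_invariant = all(winners == winners[["AGFI"]]),
                 winners_by_metric = winners,
                 tie = tie, n_excluded = nrow(tab) - length(keep)),
            class = "model_selection")
}
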