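# Independent oracles used by the tests. These never call the package's
# numerical fitting paths: the SEM oracle is the closed-form ML solution
# for recursive path models (per-equation OLS on the sample covariance),
# with all fit indices recomputed from scratch.

## Closed-form ML fit of a recursive path model with diagonal residual
## covariance: per-equation OLS read directly off S; exogenous covariances
## saturated. Returns B, Psi, F_ml, chi2 and the index bundle.
oracle_path_fit <- function(variables, edges, S, n_obs) {
  p <- length(variables)
  S <- unname(as.matrix(S))
  B <- matrix(0, p, p)
  Psi <- matrix(0, p, p)
  endo <- unique(edges$to)
  for (v in variables) {
    i <- match(v, variables)
    pa <- match(edges$from[edges$to == v], variables)
    if (length(pa)) {
      b <- solve(S[pa, pa, drop = FALSE], S[pa, i])
      B[i, pa] <- b
      Psi[i, i] <- S[i, i] - as.numeric(S[i, pa, drop = FALSE] %*% b)
    } else {
      Psi[i, i] <- S[i, i]
    }
  }
  exog <- setdiff(seq_len(p), match(endo, variables))
  if (length(exog) > 1) Psi[exog, exog] <- S[exog, exog]
  IBi <- solve(diag(p) - B)
  Sigma <- IBi %*% Psi %*% t(IBi)
  F_ml <- as.numeric(log(det(Sigma)) - log(det(S)) +
                       sum(diag(S %*% solve(Sigma))) - p)
  F_ml <- max(0, F_ml)
  n_free <- nrow(edges) + p + choose(length(exog), 2)
  df <- p * (p + 1) / 2 - n_free
  chi2 <- (n_obs - 1) * F_ml

  ## independent recomputation of the index bundle
  F_b <- as.numeric(sum(log(diag(S))) - log(det(S)))
  chi2_b <- (n_obs - 1) * max(0, F_b)
  df_b <- p * (p - 1) / 2
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom > 0) min(max(1 - max(chi2 - df, 0) / denom, 0), 1) else 1
  W <- solve(Sigma) %*% S
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) /
    sum(diag(W %*% W))
  gfi <- min(max(gfi, 0), 1)
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  pgfi <- df / (p * (p + 1) / 2) * gfi
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n_obs - 1))) else 0
  lt <- lower.tri(S, diag = TRUE)
  rmr <- sqrt(mean((S - Sigma)[lt]^2))
  list(B = B, Psi = Psi, F_ml = F_ml, chi2 = chi2, df = df,
       CFI = cfi, GFI = gfi, AGFI = agfi, PGFI = pgfi,
       RMSEA = rmsea, RMR = rmr)
}

## Random recursive path model over p variables: edges only from lower to
## higher topological index, each present with probability `density`.
random_recursive_model <- function(p, density = 0.5, seed = 1) {
  vars <- paste0("V", seq_len(p))
  set.seed(seed)
  edges <- list()
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < density) {
        edges[[length(edges) + 1]] <- c(vars[i], vars[j])
        B[j, i] <- runif(1, -0.6, 0.6)
      }
    }
  }
  if (length(edges) == 0) {
    edges <- list(c(vars[1], vars[2]))
    B[2, 1] <- 0.5
  }
  list(variables = vars, edges = edges, B = B,
       psi = runif(p, 0.5, 1.5))
}

## Small five-ROI model space (one two-option and one three-option slot)
## whose competitor models are not covariance-equivalent to the truth;
## used by the selection-recovery experiments.
selection_demo_space <- function() {
  model_space_spec(
    variables = c("SC", "vmPul", "VTA", "VC", "AttNet"),
    common_edges = list(c("SC", "vmPul"), c("SC", "VTA"), c("SC", "VC"),
                        c("VTA", "VC"), c("vmPul", "AttNet"),
                        c("VTA", "AttNet")),
    two_option_slots = list(c("vmPul", "VC")),
    three_option_slots = list(c("VC", "AttNet")))
}

selection_demo_truth <- function() {
  vars <- c("SC", "vmPul", "VTA", "VC", "AttNet")
  B <- matrix(0, 5, 5, dimnames = list(vars, vars))
  B["vmPul", "SC"] <- 0.6
  B["VTA", "SC"] <- 0.5
  B["VC", "SC"] <- 0.35
  B["VC", "VTA"] <- 0.3
  B["VC", "vmPul"] <- 0.4
  B["AttNet", "vmPul"] <- 0.3
  B["AttNet", "VTA"] <- 0.25
  B["AttNet", "VC"] <- 0.5
  list(B = B, psi = c(1, 0.8, 0.8, 0.6, 0.7),
       id = path_model(vars, list(
         c("SC", "vmPul"), c("SC", "VTA"), c("SC", "VC"),
         c("VTA", "VC"), c("vmPul", "VC"), c("vmPul", "AttNet"),
         c("VTA", "AttNet"), c("VC", "AttNet")))$id)
}

## Exp-2-style hit / near-miss trajectory pair, centroid-aligned.
exp2_aligned_paths <- function() {
  hit <- trajectory_spec(8.75, 0.75, 24, 0.65, 0.38,
                         impact_lateral_offset = 0,
                         sphere_diameter = 0.06, quadrant = "UR")
  miss <- trajectory_spec(8.75, 0.75, 24, 0.65, 0.38,
                          impact_lateral_offset = 0.06,
                          sphere_diameter = 0.06, quadrant = "UR")
  align_by_centroid(list(hit = project_trajectory(hit),
                         miss = project_trajectory(miss)))
}
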