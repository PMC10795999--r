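# Voxel-grid cluster statistics: connected-component labelling, group
# t-maps, and the cluster-mass permutation test with small-volume
# correction.

## Label connected components among `idx` (linear indices into a 3D grid of
## dims `dims`) with face (6), edge (18) or corner (26) connectivity.
## Returns an integer label per element of idx (labels start at 1).
label_components_3d <- function(idx, dims, connectivity = 6) {
  n <- length(idx)
  if (n == 0) return(integer(0))
  offs <- connectivity_offsets(connectivity)
  coord <- arrayInd(idx, dims)
  lookup <- integer(prod(dims))  # dense map: linear index -> position in idx
  lookup[idx] <- seq_len(n)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ## vectorized neighbour pairs: for each offset, shift all coords at once
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
      (nb[ok, 3] - 1) * dims[1] * dims[2]
    j <- lookup[lin]
    ii <- which(ok)[j > 0]
    jj <- j[j > 0]
    for (m in seq_along(ii)) {
      ri <- find(ii[m]); rj <- find(jj[m])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

connectivity_offsets <- function(connectivity) {
  all_off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dimnames(all_off) <- NULL
  nz <- rowSums(abs(all_off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
                 stop_domain("connectivity must be 6, 18 or 26"))
  all_off[keep, , drop = FALSE]
}

## clusters (member indices + mass) from a t-map restricted to mask voxels.
## t_vals: t per mask voxel; mask_idx: linear indices of mask voxels.
clusters_from_t <- function(t_vals, mask_idx, dims, tcrit, connectivity) {
  supra <- which(abs(t_vals) > tcrit)
  if (length(supra) == 0) {
    return(list(masses = numeric(0), members = list()))
  }
  lab <- label_components_3d(mask_idx[supra], dims, connectivity)
  masses <- as.numeric(tapply(abs(t_vals[supra]), lab, sum))
  members <- split(mask_idx[supra], lab)
  ord <- order(masses, decreasing = TRUE)
  list(masses = masses[ord], members = members[ord])
}

#' Cluster-mass permutation test with small-volume correction
#'
#' Family-wise inference on the group hit-minus-miss map restricted to an
#' ROI mask. The observed map is the one-sample t across subjects at each
#' mask voxel; clusters are face-connected sets of voxels exceeding the
#' cluster-defining threshold (two-sided voxel `p < cluster_alpha`), scored
#' by cluster mass (sum of |t|). The null flips each subject's condition
#' labels at random (a sign flip of the subject difference map) after
#' subtracting the group-average map from every subject (demeaning);
#' permutations flipping fewer than 15% or more than 85% of subjects are
#' discarded; the maximum cluster mass of each kept permutation forms the
#' null. `cluster_p` is the proportion of the kept null at or above the
#' observed mass (with the add-one convention so p is in (0, 1]).
#'
#' @param subject_diff_maps 4D array `x * y * z * subject` of per-subject
#'   hit-minus-miss maps (>= 5 subjects), or a subjects-by-voxels matrix
#'   with `dims` supplied.
#' @param roi_mask Logical 3D array (the small volume); default all voxels.
#' @param n_permutations Number of kept permutations (default 10000).
#' @param cluster_alpha Two-sided cluster-defining voxel alpha.
#' @param exchange_bounds Inclusive bounds on the flipped-subject fraction.
#' @param seed Seed for the permutation draw.
#' @param connectivity Voxel connectivity: 6 (default), 18 or 26.
#' @param dims Grid dims when `subject_diff_maps` is a matrix.
#' @return An object of class `voxel_cluster_result`: `clusters` (list of
#'   member linear indices), `cluster_mass`, `cluster_p`, `null_max_mass`,
#'   `n_permutations_kept`, `cluster_defining_alpha`, `t_map` (3D array,
#'   NA outside the mask).
#' @export
cluster_mass_permutation_svc <- function(subject_diff_maps, roi_mask = NULL,
                                         n_permutations = 10000,
                                         cluster_alpha = 0.05,
                                         exchange_bounds = c(0.15, 0.85),
                                         seed = NULL, connectivity = 6,
                                         dims = NULL) {
  if (is.matrix(subject_diff_maps)) {
    if (is.null(dims)) stop_domain("`dims` required with matrix input")
    X <- subject_diff_maps
  } else {
    d4 <- dim(subject_diff_maps)
    dims <- d4[1:3]
    X <- t(matrix(subject_diff_maps, prod(dims), d4[4]))
  }
  n <- nrow(X)
  if (n < 5) stop_domain("need >= 5 subjects")
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dims)
  mask_idx <- which(as.logical(roi_mask))
  if (length(mask_idx) == 0) stop_domain("ROI mask is empty")
  X <- X[, mask_idx, drop = FALSE]
  if (any(!is.finite(X))) stop_domain("non-finite values inside the mask")
  tcrit <- qt(1 - cluster_alpha / 2, df = n - 1)

  t_obs <- as.numeric(signflip_t_matrix(matrix(1, 1, n), X))
  obs <- clusters_from_t(t_obs, mask_idx, dims, tcrit, connectivity)

  ## null: demean, then sign-flip subsets within the exchange bounds
  Xd <- sweep(X, 2, colMeans(X))
  lo <- ceiling(exchange_bounds[1] * n)
  hi <- floor(exchange_bounds[2] * n)
  if (lo > hi) stop_domain("exchange bounds leave no admissible permutation")
  S <- with_seed(seed %||% 1L, {
    draws <- matrix(sample(c(-1L, 1L), 4 * n_permutations * n,
                           replace = TRUE), ncol = n)
    keep <- rowSums(draws == -1L) >= lo & rowSums(draws == -1L) <= hi
    draws <- draws[keep, , drop = FALSE]
    while (nrow(draws) < n_permutations) {
      more <- matrix(sample(c(-1L, 1L), 2 * n_permutations * n,
                            replace = TRUE), ncol = n)
      mkeep <- rowSums(more == -1L) >= lo & rowSums(more == -1L) <= hi
      draws <- rbind(draws, more[mkeep, , drop = FALSE])
    }
    draws[seq_len(n_permutations), , drop = FALSE]
  })
  Tp <- signflip_t_matrix(S, Xd)
  supra_p <- abs(Tp) > tcrit
  null_max <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    s <- which(supra_p[p, ])
    if (length(s)) {
      lab <- label_components_3d(mask_idx[s], dims, connectivity)
      null_max[p] <- max(tapply(abs(Tp[p, s]), lab, sum))
    }
  }
  cluster_p <- vapply(obs$masses, function(m) {
    (1 + sum(null_max >= m)) / (1 + n_permutations)
  }, numeric(1))

  t_map <- array(NA_real_, dims)
  t_map[mask_idx] <- t_obs
  structure(list(clusters = obs$members, cluster_mass = obs$masses,
                 cluster_p = cluster_p, null_max_mass = null_max,
                 n_permutations_kept = n_permutations,
                 cluster_defining_alpha = cluster_alpha,
                 connectivity = connectivity, t_map = t_map, seed = seed),
            class = "voxel_cluster_result")
}
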