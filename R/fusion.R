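# Consensus-graph learning: self-tuned view weights, the weighted fusion
# update of the consensus graph Z, and the fused spectral embedding U.

#' Self-tuned view weights
#'
#' Inverse-distance weighting: each view's weight is
#' `w_v = 1 / (2 ||Z - S_v||_F^e)` with exponent `e = 1` by default, so views
#' whose graphs sit closer to the consensus in Frobenius norm contribute
#' more.  This is the self-weighting fixed point of the fusion objective:
#' re-deriving the weights from the current consensus reproduces an implicit
#' `sum_v ||Z - S_v||_F` objective.  Distances below `1e-12` are floored so a
#' view identical to the consensus gets the largest finite weight.
#'
#' @param z consensus affinity matrix.
#' @param views list of per-view affinity matrices (same dimension as `z`).
#' @param exponent 1 (default) or 2, the power on the Frobenius distance.
#' @return numeric vector of positive weights, one per view.
#' @export
update_weights <- function(z, views, exponent = 1) {
  if (!exponent %in% c(1, 2)) stop("weight exponent must be 1 or 2")
  vapply(views, function(s) {
    dist <- sqrt(sum((z - s)^2))
    dist <- max(dist, 1e-12)
    1 / (2 * dist^exponent)
  }, numeric(1))
}

#' Weighted consensus-graph update
#'
#' Per column `j`, minimizes
#' `sum_v w_v ||z_j - s_j^v||^2 + beta sum_i q_ij z_ij`
#' over the zero-diagonal simplex, where `q_ij` are squared distances between
#' rows of the fused embedding.  The closed form is the simplex projection of
#' the weighted average of the view columns shifted by the embedding penalty:
#' `project( (sum_v w_v s_j^v - (beta/2) q_j) / sum_v w_v )`.
#'
#' @param views list of per-view affinity matrices.
#' @param weights positive view weights.
#' @param q n x n penalty matrix from [embedding_distances()] of the fused
#'   embedding.
#' @param beta nonnegative rank-constraint strength.
#' @return n x n consensus affinity matrix (columns on the simplex, zero
#'   diagonal; sparsity emerges from the projection, no k-truncation).
#' @export
update_consensus <- function(views, weights, q, beta) {
  if (beta < 0) stop("beta must be nonnegative")
  if (length(weights) != length(views) || any(weights <= 0) ||
      any(!is.finite(weights)))
    stop("weights must be positive and finite, one per view")
  n <- nrow(views[[1]])
  wsum <- sum(weights)
  avg <- matrix(0, n, n)
  for (v in seq_along(views)) avg <- avg + weights[v] * views[[v]]
  target <- (avg - (beta / 2) * q) / wsum
  z <- matrix(0, n, n)
  for (j in seq_len(n)) {
    z[, j] <- project_capped_simplex(target[, j], forbidden_index = j)
  }
  z
}

#' Fused embedding of the consensus graph
#'
#' The `c` eigenvectors of the consensus Laplacian with smallest eigenvalues;
#' identical to [update_embedding()] applied to [build_laplacian()] of `z`.
#'
#' @param z consensus affinity matrix.
#' @param c embedding dimension (target cluster count).
#' @return n x c matrix with orthonormal columns.
#' @export
update_fused_embedding <- function(z, c) {
  update_embedding(build_laplacian(z), c)
}
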