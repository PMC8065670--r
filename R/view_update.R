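# Per-view alternating updates: the spectral embedding of a view's Laplacian
# and the closed-form affinity update that trades the embedding geometry
# against agreement with the consensus graph.

#' Spectral embedding from a graph Laplacian
#'
#' The n x c matrix `F` with orthonormal columns minimizing `Tr(F' L F)`; by
#' the Ky Fan theorem the minimum equals the sum of the `c` smallest
#' eigenvalues of `L`, attained by the corresponding eigenvectors.
#'
#' Eigenvectors are ordered by ascending eigenvalue and each is given a fixed
#' sign convention (its largest-magnitude entry is positive) so repeated runs
#' produce identical output.  When the c-th eigenvalue is repeated the
#' spanned subspace is not unique; the deterministic solver then picks one
#' fixed representative.
#'
#' @param lap Laplacian from [build_laplacian()], or a symmetric matrix.
#' @param c number of embedding dimensions (target cluster count).
#' @return n x c matrix with orthonormal columns.
#' @export
update_embedding <- function(lap, c) {
  l <- if (is.list(lap)) lap$matrix else lap
  n <- nrow(l)
  if (c > n)
    stop("embedding dimension c = ", c, " exceeds n = ", n)
  es <- eigen(l, symmetric = TRUE)   # eigenvalues in decreasing order
  if (any(!is.finite(es$values)))
    stop("eigendecomposition failed: non-finite eigenvalues")
  idx <- seq(n, n - c + 1)           # the c smallest, ascending
  f <- es$vectors[, idx, drop = FALSE]
  # fixed sign: largest-magnitude entry of each eigenvector positive
  for (jj in seq_len(ncol(f))) {
    piv <- which.max(abs(f[, jj]))
    if (f[piv, jj] < 0) f[, jj] <- -f[, jj]
  }
  f
}

#' Pairwise squared distances between embedding rows
#'
#' `p_ij = ||f_i - f_j||^2` for rows `f_i` of the embedding; symmetric with
#' zero diagonal.  These penalties drive the affinity updates through the
#' identity `Tr(F' L F) = (1/2) sum_ij p_ij s_ij`.
#'
#' @param f n x c embedding matrix.
#' @return n x n symmetric nonnegative matrix.
#' @export
embedding_distances <- function(f) {
  p <- sq_col_dists(t(f))
  (p + t(p)) / 2
}

#' Closed-form affinity update for one view
#'
#' Re-learns a view's k-sparse affinity graph given the view's embedding
#' penalties `p`, the consensus graph `z` and the view weight `w`.  Per
#' column `j` it minimizes
#' `sum_i p_ij s_ij + alpha s_ij^2 + w (z_ij - s_ij)^2`
#' over the zero-diagonal simplex, with the per-column `alpha` chosen
#' implicitly so the column has exactly `k` nonzeros.  Candidates are ranked
#' by the effective cost `p_ij/2 - w z_ij` (ascending, ties broken by index)
#' and the solution is the thresholded form supported on the k best.
#'
#' @param p n x n symmetric penalty matrix (squared embedding distances).
#' @param z n x n consensus affinity graph.
#' @param w positive view weight.
#' @param k neighbor count, `1 <= k <= n - 2`.
#' @return n x n affinity matrix with attribute `delta` (per-column n-vector
#'   of the implicit `alpha + w` scale).
#' @export
update_affinity <- function(p, z, w, k) {
  n <- nrow(p)
  if (w <= 0) stop("view weight must be positive")
  if (k < 1 || k > n - 2)
    stop("k must satisfy 1 <= k <= n - 2 (got k = ", k, ", n = ", n, ")")
  s <- matrix(0, n, n)
  delta <- numeric(n)
  for (j in seq_len(n)) {
    e <- p[, j] / 2 - w * z[, j]
    col <- adaptive_column(e, k, j, n, warn_context = "update_affinity")
    delta[j] <- attr(col, "delta")
    s[, j] <- col
  }
  attr(s, "delta") <- delta
  s
}
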