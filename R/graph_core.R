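# Graph primitives: Laplacians, component counting, simplex projection and the
# adaptive-neighbor initial affinity graph.
#
# An affinity graph is stored as a plain n x n numeric matrix with zero
# diagonal whose COLUMNS lie on the probability simplex (column j holds sample
# j's similarity distribution over the other samples).  The matrix may be
# asymmetric; symmetrization (A + t(A))/2 happens only inside Laplacian and
# connected-component computations.

#' Validate an affinity graph matrix
#'
#' Checks the structural invariants every affinity graph in the package must
#' satisfy: square, nonnegative, zero diagonal, and every column summing to 1.
#'
#' @param a numeric matrix to check.
#' @param k optional neighbor count; when given, each column may have at most
#'   `k` nonzero entries.
#' @param tol tolerance on the column sums (default `1e-9`).
#' @return `a`, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_affinity <- function(a, k = NULL, tol = 1e-9) {
  if (!is.matrix(a) || !is.numeric(a) || nrow(a) != ncol(a))
    stop("affinity graph must be a square numeric matrix")
  if (any(!is.finite(a)))
    stop("affinity graph contains non-finite entries")
  if (any(a < 0))
    stop("affinity graph has negative entries")
  if (any(diag(a) != 0))
    stop("affinity graph has nonzero diagonal entries")
  cs <- colSums(a)
  if (any(abs(cs - 1) > tol))
    stop("affinity graph columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  if (!is.null(k)) {
    nnz <- colSums(a > 0)
    if (any(nnz > k))
      stop("affinity graph has a column with more than k = ", k, " nonzeros")
  }
  invisible(a)
}

#' Graph Laplacian of an affinity graph
#'
#' Returns `L = D - W` where `W = (A + t(A))/2` is the symmetrized weight
#' matrix and `D` is the diagonal matrix of its column sums.  `L` is symmetric
#' positive semidefinite with zero row sums; the multiplicity of its zero
#' eigenvalue equals the number of connected components of the graph.
#'
#' @param a square numeric weight matrix (possibly asymmetric), entries >= 0.
#' @return list with `matrix` (the n x n Laplacian) and `degree` (n-vector of
#'   symmetrized column sums).
#' @export
build_laplacian <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("weight matrix must be square")
  if (any(!is.finite(a)))
    stop("weight matrix contains non-finite entries")
  if (any(a < 0))
    stop("weight matrix has negative entries")
  w <- (a + t(a)) / 2
  d <- colSums(w)
  l <- diag(d, nrow = nrow(w)) - w
  list(matrix = l, degree = d)
}

#' Count zero eigenvalues of a Laplacian
#'
#' The number of eigenvalues below `tol`, which by the spectral
#' characterisation of graph connectivity equals the number of connected
#' components of the underlying graph.
#'
#' @param lap a Laplacian as returned by [build_laplacian()], or a symmetric
#'   matrix.
#' @param tol eigenvalues strictly below this threshold count as zero.
#' @return integer count.
#' @export
count_zero_eigenvalues <- function(lap, tol = 1e-8) {
  l <- if (is.list(lap)) lap$matrix else lap
  if (any(!is.finite(l)))
    stop("Laplacian contains non-finite entries")
  ev <- eigen(l, symmetric = TRUE, only.values = TRUE)$values
  sum(ev < tol)
}

#' Connected components of an affinity graph
#'
#' Components of the undirected graph whose edges are the entries of
#' `(A + t(A))/2` strictly greater than `support_tol`, found by breadth-first
#' traversal.  Labels are contiguous integers starting at 0, assigned in order
#' of first appearance.
#'
#' @param a square numeric weight matrix.
#' @param support_tol entries of the symmetrized matrix at or below this value
#'   are treated as absent edges.
#' @return list with `count` and `labels` (integer vector, values in
#'   `0..count-1`).
#' @export
connected_components <- function(a, support_tol = 1e-8) {
  n <- nrow(a)
  w <- (a + t(a)) / 2
  adj <- w > support_tol
  labels <- rep(NA_integer_, n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (!is.na(labels[start])) next
    queue <- start
    labels[start] <- comp
    while (length(queue) > 0) {
      i <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[i, ] & is.na(labels))
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
    comp <- comp + 1L
  }
  list(count = comp, labels = labels)
}

#' Euclidean projection onto the probability simplex with one coordinate fixed
#' at zero
#'
#' Solves `argmin_s ||s - v||^2` subject to `s >= 0`, `sum(s) = 1`, and
#' `s[forbidden_index] = 0`.  The solution has the thresholding form
#' `s = pmax(v + eta, 0)` with the shift `eta` chosen so the positive part
#' sums to 1.
#'
#' @param v numeric vector.
#' @param forbidden_index optional index clamped to zero (used for the
#'   zero-diagonal constraint); `NULL` for the plain simplex.
#' @return projected vector of the same length.
#' @export
project_capped_simplex <- function(v, forbidden_index = NULL) {
  if (any(!is.finite(v)))
    stop("cannot project a vector with non-finite entries")
  n <- length(v)
  active <- seq_len(n)
  if (!is.null(forbidden_index)) {
    if (n < 2)
      stop("projection infeasible: fewer than 2 coordinates with one forbidden")
    active <- active[-forbidden_index]
  }
  u <- sort(v[active], decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  eta <- (1 - css[rho]) / rho
  s <- pmax(v + eta, 0)
  if (!is.null(forbidden_index)) s[forbidden_index] <- 0
  s
}

# Squared Euclidean distances between the columns of x (d x n): n x n matrix.
sq_col_dists <- function(x) {
  g <- crossprod(x)              # n x n Gram matrix
  sq <- diag(g)
  d <- outer(sq, sq, "+") - 2 * g
  d[d < 0] <- 0                  # numerical noise
  diag(d) <- 0
  d
}

# Shared closed form for a k-sparse adaptive-neighbor column.
# Given per-candidate effective costs e_i (ascending is better), returns the
# simplex column with support on the k smallest costs:
#   s_i = (e_(k+1) - e_i) / delta,  delta = k e_(k+1) - sum_{l<=k} e_(l).
# Candidate order is stabilised by index so ties break deterministically.
# Degenerate ties (delta ~ 0, i.e. the k+1 smallest costs coincide) fall back
# to uniform weight over the tied nearest set, with a warning from the caller.
adaptive_column <- function(e, k, j, n, warn_context = "adaptive_column") {
  ord <- order(e[-j], method = "radix")      # ascending cost, stable in index
  cand <- seq_len(n)[-j][ord]
  es <- e[cand]
  delta <- k * es[k + 1] - sum(es[seq_len(k)])
  s <- numeric(n)
  if (delta < 1e-12) {
    tied <- which(es <= es[k] + 1e-12)
    warning(sprintf(
      "%s: degenerate cost ties in column %d; using uniform weights over %d tied neighbors",
      warn_context, j, length(tied)))
    s[cand[tied]] <- 1 / length(tied)
  } else {
    s[cand[seq_len(k)]] <- (es[k + 1] - es[seq_len(k)]) / delta
  }
  attr(s, "delta") <- delta
  s
}

#' Adaptive-neighbor initial affinity graph for one view
#'
#' For each sample `j`, learns a k-sparse similarity distribution over the
#' other samples by solving, per column,
#' `min_s sum_i d_ij s_ij + alpha ||s_j||^2` over the zero-diagonal simplex,
#' where `d_ij` is the squared Euclidean distance between samples `i` and `j`
#' in this view's feature space.  The per-column regularizer `alpha` is set
#' implicitly so each column has exactly `k` nonzeros, giving the closed form
#' `s_ij = (d_(k+1) - d_ij) / (k d_(k+1) - sum_{l<=k} d_(l))` over the `k`
#' nearest neighbors.
#'
#' @param x view matrix, features in rows and samples in columns (`d x n`).
#' @param k number of adaptive neighbors, `1 <= k <= n - 2`.
#' @return n x n affinity matrix; columns on the simplex, zero diagonal, at
#'   most `k` nonzeros per column.
#' @export
init_affinity <- function(x, k) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- ncol(x)
  if (k < 1 || k > n - 2)
    stop("k must satisfy 1 <= k <= n - 2 (got k = ", k, ", n = ", n, ")")
  d <- sq_col_dists(x)
  s <- matrix(0, n, n)
  delta <- numeric(n)
  for (j in seq_len(n)) {
    # costs on the half scale so the implicit column regularizer alpha equals
    # the returned delta (see update_affinity: e = p/2 - w z with w = 0)
    col <- adaptive_column(d[, j] / 2, k, j, n, warn_context = "init_affinity")
    delta[j] <- attr(col, "delta")
    s[, j] <- col
  }
  attr(s, "delta") <- delta
  s
}
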