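# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the QP oracle solves simplex-constrained
# quadratics by exhaustive enumeration of active sets, the assignment oracle
# enumerates permutations, and the information-theoretic oracles work from an
# explicitly built contingency table.

# Global minimizer of  (1/2) sum_i h_i s_i^2 + sum_i f_i s_i
# subject to sum(s) = 1, s >= 0, s[forbidden] = 0, with h_i > 0.
# Enumerates every candidate support set; exact for n <= ~15.
oracle_simplex_qp <- function(h, f, forbidden = NULL) {
  n <- length(f)
  h <- rep_len(h, n)
  allowed <- setdiff(seq_len(n), forbidden)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^length(allowed)) - 1) {
    sel <- allowed[bitwAnd(mask, 2^(seq_along(allowed) - 1)) > 0]
    if (length(sel) == 0) next
    eta <- -(1 + sum(f[sel] / h[sel])) / sum(1 / h[sel])
    s_sel <- -(f[sel] + eta) / h[sel]
    if (any(s_sel < -1e-12)) next
    s <- numeric(n)
    s[sel] <- pmax(s_sel, 0)
    obj <- sum(h * s^2) / 2 + sum(f * s)
    if (obj < best_obj - 1e-15) { best_obj <- obj; best <- s }
  }
  best
}

# Oracle for the per-view affinity column problem
#   min_s sum_i p_i s_i + alpha s_i^2 + w (z_i - s_i)^2  on the capped simplex
oracle_affinity_column <- function(p_col, z_col, w, alpha, j) {
  oracle_simplex_qp(h = 2 * (alpha + w), f = p_col - 2 * w * z_col,
                    forbidden = j)
}

# Oracle for the consensus column problem
#   min_z sum_v w_v ||z - s_j^v||^2 + beta sum_i q_i z_i  on the capped simplex
oracle_consensus_column <- function(s_cols, weights, q_col, beta, j) {
  f <- beta * q_col
  for (v in seq_along(s_cols)) f <- f - 2 * weights[v] * s_cols[[v]]
  oracle_simplex_qp(h = 2 * sum(weights), f = f, forbidden = j)
}

# Oracle for the adaptive-neighbor initialization column
#   min_s sum_i d_i s_i + alpha ||s||^2  on the capped simplex
oracle_init_column <- function(d_col, alpha, j) {
  oracle_simplex_qp(h = 2 * alpha, f = d_col, forbidden = j)
}

# All permutations of 1..n (n <= 7), as a list.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Accuracy by exhaustive search over one-to-one cluster/class assignments.
oracle_accuracy <- function(true_labels, pred_labels) {
  tab <- table(factor(true_labels), factor(pred_labels))
  d <- max(nrow(tab), ncol(tab))
  counts <- matrix(0, d, d)
  counts[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- 0
  for (p in all_perms(d)) {
    best <- max(best, sum(counts[cbind(seq_len(d), p)]))
  }
  best / length(true_labels)
}

# NMI by explicit plug-in computation from the contingency table, written
# with scalar loops (independent of the vectorised implementation).
oracle_nmi <- function(true_labels, pred_labels) {
  tl <- as.integer(factor(true_labels))
  pl <- as.integer(factor(pred_labels))
  n <- length(tl)
  r <- max(tl); s <- max(pl)
  cont <- matrix(0, r, s)
  for (i in seq_len(n)) cont[tl[i], pl[i]] <- cont[tl[i], pl[i]] + 1
  mi <- 0
  for (a in seq_len(r)) for (b in seq_len(s)) {
    if (cont[a, b] > 0) {
      mi <- mi + (cont[a, b] / n) *
        log(cont[a, b] * n / (sum(cont[a, ]) * sum(cont[, b])))
    }
  }
  ent <- function(counts) {
    h <- 0
    for (x in counts) if (x > 0) h <- h - (x / n) * log(x / n)
    h
  }
  ht <- ent(rowSums(cont)); hp <- ent(colSums(cont))
  if (ht == 0 && hp == 0) return(1)
  if (ht == 0 || hp == 0) return(0)
  mi / sqrt(ht * hp)
}

# Purity by direct counting.
oracle_purity <- function(true_labels, pred_labels) {
  total <- 0
  for (cl in unique(pred_labels)) {
    total <- total + max(table(true_labels[pred_labels == cl]))
  }
  total / length(true_labels)
}

# Random affinity-like graph on n nodes with a planted number of blocks:
# columnwise simplex weights supported inside blocks, so the component count
# is known by construction only when blocks stay disconnected.
random_block_graph <- function(n, blocks) {
  sizes <- table(sort(rep_len(seq_len(blocks), n)))
  labels <- rep(seq_len(blocks), sizes)
  a <- matrix(0, n, n)
  for (j in seq_len(n)) {
    mates <- setdiff(which(labels == labels[j]), j)
    if (length(mates) == 0) next
    w <- stats::runif(length(mates))
    a[mates, j] <- w / sum(w)
  }
  list(a = a, labels = labels)
}

# A random valid affinity graph (columns on the simplex, zero diagonal),
# k-sparse when k is given.
random_affinity <- function(n, k = NULL) {
  a <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- setdiff(seq_len(n), j)
    if (!is.null(k)) idx <- sample(idx, k)
    w <- stats::runif(length(idx))
    a[idx, j] <- w / sum(w)
  }
  a
}
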