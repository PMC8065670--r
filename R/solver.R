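# The LRCMC alternating optimizer: initialization, the five cyclic updates,
# dynamic beta adaptation, convergence detection and label extraction.
#
# One iteration cycles, in order: per-view affinity S^v, per-view embedding
# F^v, view weights w_v, consensus graph Z, fused embedding U.  The rank
# constraint on the consensus Laplacian is enforced indirectly: beta is
# doubled when Z has too few connected components and halved when it has too
# many, until Z has exactly c components and the clusters can be read off.

#' Solver configuration
#'
#' @param c target number of clusters (connected components of the consensus
#'   graph), `2 <= c <= n - 1`.
#' @param k adaptive neighbor count per sample, `1 <= k <= n - 2`.
#' @param beta0 initial rank-constraint strength; adapted by
#'   doubling/halving during the run.
#' @param beta_min,beta_max clamp range for the adapted beta.  The adaptation
#'   rule needs head-room in both directions, so the defaults are wide.
#' @param max_iter iteration cap.
#' @param support_tol consensus entries at or below this threshold are
#'   treated as absent edges when counting components.
#' @param weight_exponent power on the Frobenius distance in the view
#'   weights, 1 (default) or 2.
#' @param min_cluster_size optional minimum cluster size; when set, solutions
#'   with a smaller cluster are flagged (never altered).
#' @param seed integer recorded in the configuration for provenance; the
#'   optimizer itself is deterministic.
#' @return object of class `lrcmc_config`.
#' @export
lrcmc_config <- function(c, k, beta0 = 1, beta_min = 2^-20, beta_max = 2^20,
                         max_iter = 100, support_tol = 1e-8,
                         weight_exponent = 1, min_cluster_size = NULL,
                         seed = 0L) {
  if (c < 2) stop("need at least c = 2 clusters")
  if (k < 1) stop("need at least k = 1 neighbor")
  if (beta_min <= 0 || beta_max < beta_min)
    stop("beta bounds must satisfy 0 < beta_min <= beta_max")
  if (beta0 < beta_min || beta0 > beta_max)
    stop("beta0 must lie within [beta_min, beta_max]")
  structure(list(c = as.integer(c), k = as.integer(k), beta0 = beta0,
                 beta_min = beta_min, beta_max = beta_max,
                 max_iter = as.integer(max_iter), support_tol = support_tol,
                 weight_exponent = weight_exponent,
                 min_cluster_size = min_cluster_size, seed = as.integer(seed)),
            class = "lrcmc_config")
}

# Coerce the views argument to a list of d x n matrices plus shared sample ids.
as_view_list <- function(views) {
  if (is.matrix(views)) views <- list(views)
  if (!is.list(views) || length(views) == 0)
    stop("views must be a non-empty list of matrices or view_data objects")
  mats <- lapply(views, function(v) {
    if (is.list(v) && !is.null(v$matrix)) as.matrix(v$matrix) else as.matrix(v)
  })
  ns <- vapply(mats, ncol, integer(1))
  if (length(unique(ns)) != 1)
    stop("all views must have the same number of samples (columns); got: ",
         paste(ns, collapse = ", "))
  ids <- NULL
  for (v in views) {
    vi <- if (is.list(v) && !is.null(v$sample_ids)) v$sample_ids else colnames(
      if (is.list(v)) v$matrix else v)
    if (!is.null(vi)) {
      if (is.null(ids)) ids <- vi
      else if (!identical(as.character(ids), as.character(vi)))
        stop("sample ids disagree across views")
    }
  }
  if (is.null(ids)) ids <- paste0("sample_", seq_len(ns[1]))
  list(matrices = mats, sample_ids = as.character(ids))
}

#' Initialize the solver state
#'
#' Builds the per-view adaptive-neighbor graphs and embeddings, sets every
#' view weight to `1/m`, forms the initial consensus as the (projected)
#' weighted average of the view graphs, and computes the fused embedding.
#'
#' @param views list of views: `d_v x n` matrices (samples in columns) or
#'   [view_data()] objects.
#' @param config an [lrcmc_config()].
#' @return object of class `lrcmc_state`.
#' @export
lrcmc_init <- function(views, config) {
  vl <- as_view_list(views)
  mats <- vl$matrices
  n <- ncol(mats[[1]])
  m <- length(mats)
  if (config$c >= n) stop("c must be smaller than the sample count n")
  if (config$k > n - 2) stop("k must be at most n - 2")

  s <- lapply(mats, init_affinity, k = config$k)
  alpha <- lapply(s, function(si) pmax(attr(si, "delta"), 0))
  s <- lapply(s, function(si) { attr(si, "delta") <- NULL; si })
  f <- lapply(s, function(si) update_embedding(build_laplacian(si), config$c))
  p <- lapply(f, embedding_distances)
  weights <- rep(1 / m, m)

  zbar <- Reduce(`+`, Map(`*`, s, weights))
  z <- matrix(0, n, n)
  for (j in seq_len(n)) z[, j] <- project_capped_simplex(zbar[, j], j)
  u <- update_fused_embedding(z, config$c)

  comp <- connected_components(z, config$support_tol)
  state <- list(
    s = s, f = f, p = p, alpha = alpha,
    z = z, u = u, q = embedding_distances(u),
    weights = weights, beta = config$beta0,
    iteration = 0L, component_count = comp$count,
    converged = FALSE, objective_trace = numeric(0),
    beta_trace = numeric(0), component_trace = integer(0),
    sample_ids = vl$sample_ids, config = config)
  class(state) <- "lrcmc_state"
  state
}

# Objective value of the joint model at the current state:
#   sum_v [ 2 Tr(F_v' L_v F_v) + sum_j alpha_jv ||s_j^v||^2
#           + w_v ||Z - S^v||_F^2 ]  +  2 beta Tr(U' L_Z U),
# with the per-column alpha values implied by the exact-k sparsity rule.
lrcmc_objective <- function(state) {
  total <- 0
  for (v in seq_along(state$s)) {
    lv <- build_laplacian(state$s[[v]])$matrix
    total <- total + 2 * sum(state$f[[v]] * (lv %*% state$f[[v]]))
    total <- total + sum(state$alpha[[v]] * colSums(state$s[[v]]^2))
    total <- total + state$weights[v] * sum((state$z - state$s[[v]])^2)
  }
  lz <- build_laplacian(state$z)$matrix
  total + 2 * state$beta * sum(state$u * (lz %*% state$u))
}

#' One full alternating-optimization iteration
#'
#' Applies the five updates in order (per-view affinities, per-view
#' embeddings, view weights, consensus graph, fused embedding), refreshes the
#' component count of the consensus, and appends the joint objective value to
#' the trace.  Beta is not adapted here; see [adapt_beta()].
#'
#' @param state an `lrcmc_state`.
#' @return the advanced state.
#' @export
lrcmc_step <- function(state) {
  cfg <- state$config
  step_ctx <- function(expr) {
    tryCatch(expr, error = function(e)
      stop("iteration ", state$iteration + 1L, ": ", conditionMessage(e)))
  }
  for (v in seq_along(state$s)) {
    sv <- step_ctx(update_affinity(state$p[[v]], state$z,
                                   state$weights[v], cfg$k))
    state$alpha[[v]] <- pmax(attr(sv, "delta") - state$weights[v], 0)
    attr(sv, "delta") <- NULL
    state$s[[v]] <- sv
  }
  for (v in seq_along(state$s)) {
    state$f[[v]] <- step_ctx(
      update_embedding(build_laplacian(state$s[[v]]), cfg$c))
    state$p[[v]] <- embedding_distances(state$f[[v]])
  }
  state$weights <- update_weights(state$z, state$s,
                                  exponent = cfg$weight_exponent)
  state$z <- step_ctx(
    update_consensus(state$s, state$weights, state$q, state$beta))
  state$u <- step_ctx(update_fused_embedding(state$z, cfg$c))
  state$q <- embedding_distances(state$u)

  state$iteration <- state$iteration + 1L
  state$component_count <- connected_components(state$z,
                                                cfg$support_tol)$count
  state$objective_trace <- c(state$objective_trace, lrcmc_objective(state))
  state$beta_trace <- c(state$beta_trace, state$beta)
  state$component_trace <- c(state$component_trace, state$component_count)
  state
}

#' Dynamic beta adaptation
#'
#' When the consensus graph has more connected components than the target
#' `c`, the rank penalty is too strong and beta is halved; with fewer
#' components it is too weak and beta is doubled; at exactly `c` components
#' beta is left alone.  The result is clamped to
#' `[beta_min, beta_max]`.
#'
#' @param state an `lrcmc_state` (or any list with `beta` and
#'   `component_count`).
#' @param config an [lrcmc_config()].
#' @return the state with beta updated.
#' @export
adapt_beta <- function(state, config) {
  comp <- state$component_count
  if (comp > config$c) {
    state$beta <- state$beta / 2
  } else if (comp < config$c) {
    state$beta <- state$beta * 2
  }
  state$beta <- min(max(state$beta, config$beta_min), config$beta_max)
  state
}

# --- non-convergence fallback ------------------------------------------------

# Merge components of z until exactly c remain: repeatedly join the pair of
# components with the largest inter-component similarity (max entry of the
# symmetrized graph between them).
merge_to_c <- function(z, labels, c) {
  w <- (z + t(z)) / 2
  repeat {
    comps <- sort(unique(labels))
    if (length(comps) <= c) break
    best <- c(NA, NA); best_sim <- -Inf
    for (a in seq_along(comps)) {
      for (b in seq_len(a - 1L)) {
        sim <- max(w[labels == comps[a], labels == comps[b], drop = FALSE])
        if (sim > best_sim) { best_sim <- sim; best <- c(comps[a], comps[b]) }
      }
    }
    labels[labels == best[1]] <- best[2]
  }
  labels
}

# Split the largest component by 2-way spectral bisection of its submatrix
# until exactly c components exist.  The Fiedler vector's sign pattern gives
# the cut; a degenerate all-one-sided cut falls back to a median split.
split_to_c <- function(z, labels, c) {
  w <- (z + t(z)) / 2
  while (length(unique(labels)) < c) {
    comps <- sort(unique(labels))
    sizes <- vapply(comps, function(x) sum(labels == x), integer(1))
    target <- comps[which.max(sizes)]
    idx <- which(labels == target)
    if (length(idx) < 2) break  # nothing left to split
    sub <- w[idx, idx, drop = FALSE]
    lap <- build_laplacian(sub)$matrix
    es <- eigen(lap, symmetric = TRUE)
    fiedler <- es$vectors[, ncol(es$vectors) - 1L]
    side <- fiedler >= 0
    if (all(side) || !any(side)) side <- fiedler >= stats::median(fiedler)
    if (all(side) || !any(side)) side <- seq_along(idx) <= length(idx) / 2
    labels[idx[side]] <- max(labels) + 1L
  }
  labels
}

# Contiguous 0-based labels in order of first appearance.
relabel_contiguous <- function(labels) {
  u <- unique(labels)
  match(labels, u) - 1L
}

#' Fit the multiview clustering model
#'
#' Runs the alternating optimizer with dynamic beta adaptation until the
#' consensus graph has exactly `c` connected components on two consecutive
#' iterations (the two-iteration requirement guards against oscillation of
#' the beta rule), or until `max_iter`.  Labels are the connected components
#' of the final consensus graph.  If the component count still differs from
#' `c` at the iteration cap, components are merged (largest inter-component
#' similarity first) or split (spectral bisection of the largest component)
#' to reach `c`, and the result is flagged `converged = FALSE`.
#'
#' @param views list of views: `d_v x n` matrices (samples in columns) or
#'   [view_data()] objects.
#' @param config an [lrcmc_config()]; alternatively pass `c` and `k` (and any
#'   other [lrcmc_config()] arguments) via `...`.
#' @param ... arguments forwarded to [lrcmc_config()] when `config` is
#'   missing.
#' @return object of class `lrcmc_fit`: a list with `labels` (0-based
#'   integers), `n_clusters`, `converged`, `weights`, `beta`, `iterations`,
#'   `component_count`, `sample_ids`, `size_flag` (TRUE when a
#'   `min_cluster_size` check fails) and the full `state`.
#' @export
lrcmc_fit <- function(views, config = NULL, ...) {
  if (is.null(config)) config <- lrcmc_config(...)
  if (!inherits(config, "lrcmc_config")) stop("config must be an lrcmc_config")
  state <- lrcmc_init(views, config)
  hits <- 0L
  while (state$iteration < config$max_iter) {
    state <- lrcmc_step(state)
    if (state$component_count == config$c) {
      hits <- hits + 1L
      if (hits >= 2L) { state$converged <- TRUE; break }
    } else {
      hits <- 0L
    }
    state <- adapt_beta(state, config)
  }
  comp <- connected_components(state$z, config$support_tol)
  labels <- comp$labels
  if (comp$count > config$c) {
    labels <- merge_to_c(state$z, labels, config$c)
  } else if (comp$count < config$c) {
    labels <- split_to_c(state$z, labels, config$c)
  }
  labels <- relabel_contiguous(labels)

  size_flag <- FALSE
  if (!is.null(config$min_cluster_size)) {
    size_flag <- any(table(labels) < config$min_cluster_size)
    if (size_flag)
      warning("a cluster has fewer than min_cluster_size = ",
              config$min_cluster_size, " samples")
  }
  res <- list(labels = labels, n_clusters = length(unique(labels)),
              converged = state$converged, weights = state$weights,
              beta = state$beta, iterations = state$iteration,
              component_count = comp$count, sample_ids = state$sample_ids,
              size_flag = size_flag, state = state)
  class(res) <- "lrcmc_fit"
  res
}

#' @export
print.lrcmc_fit <- function(x, ...) {
  cat("Laplacian rank constrained multiview clustering fit\n")
  cat(sprintf("  samples: %d   views: %d   clusters: %d\n",
              length(x$labels), length(x$weights), x$n_clusters))
  cat(sprintf("  converged: %s after %d iterations (consensus components: %d)\n",
              x$converged, x$iterations, x$component_count))
  cat(sprintf("  final beta: %g\n", x$beta))
  cat("  view weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  cat("  cluster sizes:",
      paste(as.integer(table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.lrcmc_config <- function(x, ...) {
  cat("lrcmc_config: c =", x$c, " k =", x$k, " beta0 =", x$beta0,
      " max_iter =", x$max_iter, "\n")
  invisible(x)
}
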