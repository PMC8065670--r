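# Synthetic multiview data with known ground truth: c well-separated point
# clouds observed in m views with independent per-view noise, optionally with
# corrupted (label-shuffled) views carrying no class signal.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cluster centers for one view: an orthogonal frame scaled so pairwise
# center distance is exactly `separation` (d >= c), else a 1-D lattice with
# spacing `separation` along the first coordinate.
blob_centers <- function(c, d, separation) {
  centers <- matrix(0, d, c)
  if (d >= c) {
    scale <- separation / sqrt(2)
    centers[cbind(seq_len(c), seq_len(c))] <- scale
  } else {
    centers[1, ] <- separation * (seq_len(c) - 1)
  }
  centers
}

#' Generate multiview Gaussian blobs with known labels
#'
#' `c` clusters of `n_per_cluster` samples each, observed in `m` views.  Per
#' view, cluster centers sit on an orthogonal frame scaled so pairwise
#' center distance equals `separation` (falling back to a 1-D lattice when
#' the view has fewer than `c` dimensions), and points are the centers plus
#' isotropic Gaussian noise with the view's `noise_sd`.  Views listed in
#' `corrupt_views` are generated from an independently shuffled copy of the
#' label vector, so they retain blob structure but carry no signal about the
#' true classes.  Fully deterministic given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param n_per_cluster samples per cluster.
#' @param c number of clusters.
#' @param m number of views.
#' @param dims feature dimension per view (recycled to length `m`).
#' @param separation pairwise distance between cluster centers (must be
#'   positive).
#' @param noise_sd isotropic noise standard deviation per view (recycled).
#' @param corrupt_views integer indices of views to corrupt (label shuffle).
#' @param seed integer seed.
#' @return list with `views` (list of [view_data()] objects, matrices
#'   `d_v x n`) and `labels` (0-based integer vector of length
#'   `n_per_cluster * c`).
#' @export
make_multiview_blobs <- function(n_per_cluster, c, m, dims = 5,
                                 separation = 10, noise_sd = 1,
                                 corrupt_views = integer(0), seed = 1) {
  stopifnot(separation > 0, all(noise_sd > 0), all(dims >= 1),
            n_per_cluster >= 1, c >= 2, m >= 1)
  dims <- rep_len(as.integer(dims), m)
  noise_sd <- rep_len(noise_sd, m)
  n <- n_per_cluster * c
  labels <- rep(seq_len(c) - 1L, each = n_per_cluster)
  ids <- paste0("sample_", seq_len(n))
  with_local_seed(seed, {
    views <- vector("list", m)
    for (v in seq_len(m)) {
      lab_v <- labels
      if (v %in% corrupt_views) lab_v <- sample(labels)
      centers <- blob_centers(c, dims[v], separation)
      x <- centers[, lab_v + 1L, drop = FALSE] +
        matrix(stats::rnorm(dims[v] * n, sd = noise_sd[v]), dims[v], n)
      colnames(x) <- ids
      views[[v]] <- view_data(x, ids)
    }
    list(views = views, labels = labels)
  })
}

#' Tiny frozen worked example
#'
#' A fixed multiview instance (n = 12 samples, c = 3 clusters, m = 2 views)
#' with hard-coded matrices, used for regression tests: every number is a
#' literal, so the fixture is bit-identical on every platform.
#'
#' @return list with `views` (two [view_data()] objects) and `labels`
#'   (0-based, 4 samples per cluster).
#' @export
make_worked_fixture <- function() {
  ids <- paste0("s", sprintf("%02d", 1:12))
  v1 <- matrix(c(
     0.1, -0.2,  -0.3,  0.1,   0.2,  0.3,   0.0, -0.1,
    10.2,  0.1,   9.8, -0.3,  10.1,  0.2,   9.9,  0.0,
     0.1, 10.1,  -0.2,  9.9,   0.3, 10.2,   0.0,  9.8), nrow = 2)
  v2 <- matrix(c(
    8.1,  0.2, -0.1,   7.9, -0.1,  0.3,   8.2,  0.0,  0.1,   8.0,  0.1, -0.2,
    0.2,  8.1,  0.1,  -0.1,  7.9, -0.2,   0.1,  8.2,  0.0,   0.0,  8.0,  0.2,
    0.1, -0.2,  8.1,  -0.2,  0.1,  7.9,   0.2,  0.0,  8.2,   0.0,  0.1,  8.0),
    nrow = 3)
  colnames(v1) <- ids
  colnames(v2) <- ids
  list(views = list(view_data(v1, ids), view_data(v2, ids)),
       labels = rep(0:2, each = 4L))
}
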