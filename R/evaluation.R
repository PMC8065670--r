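# Clustering quality metrics: accuracy under optimal one-to-one label
# matching, normalized mutual information, and purity, plus repeated-run
# aggregation.

# Minimum-cost assignment on a square cost matrix (Hungarian algorithm with
# potentials, O(n^3)).  Returns the column assigned to each row.  Written
# here because no installed package exposes a weighted assignment solver.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials, position j+1 = column j (0 virtual)
  p <- integer(n + 1)      # p[j+1]: row matched to column j (0 = unmatched)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

check_label_lengths <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length (",
         length(true_labels), " vs ", length(pred_labels), ")")
  if (length(true_labels) == 0) stop("empty label vectors")
}

#' Clustering accuracy under optimal label matching
#'
#' The fraction of samples whose predicted cluster maps to their true class
#' under the best one-to-one assignment between clusters and classes, found
#' by solving the assignment problem on the negated contingency table.
#' Unequal numbers of clusters and classes are handled by padding with empty
#' rows/columns.
#'
#' @param true_labels,pred_labels label vectors of equal length (any type
#'   coercible to factor).
#' @return accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(true_labels, pred_labels) {
  check_label_lengths(true_labels, pred_labels)
  tab <- table(factor(true_labels), factor(pred_labels))
  r <- nrow(tab); s <- ncol(tab)
  d <- max(r, s)
  counts <- matrix(0, d, d)
  counts[seq_len(r), seq_len(s)] <- tab
  cost <- max(counts) - counts
  assignment <- hungarian_min(cost)
  matched <- sum(counts[cbind(seq_len(d), assignment)])
  matched / length(true_labels)
}

#' Normalized mutual information between two partitions
#'
#' `I(T; P)` divided by a normalizing combination of the partition entropies
#' (natural logs).  The default geometric-mean normalization
#' `sqrt(H(T) H(P))` is the common convention in multiview clustering;
#' `max` and `arithmetic` are also available.  When both partitions are a
#' single cluster the partitions are identical and the value is 1; when
#' exactly one is a single cluster there is no shared information and the
#' value is 0.
#'
#' @param true_labels,pred_labels label vectors of equal length.
#' @param normalization one of `"sqrt"`, `"max"`, `"arithmetic"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(true_labels, pred_labels,
                normalization = c("sqrt", "max", "arithmetic")) {
  normalization <- match.arg(normalization)
  check_label_lengths(true_labels, pred_labels)
  n <- length(true_labels)
  tab <- table(factor(true_labels), factor(pred_labels))
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ht <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hp <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (ht == 0 && hp == 0) return(1)
  if (ht == 0 || hp == 0) return(0)
  expected <- outer(pi_, pj_)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / expected[pos]))
  denom <- switch(normalization,
                  sqrt = sqrt(ht * hp),
                  max = max(ht, hp),
                  arithmetic = (ht + hp) / 2)
  max(0, min(1, mi / denom))
}

#' Purity of a clustering
#'
#' The average over predicted clusters of the fraction of the dominant true
#' class: `(1/n) sum_clusters max_class count`.
#'
#' @param true_labels,pred_labels label vectors of equal length.
#' @return purity in `[0, 1]`.
#' @export
purity <- function(true_labels, pred_labels) {
  check_label_lengths(true_labels, pred_labels)
  tab <- table(factor(true_labels), factor(pred_labels))
  sum(apply(tab, 2, max)) / length(true_labels)
}

#' All three clustering metrics at once
#'
#' @param true_labels,pred_labels label vectors of equal length.
#' @param nmi_normalization passed to [nmi()].
#' @return object of class `metric_report`: list with `acc`, `nmi`,
#'   `purity`, `n`.
#' @export
clustering_metrics <- function(true_labels, pred_labels,
                               nmi_normalization = "sqrt") {
  res <- list(acc = clustering_accuracy(true_labels, pred_labels),
              nmi = nmi(true_labels, pred_labels, nmi_normalization),
              purity = purity(true_labels, pred_labels),
              n = length(true_labels))
  class(res) <- "metric_report"
  res
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("clustering metrics (n = %d): ACC %.4f  NMI %.4f  Purity %.4f\n",
              x$n, x$acc, x$nmi, x$purity))
  invisible(x)
}

#' Aggregate metric reports over repeated runs
#'
#' @param reports list of `metric_report` objects.
#' @return data frame with one row per metric: mean and standard deviation
#'   across runs.
#' @export
aggregate_metrics <- function(reports) {
  stopifnot(length(reports) > 0)
  vals <- vapply(reports, function(r) c(r$acc, r$nmi, r$purity), numeric(3))
  data.frame(metric = c("acc", "nmi", "purity"),
             mean = rowMeans(vals),
             sd = apply(vals, 1, stats::sd),
             n_runs = length(reports))
}
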