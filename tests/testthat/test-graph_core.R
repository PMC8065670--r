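# Graph primitives: Laplacian construction, component counting, simplex
# projection, and the adaptive-neighbor initial graph.

test_that("build_laplacian matches closed forms and symmetrizes", {
  # single edge
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  l <- build_laplacian(a)
  expect_equal(l$matrix, matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sort(eigen(l$matrix, symmetric = TRUE)$values), c(0, 2))

  # empty graph
  l0 <- build_laplacian(matrix(0, 3, 3))
  expect_equal(l0$matrix, matrix(0, 3, 3))

  # asymmetric input equals symmetric graph with half-weight edge
  la <- build_laplacian(matrix(c(0, 0, 1, 0), 2, 2))
  ls <- build_laplacian(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(la$matrix, ls$matrix)

  expect_error(build_laplacian(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("Laplacians have zero row sums and are PSD", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    l <- build_laplacian(random_affinity(n))
    expect_lt(max(abs(rowSums(l$matrix))), 1e-10)
    ev <- eigen(l$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    expect_lt(min(abs(ev)), 1e-10)  # smallest eigenvalue is 0
  }
})

test_that("zero-eigenvalue count equals component count on known graphs", {
  # two disjoint edges
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 1
  expect_equal(count_zero_eigenvalues(build_laplacian(a)), 2)

  # path on 4 nodes
  p <- matrix(0, 4, 4)
  p[cbind(1:3, 2:4)] <- 1
  p[cbind(2:4, 1:3)] <- 1
  expect_equal(count_zero_eigenvalues(build_laplacian(p)), 1)

  expect_error(count_zero_eigenvalues(matrix(c(NaN, 0, 0, 0), 2, 2)),
               "non-finite")
})

test_that("connected_components labels partition the graph correctly", {
  # all-isolated nodes
  res <- connected_components(matrix(0, 5, 5))
  expect_equal(res$count, 5)
  expect_equal(sort(res$labels), 0:4)

  # two cliques of sizes 3 and 2
  a <- matrix(0, 5, 5)
  a[1:3, 1:3] <- 1; a[4:5, 4:5] <- 1; diag(a) <- 0
  res <- connected_components(a)
  expect_equal(res$count, 2)
  expect_equal(res$labels, c(0L, 0L, 0L, 1L, 1L))
  expect_equal(sort(as.integer(table(res$labels))), c(2L, 3L))
  # agrees with the spectral count
  expect_equal(count_zero_eigenvalues(build_laplacian(a)), 2)
})

test_that("component count agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:25, 1)
    g <- random_block_graph(n, sample(1:4, 1))
    mine <- connected_components(g$a)
    w <- (g$a + t(g$a)) / 2
    ig <- igraph::graph_from_adjacency_matrix(w > 1e-8, mode = "undirected")
    ref <- igraph::components(ig)
    expect_equal(mine$count, ref$no)
    # same partition up to relabeling
    expect_equal(clustering_accuracy(ref$membership, mine$labels), 1.0)
  }
})

test_that("spectral and combinatorial component counts agree on random k-NN
           graphs of separated clusters", {
  set.seed(21)
  for (i in 1:10) {
    x <- cbind(matrix(rnorm(10 * 2), 2), matrix(rnorm(10 * 2) + 50, 2),
               matrix(rnorm(10 * 2) - 50, 2))
    a <- init_affinity(x, k = 3)
    lap <- build_laplacian(a)
    expect_equal(count_zero_eigenvalues(lap), 3)
    expect_equal(connected_components(a)$count, 3)
  }
})

test_that("project_capped_simplex handles fixed points and dominant
           coordinates", {
  v <- c(0.2, 0, 0.5, 0.3)
  expect_equal(project_capped_simplex(v, forbidden_index = 2), v)
  expect_equal(project_capped_simplex(c(10, 0, 0), forbidden_index = 3),
               c(1, 0, 0))
  expect_error(project_capped_simplex(1, forbidden_index = 1), "infeasible")
  expect_error(project_capped_simplex(c(1, NA)), "non-finite")
})

test_that("project_capped_simplex matches the exhaustive QP oracle", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    v <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
    j <- sample(n, 1)
    got <- project_capped_simplex(v, forbidden_index = j)
    want <- oracle_simplex_qp(h = 2, f = -2 * v, forbidden = j)
    expect_lt(max(abs(got - want)), 1e-6)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_true(all(got >= 0))
  }
})

test_that("init_affinity reproduces the worked 1-D example", {
  x <- matrix(c(0, 1, 3, 10), nrow = 1)
  s <- init_affinity(x, k = 2)
  # column for point 0: distances (1, 9, 100) to points 1, 3, 10
  expect_equal(s[, 1], c(0, 99 / 190, 91 / 190, 0))
  expect_equal(colSums(s), rep(1, 4))
})

test_that("init_affinity with k = 1 gives the nearest neighbor weight 1", {
  set.seed(41)
  x <- matrix(rnorm(3 * 6), 3, 6)
  s <- init_affinity(x, k = 1)
  expect_true(all(colSums(s > 0) == 1))
  expect_equal(colSums(s), rep(1, 6))
  d <- as.matrix(dist(t(x)))^2
  diag(d) <- Inf
  expect_equal(apply(s, 2, which.max), unname(apply(d, 2, which.min)))
})

test_that("init_affinity columns solve the per-column QP", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(6:9, 1)
    k <- sample(2:(n - 3), 1)
    x <- matrix(rnorm(4 * n), 4, n)
    s <- init_affinity(x, k)
    delta <- attr(s, "delta")
    d <- as.matrix(dist(t(x)))^2
    for (j in seq_len(n)) {
      want <- oracle_init_column(d[, j], alpha = delta[j], j = j)
      expect_lt(max(abs(s[, j] - want)), 1e-6)
    }
    validate_affinity(s, k = k)
  }
})

test_that("init_affinity is invariant to rotation of the feature space", {
  set.seed(61)
  x <- matrix(rnorm(5 * 12), 5, 12)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))   # random orthogonal matrix
  s1 <- init_affinity(x, k = 4)
  s2 <- init_affinity(q %*% x, k = 4)
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("duplicated points trigger the uniform tied-neighbor fallback", {
  x <- matrix(c(0, 0, 0, 0, 5), nrow = 1)   # four coincident points
  warns <- capture_warnings(s <- init_affinity(x, k = 2))
  expect_true(any(grepl("uniform", warns)))  # every tied column warns
  # column 1 sees three zero-distance mates: uniform over the tied set
  expect_equal(s[, 1], c(0, 1/3, 1/3, 1/3, 0))
  expect_equal(colSums(s), rep(1, 5))
})

test_that("validate_affinity rejects each invariant violation", {
  a <- random_affinity(5)
  expect_silent(validate_affinity(a))
  bad <- a; bad[1, 2] <- bad[1, 2] - 2
  expect_error(validate_affinity(abs(bad)), "sum")
  bad <- a; bad[2, 2] <- 0.5
  expect_error(validate_affinity(bad), "diagonal")
  bad <- a; bad[1, 2] <- -bad[1, 2]
  expect_error(validate_affinity(bad), "negative")
})
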