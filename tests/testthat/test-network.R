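test_that("partial correlations recover the equicorrelation closed form", {
  # three exchangeable variables with pairwise correlation r have partial
  # correlations r / (1 + r) = 1/3 at r = 0.5
  set.seed(51)
  n <- 20000
  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  X <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(R)
  P <- partial_correlation_matrix(X, shrinkage = "none")
  off <- P[upper.tri(P)]
  expect_equal(off, rep(1 / 3, 3), tolerance = 0.03)
})

test_that("independent variables have vanishing partial correlation", {
  set.seed(52)
  X <- matrix(stats::rnorm(20000 * 4), ncol = 4)
  P <- partial_correlation_matrix(X, shrinkage = "none")
  expect_lt(max(abs(P[upper.tri(P)])), 0.03)
})

test_that("unshrunk estimation matches the residual-regression oracle", {
  set.seed(53)
  for (p in c(4, 5, 6)) {
    X <- matrix(stats::rnorm(40 * p), 40, p)
    X[, 1] <- X[, 1] + 0.5 * X[, 2]
    P <- partial_correlation_matrix(X, shrinkage = "none")
    expect_equal(unname(P), oracle_partial_correlation(X), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("singular covariance without shrinkage fails with guidance", {
  set.seed(54)
  X <- matrix(stats::rnorm(30 * 3), 30, 3)
  X <- cbind(X, X[, 3])  # exact duplicate column
  expect_error(partial_correlation_matrix(X, shrinkage = "none"),
               "shrinkage")
  # shrinkage makes the same problem estimable
  expect_silent(partial_correlation_matrix(X, shrinkage = "auto"))
})

test_that("automatic shrinkage reproduces the analytic Ledoit-Wolf intensity", {
  # frozen from an independent implementation of the analytic formula
  # (scikit-learn LedoitWolf) on this exact draw
  set.seed(42)
  X <- matrix(stats::rnorm(30), 6, 5)
  P <- partial_correlation_matrix(X, shrinkage = "auto")
  expect_equal(attr(P, "shrinkage_intensity"), 0.979616481829,
               tolerance = 1e-9)
})

test_that("shrinkage vanishing recovers the unregularized matrix", {
  set.seed(55)
  X <- matrix(stats::rnorm(100 * 5), 100, 5)
  P0 <- partial_correlation_matrix(X, shrinkage = "none")
  d6 <- max(abs(partial_correlation_matrix(X, shrinkage = 1e-6) - P0))
  d3 <- max(abs(partial_correlation_matrix(X, shrinkage = 1e-3) - P0))
  expect_lt(d6, d3)
  expect_lt(d6, 1e-5)
})

test_that("binarization keeps exactly the strongest edges", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9
  w[1, 3] <- 0.7
  w[1, 4] <- 0.5
  w[2, 3] <- 0.4
  w[2, 4] <- 0.3
  w[3, 4] <- 0.1
  w <- w + t(w)
  adj <- binarize_by_sparsity(w, 1 / 3)
  expect_equal(sum(adj) / 2, 2)
  expect_equal(adj[1, 2], 1)
  expect_equal(adj[1, 3], 1)
  expect_equal(binarize_by_sparsity(w, 1), (w > 0) * 1)
  # negative weights rank last under the positive rule but first by |w|
  w2 <- w
  w2[3, 4] <- w2[4, 3] <- -0.95
  expect_equal(binarize_by_sparsity(w2, 1 / 6, "positive")[1, 2], 1)
  expect_equal(binarize_by_sparsity(w2, 1 / 6, "abs")[3, 4], 1)
})

test_that("ties at the cutoff break deterministically", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9
  w[1, 3] <- 0.5
  w[2, 3] <- 0.5
  w[1, 4] <- 0.5
  w <- w + t(w)
  adj <- binarize_by_sparsity(w, 1 / 3)  # keeps 2 edges
  expect_equal(adj[1, 2], 1)
  # among the tied 0.5 edges, node 1 wins, then its higher partner: (1, 4)
  expect_equal(adj[1, 4], 1)
  expect_equal(sum(adj) / 2, 2)
})

test_that("edge counts equal round(sparsity * 2016) on the full atlas", {
  set.seed(56)
  vals <- matrix(stats::runif(15 * 64, 500, 9000), 15, 64)
  net <- build_network(make_table(vals))
  expect_length(net$adjacency, 19L)
  for (i in seq_along(net$sparsity)) {
    expect_equal(sum(net$adjacency[[i]]) / 2,
                 round(net$sparsity[i] * 2016))
  }
})

test_that("adjacencies are nested along the sparsity grid", {
  set.seed(57)
  vals <- matrix(stats::runif(15 * 64, 500, 9000), 15, 64)
  net <- build_network(make_table(vals),
                       sparsity_range = c(0.1, 0.2, 0.3, 0.4))
  for (i in 1:3) {
    expect_true(all(net$adjacency[[i]] <= net$adjacency[[i + 1]]))
  }
  # determinism
  net2 <- build_network(make_table(vals),
                        sparsity_range = c(0.1, 0.2, 0.3, 0.4))
  expect_identical(net$adjacency, net2$adjacency)
})

test_that("network construction rejects invalid input", {
  expect_error(binarize_by_sparsity(diag(4), 0), "(0, 1]", fixed = TRUE)
  expect_error(binarize_by_sparsity(diag(4), 1.2), "(0, 1]", fixed = TRUE)
  w <- matrix(stats::rnorm(16), 4, 4)
  expect_error(binarize_by_sparsity(w, 0.5), "symmetric")
  expect_error(partial_correlation_matrix(matrix(1:4, 2, 2)),
               "at least 3 subjects")
})
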