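k_n <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}

cycle_n <- function(n) {
  ring_lattice(n, 2)
}

test_that("metrics take their textbook values on canonical graphs", {
  K3 <- k_n(3)
  expect_equal(clustering_coefficient(K3)$per_node, rep(1, 3))
  expect_equal(clustering_coefficient(K3)$Cp, 1)

  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(clustering_coefficient(P3)$Cp, 0)

  K4_minus <- k_n(4)
  K4_minus[3, 4] <- K4_minus[4, 3] <- 0
  expect_equal(clustering_coefficient(K4_minus)$Cp, 5 / 6)

  expect_equal(characteristic_path_length(k_n(4))$Lp, 1)
  C5 <- cycle_n(5)
  expect_equal(characteristic_path_length(C5)$Lp, 1.5)
  expect_equal(global_efficiency(C5), 0.75)
  expect_equal(local_efficiency(C5), 0)

  expect_equal(global_efficiency(k_n(6)), 1)
  expect_equal(local_efficiency(k_n(4)), 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(star), 0)
  expect_equal(clustering_coefficient(star)$Cp, 0)
})

test_that("degenerate graphs follow the stated conventions", {
  empty <- matrix(0, 5, 5)
  lp <- characteristic_path_length(empty)
  expect_true(is.nan(lp$Lp))
  expect_true(lp$disconnected)
  expect_equal(global_efficiency(empty), 0)
  # two disjoint triangles: finite-pairs mean is 1, flagged disconnected
  two_tri <- rbind(cbind(k_n(3), matrix(0, 3, 3)),
                   cbind(matrix(0, 3, 3), k_n(3)))
  lp2 <- characteristic_path_length(two_tri)
  expect_equal(lp2$Lp, 1)
  expect_true(lp2$disconnected)
})

test_that("binary clustering is the exact reduction of the weighted form", {
  set.seed(61)
  for (rep in 1:5) {
    A <- random_adjacency(10, 0.4)
    expect_equal(volnet:::.clustering_onnela(A)$per_node,
                 unname(clustering_coefficient(A)$per_node),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(62)
  for (rep in 1:10) {
    A <- random_adjacency(16, 0.35)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    ig_c <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(clustering_coefficient(A)$Cp, mean(ig_c), tolerance = 1e-12)
    expect_equal(global_efficiency(A), igraph::global_efficiency(g),
                 tolerance = 1e-12)
    if (igraph::is_connected(g)) {
      expect_equal(characteristic_path_length(A)$Lp,
                   igraph::mean_distance(g), tolerance = 1e-12)
    }
  }
})

test_that("rewiring preserves the degree sequence exactly", {
  set.seed(63)
  for (rep in 1:10) {
    A <- random_adjacency(20, 0.3)
    B <- rewire_adjacency(A, rewires_per_edge = 10)
    expect_equal(rowSums(B), rowSums(A))
    expect_true(all(B %in% c(0, 1)))
    expect_true(all(diag(B) == 0))
    expect_equal(B, t(B))
  }
})

test_that("rigid degree sequences return the graph itself", {
  K3 <- k_n(3)
  nulls <- random_null_metrics(K3, null_model_config(n_null = 5, seed = 1))
  expect_equal(nulls$Crand, 1)
  expect_equal(nulls$Lrand, 1)
  sw <- small_world(K3, null_model_config(n_null = 5, seed = 1))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_false(sw$is_small_world)
})

test_that("null metrics are exactly reproducible under a fixed seed", {
  set.seed(64)
  A <- random_adjacency(30, 0.2)
  cfg <- null_model_config(n_null = 10, seed = 123)
  expect_identical(random_null_metrics(A, cfg), random_null_metrics(A, cfg))
  cfg2 <- null_model_config(n_null = 10, seed = 124)
  expect_false(identical(random_null_metrics(A, cfg)$Crand,
                         random_null_metrics(A, cfg2)$Crand))
})

test_that("rewiring destroys lattice clustering", {
  lattice <- ring_lattice(64, 6)
  cp <- clustering_coefficient(lattice)$Cp
  nulls <- random_null_metrics(lattice,
                               null_model_config(n_null = 20, seed = 7))
  expect_lt(nulls$Crand, cp)
})

test_that("rewired ring lattices are small-world, matched random graphs are not", {
  gammas <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    ws <- watts_strogatz(64, 6, 0.1)
    sw <- small_world(ws, null_model_config(n_null = 20, seed = s))
    gammas[s] <- sw$gamma
  }
  expect_true(all(gammas > 1))

  # an Erdos-Renyi graph is statistically its own null family
  er_gamma <- numeric(5)
  for (s in 1:5) {
    set.seed(100 + s)
    er <- random_adjacency(64, 0.15)
    er_gamma[s] <- small_world(er, null_model_config(n_null = 20,
                                                     seed = s))$gamma
  }
  expect_gt(mean(er_gamma), 0.75)
  expect_lt(mean(er_gamma), 1.3)
})

test_that("global efficiency never decreases when an edge is added", {
  set.seed(65)
  for (rep in 1:10) {
    A <- random_adjacency(12, 0.25)
    absent <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    B <- A
    B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1
    expect_gte(global_efficiency(B), global_efficiency(A))
  }
})

test_that("range aggregation uses the trapezoid rule", {
  expect_equal(volnet:::.trapezoid_auc(seq(0.1, 0.5, 0.1), rep(2, 5)), 0.8)
  expect_true(is.na(volnet:::.trapezoid_auc(0.2, 1.5)))
  set.seed(66)
  vals <- matrix(stats::runif(12 * 64, 500, 9000), 12, 64)
  net1 <- build_network(make_table(vals), sparsity_range = 0.25)
  rep1 <- metrics_over_range(net1, null_model_config(n_null = 3, seed = 1))
  expect_equal(nrow(rep1$per_sparsity), 1L)
  expect_true(is.na(rep1$auc$Cp))
  net3 <- build_network(make_table(vals),
                        sparsity_range = c(0.2, 0.3, 0.4))
  rep3 <- metrics_over_range(net3, null_model_config(n_null = 3, seed = 1))
  expect_equal(nrow(rep3$per_sparsity), 3L)
  expect_equal(rep3$auc$Cp,
               volnet:::.trapezoid_auc(rep3$per_sparsity$sparsity,
                                       rep3$per_sparsity$Cp))
})

test_that("adjacency validation rejects malformed input", {
  expect_error(clustering_coefficient(matrix(2, 3, 3)), "binary")
  m <- matrix(0, 3, 3)
  m[1, 2] <- 1
  expect_error(clustering_coefficient(m), "symmetric")
  m2 <- diag(3)
  expect_error(clustering_coefficient(m2), "zero diagonal")
  expect_error(random_null_metrics(matrix(0, 3, 3)), "at least 2 edges")
})
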