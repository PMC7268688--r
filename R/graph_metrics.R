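.check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (any(adj != 0 & adj != 1)) {
    stop("adjacency must be binary (0/1)", call. = FALSE)
  }
  if (any(adj != t(adj))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(adj) != 0)) {
    stop("adjacency must have a zero diagonal", call. = FALSE)
  }
  invisible(adj)
}

.distances <- function(adj) {
  m <- adj
  storage.mode(m) <- "integer"
  D <- .graph_distances_cpp(m)
  D <- matrix(as.numeric(D), nrow(adj))
  D[D < 0] <- Inf
  D
}

#' Clustering coefficient
#'
#' Per-node clustering on a binary graph: the fraction of a node's neighbour
#' pairs that are themselves connected, `C(i) = 2 t_i / (k_i (k_i - 1))`
#' with `t_i` the number of triangles through node `i`.  This is the exact
#' binary reduction of the geometric-mean (Onnela) weighted form
#' \eqn{C(i) = \frac{2}{k_i(k_i-1)} \sum_{j,k} (w_{ij} w_{jk} w_{ki})^{1/3}}.
#' Nodes with degree 0 or 1 have `C(i) = 0` by convention.
#'
#' @param adj symmetric binary adjacency matrix with zero diagonal.
#' @return list with `per_node` (numeric vector) and `Cp` (mean over all
#'   nodes).
#' @export
clustering_coefficient <- function(adj) {
  .check_adjacency(adj)
  k <- rowSums(adj)
  paths3 <- diag(adj %*% adj %*% adj)   # 2 * triangles through each node
  per_node <- ifelse(k > 1, paths3 / (k * (k - 1)), 0)
  names(per_node) <- rownames(adj)
  list(per_node = per_node, Cp = mean(per_node))
}

# Weighted (Onnela geometric-mean) clustering; weights scaled by max weight.
# Retained for cross-checking that the binary reduction is exact.
.clustering_onnela <- function(W) {
  stopifnot(isSymmetric(W), all(diag(W) == 0), all(W >= 0))
  k <- rowSums(W > 0)
  Wn <- if (max(W) > 0) W / max(W) else W
  B <- Wn^(1 / 3)
  s <- diag(B %*% B %*% B)
  per_node <- ifelse(k > 1, s / (k * (k - 1)), 0)
  list(per_node = per_node, Cp = mean(per_node))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs at finite distance
#' (pairs in different components are excluded from the mean, and the result
#' carries a `disconnected` flag).  Shortest paths are breadth-first
#' distances on unit-weight edges.
#'
#' @inheritParams clustering_coefficient
#' @return list with `Lp` (NaN for an edgeless graph), `disconnected`
#'   (logical: any unreachable pair), and `n_finite_pairs`.
#' @export
characteristic_path_length <- function(adj) {
  .check_adjacency(adj)
  n <- nrow(adj)
  D <- .distances(adj)
  off <- D[upper.tri(D)]
  finite <- is.finite(off)
  if (!any(finite)) {
    return(list(Lp = NaN, disconnected = TRUE, n_finite_pairs = 0L))
  }
  list(Lp = mean(off[finite]), disconnected = any(!finite),
       n_finite_pairs = 2L * sum(finite))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with
#' `1/Inf = 0` for disconnected pairs:
#' \eqn{E_{glob}(G) = \frac{1}{N(N-1)} \sum_{i \ne j} 1 / L_{ij}}.
#'
#' @inheritParams clustering_coefficient
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  .check_adjacency(adj)
  n <- nrow(adj)
  if (n < 2L) return(0)
  D <- .distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbours; nodes with fewer than two neighbours contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return scalar in `[0, 1]`.
#' @export
local_efficiency <- function(adj) {
  .check_adjacency(adj)
  n <- nrow(adj)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) >= 2L) {
      eff[i] <- global_efficiency(adj[nb, nb, drop = FALSE])
    }
  }
  mean(eff)
}

#' Null-model configuration
#'
#' Settings for the degree-preserving random rewiring (Maslov-Sneppen edge
#' swaps) used to calibrate small-worldness.
#'
#' @param n_null number of null graphs (default 100).
#' @param rewires_per_edge attempted swaps per edge per null graph
#'   (default 10).
#' @param seed integer RNG seed.
#' @return An object of class `null_model_config`.
#' @export
null_model_config <- function(n_null = 100L, rewires_per_edge = 10L,
                              seed = 1L) {
  stopifnot(n_null >= 1L, rewires_per_edge >= 1L)
  structure(list(n_null = as.integer(n_null),
                 rewires_per_edge = as.integer(rewires_per_edge),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Degree-preserving rewired copy of a graph
#'
#' Performs `rewires_per_edge * |E|` attempted edge swaps, rejecting swaps
#' that would create self-loops or multi-edges.  Every output graph has
#' exactly the degree sequence of the input.  Graphs whose degree sequence
#' admits no swap (e.g. complete graphs) are returned unchanged.
#'
#' @inheritParams clustering_coefficient
#' @param rewires_per_edge attempted swaps per edge.
#' @return a rewired binary adjacency matrix.
#' @export
rewire_adjacency <- function(adj, rewires_per_edge = 10L) {
  .check_adjacency(adj)
  n <- nrow(adj)
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2L) return(adj)
  res <- .rewire_edges_cpp(as.integer(idx[, 1L] - 1L),
                           as.integer(idx[, 2L] - 1L),
                           n, as.integer(rewires_per_edge * m))
  A <- matrix(0, n, n, dimnames = dimnames(adj))
  A[cbind(res[, 1L] + 1L, res[, 2L] + 1L)] <- 1
  A + t(A)
}

#' Null-model clustering and path length
#'
#' Generates `n_null` degree-preserving rewired versions of the graph and
#' returns the means of their clustering coefficient and characteristic path
#' length (finite-pairs convention).  Seeded and exactly reproducible.
#'
#' @inheritParams clustering_coefficient
#' @param config a [null_model_config()].
#' @return list with `Crand`, `Lrand`, and the per-null vectors `Cp_null`,
#'   `Lp_null`.
#' @export
random_null_metrics <- function(adj, config = null_model_config()) {
  .check_adjacency(adj)
  if (sum(adj) / 2 < 2) {
    stop("null models require a graph with at least 2 edges", call. = FALSE)
  }
  set.seed(config$seed)
  cp <- numeric(config$n_null)
  lp <- numeric(config$n_null)
  for (b in seq_len(config$n_null)) {
    null_adj <- rewire_adjacency(adj, config$rewires_per_edge)
    cp[b] <- clustering_coefficient(null_adj)$Cp
    lp[b] <- characteristic_path_length(null_adj)$Lp
  }
  list(Crand = mean(cp), Lrand = mean(lp), Cp_null = cp, Lp_null = lp)
}

#' Small-world assessment of a binary graph
#'
#' Computes `gamma = Cp / Crand` and `lambda = Lp / Lrand` against
#' degree-preserving rewired nulls.  The graph is called small-world when
#' `gamma > 1` and `lambda <= lambda_tol`; the tolerance operationalizes the
#' usual "path length comparable to random" requirement (default 1.5).
#'
#' @inheritParams random_null_metrics
#' @param lambda_tol upper bound on `lambda` for the small-world verdict.
#' @return list with `Cp`, `Lp`, `Crand`, `Lrand`, `gamma`, `lambda`,
#'   `is_small_world`, `degenerate` (TRUE when a null denominator is zero).
#' @export
small_world <- function(adj, config = null_model_config(),
                        lambda_tol = 1.5) {
  cp <- clustering_coefficient(adj)$Cp
  lp <- characteristic_path_length(adj)$Lp
  nulls <- random_null_metrics(adj, config)
  degenerate <- !is.finite(nulls$Crand) || nulls$Crand <= 0 ||
    !is.finite(nulls$Lrand) || nulls$Lrand <= 0
  gamma <- if (nulls$Crand > 0) cp / nulls$Crand else NA_real_
  lambda <- if (is.finite(nulls$Lrand) && nulls$Lrand > 0) {
    lp / nulls$Lrand
  } else {
    NA_real_
  }
  list(Cp = cp, Lp = lp, Crand = nulls$Crand, Lrand = nulls$Lrand,
       gamma = gamma, lambda = lambda,
       is_small_world = isTRUE(gamma > 1 && lambda <= lambda_tol),
       degenerate = degenerate)
}

#' Graph metrics across the sparsity range of a network
#'
#' Computes, at every sparsity level of a [build_network()] result, the
#' clustering coefficient, characteristic path length, global and local
#' efficiency, the null-model means `Crand` and `Lrand`, the small-world
#' ratios `gamma` and `lambda`, and the per-level small-world verdict; plus
#' the trapezoidal AUC of each metric over the sparsity grid.  The overall
#' small-world verdict is a majority vote over levels.
#'
#' @param net a `brain_network`.
#' @param config a [null_model_config()]; level `i` uses seed
#'   `config$seed + i - 1` so levels are independent but reproducible.
#' @param lambda_tol see [small_world()].
#' @return An object of class `metric_report`: list with `per_sparsity`
#'   (data frame), `auc` (named list; `NA` with fewer than two levels),
#'   `small_world_overall`, `lambda_tol`.
#' @export
metrics_over_range <- function(net, config = null_model_config(),
                               lambda_tol = 1.5) {
  stopifnot(inherits(net, "brain_network"))
  if (length(net$adjacency) < 1L) {
    stop("network has no sparsity levels", call. = FALSE)
  }
  rows <- vector("list", length(net$adjacency))
  for (i in seq_along(net$adjacency)) {
    adj <- net$adjacency[[i]]
    cfg_i <- null_model_config(config$n_null, config$rewires_per_edge,
                               config$seed + i - 1L)
    sw <- small_world(adj, cfg_i, lambda_tol = lambda_tol)
    lp_info <- characteristic_path_length(adj)
    rows[[i]] <- data.frame(
      sparsity = net$sparsity[i],
      Cp = sw$Cp, Lp = sw$Lp,
      Eglob = global_efficiency(adj), Eloc = local_efficiency(adj),
      Crand = sw$Crand, Lrand = sw$Lrand,
      gamma = sw$gamma, lambda = sw$lambda,
      small_world = sw$is_small_world,
      disconnected = lp_info$disconnected)
  }
  per_sparsity <- do.call(rbind, rows)
  metric_cols <- c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda")
  auc <- lapply(metric_cols, function(mc) {
    .trapezoid_auc(per_sparsity$sparsity, per_sparsity[[mc]])
  })
  names(auc) <- metric_cols
  structure(
    list(per_sparsity = per_sparsity, auc = auc,
         small_world_overall = mean(per_sparsity$small_world) > 0.5,
         lambda_tol = lambda_tol, null_config = config),
    class = "metric_report")
}

.trapezoid_auc <- function(x, y) {
  if (length(x) < 2L || any(!is.finite(y))) return(NA_real_)
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report over", nrow(x$per_sparsity), "sparsity level(s)\n")
  print(x$per_sparsity, digits = 4, row.names = FALSE)
  cat("small-world overall:", x$small_world_overall, "\n")
  invisible(x)
}
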