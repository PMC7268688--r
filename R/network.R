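#' Partial correlations between regional volumes
#'
#' Estimates the edge weights of the structural covariance network: the
#' partial correlation between every pair of regions across subjects,
#' obtained from the (optionally shrinkage-regularized) inverse covariance
#' matrix \eqn{\Omega} as \eqn{p_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}
#' \Omega_{jj}}}.
#'
#' With fewer subjects than regions the sample covariance is singular, so
#' some regularization is unavoidable.  The default shrinks the covariance
#' toward a scaled identity with the analytic Ledoit-Wolf intensity; a fixed
#' intensity in `[0, 1]` or `"none"` (which fails loudly on singular input)
#' can be requested instead.
#'
#' @param table a [volume_table()] or a numeric subjects x variables matrix
#'   (>= 3 rows, no missing values).
#' @param shrinkage `"auto"` (Ledoit-Wolf), `"none"`, or a fixed intensity
#'   in `[0, 1]`.
#' @return symmetric weight matrix with zero diagonal and entries in
#'   `[-1, 1]`; the shrinkage intensity used is attached as attribute
#'   `"shrinkage_intensity"`.
#' @export
partial_correlation_matrix <- function(table, shrinkage = "auto") {
  X <- if (inherits(table, "volume_table")) table$values else as.matrix(table)
  if (nrow(X) < 3L) {
    stop("at least 3 subjects are required", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("missing or non-finite values", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  S <- crossprod(Xc) / n
  rho <- if (identical(shrinkage, "auto")) {
    .ledoit_wolf_intensity(Xc, S)
  } else if (identical(shrinkage, "none")) {
    0
  } else if (is.numeric(shrinkage) && length(shrinkage) == 1L &&
             shrinkage >= 0 && shrinkage <= 1) {
    shrinkage
  } else {
    stop("'shrinkage' must be \"auto\", \"none\" or a number in [0, 1]",
         call. = FALSE)
  }
  mu <- sum(diag(S)) / p
  Sigma <- (1 - rho) * S
  diag(Sigma) <- diag(Sigma) + rho * mu
  Omega <- tryCatch(solve(Sigma), error = function(e) NULL)
  if (is.null(Omega) || !all(is.finite(Omega))) {
    stop("covariance matrix is singular (", n, " subjects, ", p,
         " regions); use shrinkage = \"auto\" or a fixed intensity > 0",
         call. = FALSE)
  }
  d <- sqrt(diag(Omega))
  P <- -Omega / tcrossprod(d)
  P <- (P + t(P)) / 2
  P[P > 1] <- 1
  P[P < -1] <- -1
  diag(P) <- 0
  dimnames(P) <- list(colnames(X), colnames(X))
  attr(P, "shrinkage_intensity") <- rho
  P
}

# Ledoit-Wolf (2004) analytic shrinkage intensity toward mu * I, with the
# 1/n covariance convention; Xc is the centred data matrix.
.ledoit_wolf_intensity <- function(Xc, S) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  mu <- sum(diag(S)) / p
  d2 <- (sum(S^2) - 2 * mu * sum(diag(S)) + p * mu^2) / p
  if (d2 <= .Machine$double.eps) return(0)
  # sum_k ||x_k x_k' - S||_F^2 = sum_k (x_k'x_k)^2 - n ||S||_F^2
  b2bar <- (sum(rowSums(Xc^2)^2) - n * sum(S^2)) / n^2 / p
  b2 <- min(b2bar, d2)
  b2 / d2
}

#' Binarize a weight matrix at a given sparsity
#'
#' Keeps the strongest `round(sparsity * p(p-1)/2)` undirected edges and
#' sets them to 1.  Edges are ranked by signed weight (`edge_rule =
#' "positive"`, so negative partial correlations are the last to enter) or
#' by absolute weight (`"abs"`).  Ties are broken deterministically by lower
#' first-node index, then higher second-node index, making the selection a
#' total order.
#'
#' @param weights symmetric numeric matrix with zero diagonal.
#' @param sparsity fraction of all possible edges to keep, in (0, 1].
#' @param edge_rule `"positive"` or `"abs"`.
#' @return binary adjacency matrix of the same dimension.
#' @export
binarize_by_sparsity <- function(weights, sparsity,
                                 edge_rule = c("positive", "abs")) {
  edge_rule <- match.arg(edge_rule)
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity > 1) {
    stop("'sparsity' must be in (0, 1]", call. = FALSE)
  }
  p <- nrow(weights)
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("'weights' must be symmetric", call. = FALSE)
  }
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[upper.tri(weights)]
  score <- if (edge_rule == "abs") abs(w) else w
  k <- round(sparsity * p * (p - 1) / 2)
  ord <- order(-score, ut[, 1L], -ut[, 2L])
  keep <- ord[seq_len(k)]
  A <- matrix(0, p, p, dimnames = dimnames(weights))
  A[ut[keep, , drop = FALSE]] <- 1
  A + t(A)
}

#' Build a structural covariance network over a sparsity range
#'
#' Estimates partial-correlation edge weights from a volume table and
#' binarizes them at each requested sparsity level.  Because binarization is
#' a nested top-k selection, the adjacency at a lower sparsity is always a
#' subgraph of the adjacency at a higher one.
#'
#' @inheritParams partial_correlation_matrix
#' @inheritParams binarize_by_sparsity
#' @param sparsity_range numeric vector of sparsity levels; the default grid
#'   0.10 to 0.46 in steps of 0.02 (19 levels) spans densities at which
#'   structural covariance networks are typically analysed.
#' @return An object of class `brain_network`: list with `weights`,
#'   `adjacency` (named list, one binary matrix per sparsity level),
#'   `sparsity`, `edge_rule`, `shrinkage`, `shrinkage_intensity`,
#'   `workflow`.
#' @export
build_network <- function(table, sparsity_range = default_sparsity_grid(),
                          shrinkage = "auto",
                          edge_rule = c("positive", "abs")) {
  edge_rule <- match.arg(edge_rule)
  weights <- partial_correlation_matrix(table, shrinkage = shrinkage)
  adjacency <- list()
  for (s in sparsity_range) {
    adjacency[[sprintf("%.2f", s)]] <-
      binarize_by_sparsity(weights, s, edge_rule = edge_rule)
  }
  workflow <- if (inherits(table, "volume_table")) table$workflow else NA
  .new_brain_network(weights = weights, adjacency = adjacency,
                     sparsity = as.numeric(sparsity_range),
                     edge_rule = edge_rule, shrinkage = shrinkage,
                     shrinkage_intensity = attr(weights,
                                                "shrinkage_intensity"),
                     workflow = workflow)
}

#' Default sparsity grid
#'
#' @return `seq(0.10, 0.46, by = 0.02)`, the 19-level default grid.
#' @export
default_sparsity_grid <- function() {
  seq(0.10, 0.46, by = 0.02)
}

.new_brain_network <- function(weights, adjacency, sparsity, edge_rule,
                               shrinkage, shrinkage_intensity, workflow,
                               atlas = NULL) {
  structure(
    list(weights = weights, adjacency = adjacency, sparsity = sparsity,
         edge_rule = edge_rule, shrinkage = shrinkage,
         shrinkage_intensity = shrinkage_intensity, workflow = workflow),
    class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat("brain_network: ", nrow(x$weights), " nodes, ",
      length(x$adjacency), " sparsity level(s) [",
      sprintf("%.2f", min(x$sparsity)), "-",
      sprintf("%.2f", max(x$sparsity)), "], edge rule: ", x$edge_rule,
      ", shrinkage intensity: ",
      format(x$shrinkage_intensity, digits = 3), "\n", sep = "")
  invisible(x)
}
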