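# Independent brute-force oracles used to validate the package's graph,
# partial-correlation and variance-components code.  These deliberately use
# different algorithms from the implementation (edge-list triangle
# enumeration, Floyd-Warshall, residual regression, aov mean squares).

oracle_local_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        links <- links + A[nb[a], nb[b]]
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  off <- D[upper.tri(D)]
  mean(off[is.finite(off)])
}

oracle_eglob <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_eloc <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_eglob(A[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# Erdos-Renyi style random adjacency; caller controls the RNG state.
random_adjacency <- function(n, p_edge) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p_edge)
  A + t(A)
}

ring_lattice <- function(n, k) {
  stopifnot(k %% 2 == 0)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      A[i, j] <- A[j, i] <- 1
    }
  }
  A
}

# Watts-Strogatz style rewiring of a ring lattice: each edge is, with
# probability p, re-attached at one endpoint to a uniformly chosen node
# (avoiding self-loops and duplicates).
watts_strogatz <- function(n, k, p) {
  A <- ring_lattice(n, k)
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    if (stats::runif(1) < p) {
      i <- idx[e, 1]
      j <- idx[e, 2]
      new_j <- sample(seq_len(n), 1)
      if (new_j != i && A[i, new_j] == 0) {
        A[i, j] <- A[j, i] <- 0
        A[i, new_j] <- A[new_j, i] <- 1
      }
    }
  }
  A
}

# Partial correlation by residual regression: regress i and j on all other
# variables and correlate the residuals.
oracle_partial_correlation <- function(X) {
  p <- ncol(X)
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      ri <- stats::resid(stats::lm(X[, i] ~ X[, others]))
      rj <- stats::resid(stats::lm(X[, j] ~ X[, others]))
      P[i, j] <- P[j, i] <- stats::cor(ri, rj)
    }
  }
  P
}

# ICC(A,1) with mean squares taken from aov() rather than closed-form sums.
oracle_icc_aov <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  df <- data.frame(v = as.vector(y),
                   subj = factor(rep(seq_len(n), k)),
                   meas = factor(rep(seq_len(k), each = n)))
  ms <- stats::anova(stats::aov(v ~ subj + meas, data = df))[["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Classic one-way ANOVA F from explicit between/within mean squares.
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Small volume table on the atlas grid from a plain matrix.
make_table <- function(values, workflow = "test", measurement_id = 1L) {
  volume_table(values, workflow = workflow, measurement_id = measurement_id)
}
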