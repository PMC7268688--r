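#' Intraclass correlation of repeated volume measurements
#'
#' Per-region test-retest reliability from two or more repeated volume
#' tables sharing the same subjects: the two-way random-effects, absolute
#' agreement, single-measures intraclass correlation (ICC(A,1)), computed
#' from the balanced two-way mean squares
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C -
#'   MS_E)}}
#' with subjects as rows and measurements as columns.  Regions with zero
#' total variance are reported as ICC 1 and flagged as degenerate.
#'
#' @param tables list of >= 2 [volume_table()] objects with identical
#'   subjects and regions (repeated measurements).
#' @return An object of class `icc_result`: list with `per_region` (named
#'   numeric), `average` (mean over regions), `model` (description tag),
#'   `degenerate` (labels of zero-variance regions), `n_subjects`,
#'   `n_measurements`.
#' @export
icc <- function(tables) {
  .check_repeats(tables)
  k <- length(tables)
  n <- nrow(tables[[1L]]$values)
  labels <- tables[[1L]]$region_labels
  p <- length(labels)
  per_region <- numeric(p)
  degenerate <- character(0L)
  for (r in seq_len(p)) {
    y <- vapply(tables, function(t) t$values[, r], numeric(n))  # n x k
    grand <- mean(y)
    sst <- sum((y - grand)^2)
    if (sst <= .Machine$double.eps * max(1, grand^2) * n * k) {
      per_region[r] <- 1
      degenerate <- c(degenerate, labels[r])
      next
    }
    rm_ <- rowMeans(y)
    cm_ <- colMeans(y)
    ssr <- k * sum((rm_ - grand)^2)
    ssc <- n * sum((cm_ - grand)^2)
    sse <- sst - ssr - ssc
    msr <- ssr / (n - 1)
    msc <- ssc / (k - 1)
    mse <- sse / ((n - 1) * (k - 1))
    per_region[r] <- (msr - mse) /
      (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  names(per_region) <- labels
  structure(
    list(per_region = per_region, average = mean(per_region),
         model = "two-way random effects, absolute agreement, single measures (ICC(A,1))",
         degenerate = degenerate, n_subjects = n, n_measurements = k),
    class = "icc_result")
}

.check_repeats <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop("at least 2 repeated volume tables are required", call. = FALSE)
  }
  ref <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!inherits(t, "volume_table") ||
        !identical(t$subject_ids, ref$subject_ids) ||
        !identical(t$region_labels, ref$region_labels)) {
      stop("all tables must share the same subjects and regions",
           call. = FALSE)
    }
  }
  invisible(tables)
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC (", x$model, ")\n", sep = "")
  cat("  average over ", length(x$per_region), " regions: ",
      format(x$average, digits = 4), "\n", sep = "")
  if (length(x$degenerate) > 0L) {
    cat("  degenerate (zero-variance) regions:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bland-Altman agreement of two paired measurements
#'
#' Differences `x - y` are summarised by their mean, SD (n-1 denominator)
#' and the limits of agreement `mean +/- 1.96 SD`, plus the percentage of
#' pairs falling inside the limits.
#'
#' @param x,y numeric vectors of equal length >= 2 (paired measurements).
#' @return An object of class `bland_altman_result`: list with `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `pct_within`, `n`, and the
#'   per-pair `differences` and `means` (for plotting).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("at least 2 pairs are required", call. = FALSE)
  d <- x - y
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- mean_diff - 1.96 * sd_diff
  loa_high <- mean_diff + 1.96 * sd_diff
  structure(
    list(mean_diff = mean_diff, sd_diff = sd_diff,
         loa_low = loa_low, loa_high = loa_high,
         pct_within = 100 * mean(d >= loa_low & d <= loa_high),
         n = length(d), differences = d, means = (x + y) / 2),
    class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n", sep = "")
  cat("  mean difference: ", format(x$mean_diff, digits = 4),
      ", SD: ", format(x$sd_diff, digits = 4), "\n", sep = "")
  cat("  limits of agreement: [", format(x$loa_low, digits = 4), ", ",
      format(x$loa_high, digits = 4), "]  (",
      format(x$pct_within, digits = 4), "% of pairs within)\n", sep = "")
  invisible(x)
}

#' Per-region one-way ANOVA across workflows
#'
#' For every atlas region, a one-way fixed-effects ANOVA of volume against
#' workflow group, with the number of regions significant at `alpha` after
#' the selected multiple-testing adjustment (default none, i.e. raw
#' p < alpha).
#'
#' @param tables named list of >= 2 [volume_table()] objects (one per
#'   workflow, each with >= 2 subjects).
#' @param alpha significance level (default 0.05).
#' @param adjustment `"none"` or `"BH"` (Benjamini-Hochberg).
#' @return An object of class `region_comparison`: list with `per_region`
#'   (data frame: region, F, p, p_adj), `n_significant`, `alpha`,
#'   `adjustment`.
#' @export
anova_per_region <- function(tables, alpha = 0.05,
                             adjustment = c("none", "BH")) {
  adjustment <- match.arg(adjustment)
  if (!is.list(tables) || length(tables) < 2L) {
    stop("at least 2 workflow tables are required", call. = FALSE)
  }
  sizes <- vapply(tables, function(t) nrow(t$values), integer(1L))
  if (any(sizes < 2L)) {
    stop("every workflow group needs at least 2 subjects", call. = FALSE)
  }
  labels <- tables[[1L]]$region_labels
  for (t in tables[-1L]) {
    if (!identical(t$region_labels, labels)) {
      stop("all tables must share the same region set", call. = FALSE)
    }
  }
  group <- factor(rep(names(tables), times = sizes))
  fstat <- pval <- numeric(length(labels))
  for (r in seq_along(labels)) {
    v <- unlist(lapply(tables, function(t) t$values[, r]), use.names = FALSE)
    if (stats::var(v) <= .Machine$double.eps * max(1, mean(v)^2)) {
      fstat[r] <- 0
      pval[r] <- 1
      next
    }
    ow <- stats::oneway.test(v ~ group, var.equal = TRUE)
    fstat[r] <- unname(ow$statistic)
    pval[r] <- ow$p.value
  }
  p_adj <- stats::p.adjust(pval, method = if (adjustment == "BH") "BH"
                                          else "none")
  per_region <- data.frame(region = labels, F = fstat, p = pval,
                           p_adj = p_adj, stringsAsFactors = FALSE)
  structure(
    list(per_region = per_region, n_significant = sum(p_adj < alpha),
         alpha = alpha, adjustment = adjustment),
    class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat("per-region one-way ANOVA: ", x$n_significant, " of ",
      nrow(x$per_region), " regions significant at alpha = ", x$alpha,
      " (adjustment: ", x$adjustment, ")\n", sep = "")
  invisible(x)
}

#' Permutation comparison of network metrics between workflows
#'
#' For every pair of workflows and every requested graph metric, computes
#' the observed difference in the metric's sparsity-range summary (the
#' trapezoidal AUC over the grid, or the plain value for a single level)
#' between the two group-level networks, and a two-sided p-value from a
#' permutation null: workflow labels are randomly swapped within each
#' subject (the subjects are paired across workflows) and both networks are
#' rebuilt from scratch in every permutation.
#'
#' @param tables named list of >= 2 [volume_table()] objects with identical
#'   subjects.
#' @param sparsity_range,shrinkage,edge_rule passed to [build_network()].
#' @param metrics subset of `c("Cp", "Lp", "Eglob", "Eloc")`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return An object of class `network_comparison`: list with `comparisons`
#'   (data frame: workflow_a, workflow_b, metric, observed_a, observed_b,
#'   observed_diff, p_value), `n_perm`, `sparsity_range`.
#' @export
compare_network_metrics <- function(tables,
                                    sparsity_range = default_sparsity_grid(),
                                    shrinkage = "auto",
                                    edge_rule = "positive",
                                    metrics = c("Cp", "Lp", "Eglob", "Eloc"),
                                    n_perm = 1000L, seed = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.list(tables) || length(tables) < 2L) {
    stop("at least 2 workflow tables are required", call. = FALSE)
  }
  if (n_perm < 100L) stop("'n_perm' must be >= 100", call. = FALSE)
  ref_ids <- tables[[1L]]$subject_ids
  for (t in tables[-1L]) {
    if (!identical(t$subject_ids, ref_ids)) {
      stop("paired permutation requires identical subjects in every table",
           call. = FALSE)
    }
  }
  summarise <- function(values_matrix) {
    net <- build_network(values_matrix, sparsity_range = sparsity_range,
                         shrinkage = shrinkage, edge_rule = edge_rule)
    out <- numeric(length(metrics))
    names(out) <- metrics
    per_level <- matrix(NA_real_, length(net$adjacency), length(metrics),
                        dimnames = list(NULL, metrics))
    for (i in seq_along(net$adjacency)) {
      adj <- net$adjacency[[i]]
      if ("Cp" %in% metrics) {
        per_level[i, "Cp"] <- clustering_coefficient(adj)$Cp
      }
      if ("Lp" %in% metrics) {
        per_level[i, "Lp"] <- characteristic_path_length(adj)$Lp
      }
      if ("Eglob" %in% metrics) {
        per_level[i, "Eglob"] <- global_efficiency(adj)
      }
      if ("Eloc" %in% metrics) {
        per_level[i, "Eloc"] <- local_efficiency(adj)
      }
    }
    for (mc in metrics) {
      out[mc] <- if (length(sparsity_range) >= 2L) {
        .trapezoid_auc(sparsity_range, per_level[, mc])
      } else {
        per_level[1L, mc]
      }
    }
    out
  }
  pairs <- utils::combn(names(tables), 2L)
  set.seed(seed)
  rows <- list()
  n_sub <- length(ref_ids)
  for (pc in seq_len(ncol(pairs))) {
    wa <- pairs[1L, pc]
    wb <- pairs[2L, pc]
    va <- tables[[wa]]$values
    vb <- tables[[wb]]$values
    obs_a <- summarise(va)
    obs_b <- summarise(vb)
    obs_diff <- obs_a - obs_b
    exceed <- stats::setNames(numeric(length(metrics)), metrics)
    for (b in seq_len(n_perm)) {
      flip <- stats::runif(n_sub) < 0.5
      pa <- va
      pb <- vb
      pa[flip, ] <- vb[flip, ]
      pb[flip, ] <- va[flip, ]
      pd <- summarise(pa) - summarise(pb)
      exceed <- exceed + (abs(pd) >= abs(obs_diff) - 1e-12)
    }
    pvals <- (1 + exceed) / (n_perm + 1)
    rows[[pc]] <- data.frame(
      workflow_a = wa, workflow_b = wb, metric = metrics,
      observed_a = unname(obs_a), observed_b = unname(obs_b),
      observed_diff = unname(obs_diff), p_value = unname(pvals),
      stringsAsFactors = FALSE)
  }
  structure(
    list(comparisons = do.call(rbind, rows), n_perm = as.integer(n_perm),
         sparsity_range = sparsity_range),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("network metric comparison (", x$n_perm, " permutations)\n", sep = "")
  print(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}
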