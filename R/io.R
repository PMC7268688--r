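#' Write a brain network to a directory
#'
#' Writes the partial-correlation weight matrix (`weights.csv`), one binary
#' adjacency matrix per sparsity level (`adjacency_<sparsity>.csv`) and a
#' small `network.json` with the construction parameters.  All matrices are
#' CSV with region labels as header and first column.
#'
#' @param net a `brain_network`, see [build_network()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "brain_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_labelled_matrix(net$weights, file.path(dir, "weights.csv"),
                         digits = 12)
  for (s in names(net$adjacency)) {
    .write_labelled_matrix(net$adjacency[[s]],
                           file.path(dir, paste0("adjacency_", s, ".csv")),
                           digits = NA)
  }
  meta <- list(sparsity = net$sparsity, edge_rule = net$edge_rule,
               shrinkage = net$shrinkage,
               shrinkage_intensity = net$shrinkage_intensity,
               workflow = net$workflow)
  jsonlite::write_json(meta, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a brain network written by [write_network()]
#'
#' @param dir directory produced by [write_network()].
#' @param atlas region atlas.
#' @return A `brain_network` object.
#' @export
read_network <- function(dir, atlas = load_region_atlas()) {
  meta <- jsonlite::read_json(file.path(dir, "network.json"),
                              simplifyVector = TRUE)
  weights <- .read_labelled_matrix(file.path(dir, "weights.csv"))
  sparsity <- as.numeric(meta$sparsity)
  adjacency <- list()
  for (s in sprintf("%.2f", sparsity)) {
    adjacency[[s]] <- .read_labelled_matrix(
      file.path(dir, paste0("adjacency_", s, ".csv")))
  }
  .new_brain_network(weights = weights, adjacency = adjacency,
                     sparsity = sparsity, edge_rule = meta$edge_rule,
                     shrinkage = meta$shrinkage,
                     shrinkage_intensity = meta$shrinkage_intensity,
                     workflow = meta$workflow, atlas = atlas)
}

#' Write a metric report
#'
#' Serializes a `metric_report` (see [metrics_over_range()]) to JSON: one
#' record per sparsity level plus the range-aggregated (trapezoidal AUC)
#' values and the overall small-world verdict.
#'
#' @param report a `metric_report`.
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  out <- list(per_sparsity = report$per_sparsity,
              auc = report$auc,
              small_world_overall = report$small_world_overall,
              lambda_tol = report$lambda_tol)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

.write_labelled_matrix <- function(m, path, digits = 12) {
  df <- data.frame(region = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    df[[colnames(m)[j]]] <- if (is.na(digits)) {
      format(col, trim = TRUE)
    } else {
      sprintf(paste0("%.", digits, "g"), col)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_labelled_matrix <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- raw[[1L]]
  storage.mode(m) <- "double"
  m
}
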