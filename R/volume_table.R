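#' Construct a volume table
#'
#' A volume table is the unit of exchange between all pipeline stages: a
#' subjects x regions matrix of regional brain volumes in cubic millimetres,
#' with the region axis fixed to the 64-region atlas order.
#'
#' @param values numeric matrix, subjects in rows, regions in columns.
#'   Columns must be named with atlas region labels (see [region_labels()]);
#'   they are reordered to atlas order if necessary.
#' @param subject_ids character vector of unique subject identifiers;
#'   defaults to the rownames of `values`.
#' @param workflow free-text tag for the preprocessing workflow that produced
#'   the volumes (e.g. `"BET"`, `"iBEAT"`, `"iBEAT_corrected"`).
#' @param measurement_id integer >= 1 identifying the repeated measurement.
#' @param atlas region atlas, see [load_region_atlas()].
#' @return An object of class `volume_table`: a list with elements `values`
#'   (matrix), `subject_ids`, `region_labels`, `workflow`, `measurement_id`.
#' @export
volume_table <- function(values, subject_ids = rownames(values),
                         workflow = "unspecified", measurement_id = 1L,
                         atlas = load_region_atlas()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  labels <- region_labels(atlas)
  if (is.null(colnames(values))) {
    if (ncol(values) != length(labels)) {
      stop("unnamed 'values' must have exactly ", length(labels),
           " columns in atlas order", call. = FALSE)
    }
    colnames(values) <- labels
  }
  unknown <- setdiff(colnames(values), labels)
  if (length(unknown) > 0L) {
    stop("region column(s) not in the atlas: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(labels, colnames(values))
  if (length(absent) > 0L) {
    stop("missing region column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  values <- values[, labels, drop = FALSE]
  if (is.null(subject_ids)) {
    subject_ids <- paste0("subject", seq_len(nrow(values)))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values)) {
    stop("length of 'subject_ids' must equal the number of rows", call. = FALSE)
  }
  dup <- anyDuplicated(subject_ids)
  if (dup) {
    stop("duplicate subject id '", subject_ids[dup], "'", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("volumes must be finite and strictly positive; first offence at ",
         "subject '", subject_ids[bad[1L, 1L]], "', region '",
         labels[bad[1L, 2L]], "'", call. = FALSE)
  }
  rownames(values) <- subject_ids
  structure(
    list(values = values, subject_ids = subject_ids, region_labels = labels,
         workflow = as.character(workflow),
         measurement_id = as.integer(measurement_id)),
    class = "volume_table"
  )
}

#' @export
print.volume_table <- function(x, ...) {
  cat("volume_table: ", nrow(x$values), " subjects x ", ncol(x$values),
      " regions  [workflow: ", x$workflow,
      ", measurement ", x$measurement_id, "]\n", sep = "")
  cat("  volume range: ", format(min(x$values), digits = 5), " - ",
      format(max(x$values), digits = 5), " mm^3\n", sep = "")
  invisible(x)
}

#' Read a volume table from a CSV file
#'
#' The file must be comma-separated with a header row: first column the
#' subject id, remaining columns one per atlas region (labelled as in
#' [region_labels()]).  Columns are reordered to atlas order; values are
#' volumes in cubic millimetres and must be finite and strictly positive.
#'
#' @param path path to a CSV file.
#' @param atlas region atlas.
#' @inheritParams volume_table
#' @return A [volume_table()].
#' @export
read_volume_table <- function(path, atlas = load_region_atlas(),
                              workflow = "unspecified", measurement_id = 1L) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2L) {
    stop("'", path, "' has no region columns", call. = FALSE)
  }
  ids <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  non_num <- which(!vapply(vals, is.numeric, logical(1L)))
  if (length(non_num) > 0L) {
    stop("non-numeric volume in column '", names(vals)[non_num[1L]],
         "' of '", path, "'", call. = FALSE)
  }
  m <- as.matrix(vals)
  volume_table(m, subject_ids = ids, workflow = workflow,
               measurement_id = measurement_id, atlas = atlas)
}

#' Write a volume table to a CSV file
#'
#' Values are written with 12 significant digits; re-reading a written file
#' reproduces the table exactly on that numeric grid (write/read/write is
#' idempotent).
#'
#' @param table a [volume_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(table, path) {
  stopifnot(inherits(table, "volume_table"))
  df <- data.frame(subject_id = table$subject_ids, stringsAsFactors = FALSE)
  for (lab in table$region_labels) {
    df[[lab]] <- sprintf("%.12g", table$values[, lab])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
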