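#' Load the packaged 64-region grey-matter atlas
#'
#' Returns the ordered node list used throughout the package: 64 grey-matter
#' regions (32 per hemisphere) covering cortical gyri plus thalamus, basal
#' ganglia, amygdala, hippocampus and the cerebellar hemispheres.  Row order
#' is the canonical node order of every volume table, network matrix and
#' metric report produced by the package.
#'
#' Label-map codes are assigned 1..64 in atlas row order; external label maps
#' must be remapped to this convention before use with
#' [region_volume()] / [all_region_volumes()].
#'
#' @return A data frame with one row per region and columns
#'   \describe{
#'     \item{index}{integer 1..64, the canonical node index}
#'     \item{name}{region name}
#'     \item{hemisphere}{"Left" or "Right"}
#'     \item{label_code}{positive integer code used in label maps}
#'     \item{label}{unique column label, `"<name>_<hemisphere>"`, used as the
#'       region axis of volume tables and network matrices}
#'   }
#' @export
#' @examples
#' atlas <- load_region_atlas()
#' nrow(atlas)          # 64
#' table(atlas$hemisphere)
load_region_atlas <- function() {
  path <- system.file("extdata", "region_atlas_64.csv",
                      package = "volnet", mustWork = TRUE)
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_atlas(atlas)
  atlas$label <- paste(gsub("[^A-Za-z0-9]+", ".", atlas$name),
                       atlas$hemisphere, sep = "_")
  atlas
}

#' Region labels in atlas order
#'
#' @param atlas a region atlas, as returned by [load_region_atlas()].
#' @return character vector of 64 unique region labels.
#' @export
region_labels <- function(atlas = load_region_atlas()) {
  atlas$label
}

.validate_atlas <- function(atlas) {
  required <- c("index", "name", "hemisphere", "label_code")
  missing_cols <- setdiff(required, names(atlas))
  if (length(missing_cols) > 0L) {
    stop("atlas data is corrupt: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(atlas) != 64L) {
    stop("atlas data is corrupt: expected 64 rows, found ", nrow(atlas),
         call. = FALSE)
  }
  bad <- which(!atlas$hemisphere %in% c("Left", "Right"))
  if (length(bad) > 0L) {
    stop("atlas data is corrupt: row ", bad[1L],
         " has hemisphere '", atlas$hemisphere[bad[1L]], "'", call. = FALSE)
  }
  if (!identical(as.integer(atlas$index), 1:64)) {
    stop("atlas data is corrupt: row ",
         which(as.integer(atlas$index) != 1:64)[1L],
         " breaks the contiguous 1..64 index order", call. = FALSE)
  }
  bad <- which(is.na(atlas$label_code) | atlas$label_code < 1)
  if (length(bad) > 0L) {
    stop("atlas data is corrupt: row ", bad[1L],
         " has a non-positive label code", call. = FALSE)
  }
  if (anyDuplicated(atlas$label_code)) {
    stop("atlas data is corrupt: row ", anyDuplicated(atlas$label_code),
         " duplicates a label code", call. = FALSE)
  }
  key <- paste(atlas$name, atlas$hemisphere)
  if (anyDuplicated(key)) {
    stop("atlas data is corrupt: row ", anyDuplicated(key),
         " duplicates a (name, hemisphere) pair", call. = FALSE)
  }
  counts <- table(atlas$hemisphere)
  if (!all(counts == 32L)) {
    stop("atlas data is corrupt: expected 32 regions per hemisphere, found ",
         paste(names(counts), counts, collapse = ", "), call. = FALSE)
  }
  invisible(atlas)
}
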