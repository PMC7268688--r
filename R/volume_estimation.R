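#' Estimate the volume of one atlas region for a subject
#'
#' Implements atlas-based regional volumetry: with the individual registered
#' to the template by a rigid + affine (linear) transform and a residual
#' nonlinear warp, the subject's volume of a region is the integral of the
#' nonlinear Jacobian determinant over the template region, divided by the
#' linear volume change,
#' \deqn{V_i = \frac{\sum_{V_t} J_F \cdot v}{|A^{rigid}_{3\times3}|\,
#'       |A^{affine}_{3\times3}|},}
#' where the sum runs over template voxels of the region, `v` is the voxel
#' volume, and the determinants are those of the upper-left 3x3 sub-matrices
#' of the individual-to-template transforms.
#'
#' The convention implemented is that the stored Jacobian field describes
#' the nonlinear (post-affine) component only, so `J_F = 1` for a purely
#' linear registration and linear scaling enters solely through the
#' denominator.  `eq1_literal = TRUE` instead folds the inverse linear
#' determinant into the Jacobian as well (treating the field as
#' `J_F / (|rigid| |affine|)`), which double-counts linear scaling; it is
#' retained only for comparing the two readings of the formula.
#'
#' @param fixture a [registration_fixture()].
#' @param label_code region code present in the label map.
#' @param eq1_literal logical, see Details.
#' @return volume in mm^3.
#' @export
region_volume <- function(fixture, label_code, eq1_literal = FALSE) {
  stopifnot(inherits(fixture, "registration_fixture"))
  mask <- fixture$label_map == label_code
  if (!any(mask)) {
    stop("label code ", label_code, " is not present in the label map",
         call. = FALSE)
  }
  d_rigid <- abs(det(fixture$rigid[1:3, 1:3]))
  d_affine <- abs(det(fixture$affine[1:3, 1:3]))
  if (d_rigid <= 0 || d_affine <= 0) {
    stop("transform determinants must be non-zero", call. = FALSE)
  }
  voxel_volume <- prod(fixture$voxel_size)
  jac_sum <- sum(fixture$jacobian[mask])
  denom <- d_rigid * d_affine
  if (eq1_literal) {
    jac_sum <- jac_sum / denom
  }
  jac_sum * voxel_volume / denom
}

#' Estimate volumes of all atlas regions for one subject
#'
#' Applies [region_volume()] to every atlas region.  Regions whose label
#' code does not occur in the label map are reported as missing (`NA`), not
#' as zero.
#'
#' @param fixture a [registration_fixture()].
#' @param atlas region atlas.
#' @param subject_id identifier attached to the resulting row.
#' @param eq1_literal see [region_volume()].
#' @return A data frame with one row per atlas region and columns
#'   `subject_id`, `region` (label), `label_code`, `volume` (NA when the
#'   region is absent from the label map), `missing`.
#' @export
all_region_volumes <- function(fixture, atlas = load_region_atlas(),
                               subject_id = "subject1",
                               eq1_literal = FALSE) {
  stopifnot(inherits(fixture, "registration_fixture"))
  present_codes <- unique(as.vector(fixture$label_map))
  volume <- rep(NA_real_, nrow(atlas))
  for (i in seq_len(nrow(atlas))) {
    code <- atlas$label_code[i]
    if (code %in% present_codes) {
      volume[i] <- region_volume(fixture, code, eq1_literal = eq1_literal)
    }
  }
  data.frame(subject_id = subject_id, region = region_labels(atlas),
             label_code = atlas$label_code, volume = volume,
             missing = is.na(volume), stringsAsFactors = FALSE)
}

#' Assemble per-subject volume rows into a volume table
#'
#' @param rows list of data frames from [all_region_volumes()], one per
#'   subject, each with full atlas coverage.
#' @param workflow,measurement_id,atlas passed to [volume_table()].
#' @return A [volume_table()].
#' @export
volumes_to_table <- function(rows, workflow = "unspecified",
                             measurement_id = 1L,
                             atlas = load_region_atlas()) {
  stopifnot(length(rows) >= 1L)
  incomplete <- vapply(rows, function(r) any(r$missing), logical(1L))
  if (any(incomplete)) {
    stop("subject '", rows[[which(incomplete)[1L]]]$subject_id[1L],
         "' has regions missing from its label map; cannot form a table",
         call. = FALSE)
  }
  values <- do.call(rbind, lapply(rows, function(r) r$volume))
  colnames(values) <- rows[[1L]]$region
  ids <- vapply(rows, function(r) r$subject_id[1L], character(1L))
  volume_table(values, subject_ids = ids, workflow = workflow,
               measurement_id = measurement_id, atlas = atlas)
}
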