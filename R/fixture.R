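#' Construct a registration fixture
#'
#' A registration fixture bundles everything the atlas-based volume
#' estimator needs for one subject: the template label map with its voxel
#' size, the rigid and affine 4x4 transform matrices (mapping the individual
#' to the template), and the Jacobian-determinant field of the nonlinear
#' component of the warp, sampled on the template grid.
#'
#' @param label_map 3-D integer array of region label codes (0 = background).
#' @param voxel_size numeric length-3, mm per axis.
#' @param rigid 4x4 rigid transform; its 3x3 sub-matrix must be a rotation
#'   (determinant 1 within 1e-6).
#' @param affine 4x4 affine transform.
#' @param jacobian 3-D strictly positive array congruent with `label_map`.
#' @param atlas region atlas used to check label codes.
#' @return An object of class `registration_fixture`.
#' @export
registration_fixture <- function(label_map, voxel_size, rigid, affine,
                                 jacobian, atlas = load_region_atlas()) {
  stopifnot(length(dim(label_map)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0),
            identical(dim(label_map), dim(jacobian)),
            identical(dim(rigid), c(4L, 4L)),
            identical(dim(affine), c(4L, 4L)))
  if (abs(det(rigid[1:3, 1:3]) - 1) > 1e-6) {
    stop("rigid 3x3 sub-matrix must have determinant 1 (rotation, no scale)",
         call. = FALSE)
  }
  if (any(jacobian <= 0)) {
    stop("jacobian field must be strictly positive everywhere", call. = FALSE)
  }
  codes <- sort(unique(as.vector(label_map)))
  unknown <- setdiff(codes, c(0L, atlas$label_code))
  if (length(unknown) > 0L) {
    stop("label map contains code(s) outside the atlas: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(label_map = label_map, voxel_size = as.numeric(voxel_size),
         rigid = rigid, affine = affine, jacobian = jacobian),
    class = "registration_fixture")
}

#' Generate a synthetic registration fixture
#'
#' Builds a template label map by packing the requested number of voxels per
#' region into a cuboid grid (regions occupy disjoint runs of voxels, so
#' placements can never overlap), an identity rigid transform, an isotropic
#' affine scaling, and either a uniform or a smooth random Jacobian field.
#'
#' The smooth field is `1 + a * (s1(x) + s2(y) + s3(z))` with random-phase
#' integer-frequency sinusoids per axis, so it is strictly positive for
#' `3 * a < 1` and has spatial mean very close to 1.
#'
#' @param seed integer seed for the random field.
#' @param region_voxel_counts named or plain integer vector: voxels per
#'   region label code (names are the codes; unnamed vectors use codes
#'   1..length).
#' @param voxel_size mm per axis (length 3).
#' @param affine_scale isotropic affine scale factor (> 0).
#' @param jacobian `"uniform"` (constant `jacobian_value`) or `"smooth"`.
#' @param jacobian_value constant for the uniform field.
#' @param smooth_amplitude per-sinusoid amplitude `a` of the smooth field.
#' @param atlas region atlas.
#' @return A [registration_fixture()].
#' @export
generate_registration_fixture <- function(seed = 1L, region_voxel_counts,
                                          voxel_size = c(1, 1, 1),
                                          affine_scale = 1,
                                          jacobian = c("uniform", "smooth"),
                                          jacobian_value = 1,
                                          smooth_amplitude = 0.15,
                                          atlas = load_region_atlas()) {
  jacobian <- match.arg(jacobian)
  stopifnot(affine_scale > 0, all(region_voxel_counts > 0))
  codes <- if (is.null(names(region_voxel_counts))) {
    seq_along(region_voxel_counts)
  } else {
    as.integer(names(region_voxel_counts))
  }
  counts <- as.integer(region_voxel_counts)
  total <- sum(counts)
  side <- max(2L, ceiling((total * 1.3)^(1 / 3)))
  dims <- c(side, side, side)
  lab <- integer(prod(dims))
  pos <- 1L
  for (i in seq_along(codes)) {
    lab[pos:(pos + counts[i] - 1L)] <- codes[i]
    pos <- pos + counts[i]
  }
  label_map <- array(lab, dim = dims)
  jac <- if (jacobian == "uniform") {
    array(jacobian_value, dim = dims)
  } else {
    set.seed(seed)
    if (3 * smooth_amplitude >= 1) {
      stop("'smooth_amplitude' must be < 1/3 to keep the field positive",
           call. = FALSE)
    }
    field <- array(1, dim = dims)
    for (axis in 1:3) {
      k <- sample(2:5, 1L)
      phase <- stats::runif(1L, 0, 2 * pi)
      s <- smooth_amplitude * sin(2 * pi * k * (seq_len(dims[axis]) - 1L) /
                                    dims[axis] + phase)
      perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
      add <- aperm(array(s, dim = dims[perm]), order(perm))
      field <- field + add
    }
    field
  }
  registration_fixture(
    label_map = label_map, voxel_size = voxel_size,
    rigid = diag(4),
    affine = diag(c(rep(affine_scale, 3), 1)),
    jacobian = jac, atlas = atlas)
}

#' Write / read a registration fixture
#'
#' The label map and Jacobian field are written as NIfTI (`label_map.nii.gz`,
#' `jacobian.nii.gz`, voxel size in the header); the rigid and affine
#' transforms as 4-line plain-text row-major 4x4 matrices (`rigid.txt`,
#' `affine.txt`).
#'
#' @param fixture a [registration_fixture()].
#' @param dir directory to write to / read from.
#' @param atlas region atlas.
#' @return `write_registration_fixture()` returns `dir` invisibly;
#'   `read_registration_fixture()` returns a [registration_fixture()].
#' @export
write_registration_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "registration_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- RNifti::asNifti(fixture$label_map)
  RNifti::pixdim(lab) <- fixture$voxel_size
  RNifti::writeNifti(lab, file.path(dir, "label_map.nii.gz"))
  jac <- RNifti::asNifti(fixture$jacobian)
  RNifti::pixdim(jac) <- fixture$voxel_size
  RNifti::writeNifti(jac, file.path(dir, "jacobian.nii.gz"))
  .write_matrix4(fixture$rigid, file.path(dir, "rigid.txt"))
  .write_matrix4(fixture$affine, file.path(dir, "affine.txt"))
  invisible(dir)
}

#' @rdname write_registration_fixture
#' @export
read_registration_fixture <- function(dir, atlas = load_region_atlas()) {
  lab_img <- RNifti::readNifti(file.path(dir, "label_map.nii.gz"))
  jac_img <- RNifti::readNifti(file.path(dir, "jacobian.nii.gz"))
  voxel_size <- RNifti::pixdim(lab_img)[1:3]
  label_map <- array(as.integer(round(as.array(lab_img))), dim = dim(lab_img))
  registration_fixture(
    label_map = label_map, voxel_size = voxel_size,
    rigid = .read_matrix4(file.path(dir, "rigid.txt")),
    affine = .read_matrix4(file.path(dir, "affine.txt")),
    jacobian = array(as.numeric(jac_img), dim = dim(jac_img)),
    atlas = atlas)
}

.write_matrix4 <- function(m, path) {
  lines <- apply(m, 1L, function(row) paste(sprintf("%.17g", row),
                                            collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

.read_matrix4 <- function(path) {
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (!identical(dim(m), c(4L, 4L))) {
    stop("'", path, "' is not a 4-line 4x4 matrix", call. = FALSE)
  }
  m
}
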