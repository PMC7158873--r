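#' 3-D volume with world-coordinate affine
#'
#' A minimal container for scalar, integer-label and binary volumes: a 3-D
#' array plus a 4x4 affine mapping zero-based voxel indices to world RAS
#' coordinates in millimetres (the NIfTI convention; +X right, +Y anterior,
#' +Z superior). R's one-based array indices are converted internally.
#'
#' @param data a 3-D numeric or logical array.
#' @param affine a 4x4 numeric matrix, last row `(0, 0, 0, 1)`.
#' @return an object of class `vol3d`.
#' @examples
#' v <- vol3d(array(0, c(16, 16, 16)), affine_scale(c(2, 2, 2)))
#' dim(v$data)
#' @export
vol3d <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("`affine` must be a 4x4 matrix with last row (0, 0, 0, 1)")
  structure(list(data = data, affine = affine), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat("<vol3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ",
      paste(signif(voxel_size(x), 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Diagonal scaling affine with centred origin
#'
#' Convenience affine for synthetic grids: voxel axes aligned with world
#' axes, with the grid centre at the world origin when `dim` is given.
#'
#' @param voxel voxel edge lengths in mm (length 1 or 3).
#' @param dim optional grid dimensions; when supplied the translation places
#'   the centre of the grid at world (0, 0, 0).
#' @return a 4x4 affine matrix.
#' @export
affine_scale <- function(voxel, dim = NULL) {
  voxel <- rep_len(voxel, 3L)
  a <- diag(c(voxel, 1))
  if (!is.null(dim)) a[1:3, 4] <- -voxel * (dim - 1) / 2
  a
}

#' @rdname vol3d
#' @param x a `vol3d`.
#' @export
voxel_size <- function(x) {
  a <- if (inherits(x, "vol3d")) x$affine else x
  sqrt(colSums(a[1:3, 1:3]^2))
}

# One-based R voxel indices (n x 3) -> world mm (n x 3).
vox_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(affine[1:3, 1:3] %*% t(ijk - 1) + affine[1:3, 4])
}

# World mm (n x 3) -> continuous one-based R voxel indices (n x 3).
world_to_vox <- function(affine, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  t(solve(affine[1:3, 1:3]) %*% (t(xyz) - affine[1:3, 4])) + 1
}

# World coordinates of every voxel centre, in array order (n_vox x 3).
grid_world <- function(vol) {
  d <- dim(vol$data)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  vox_to_world(vol$affine, ijk)
}

# World-space bounding box of the voxel-centre lattice (2 x 3: min, max).
grid_bbox <- function(vol) {
  d <- dim(vol$data)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  w <- vox_to_world(vol$affine, corners)
  rbind(apply(w, 2, min), apply(w, 2, max))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(what, " must share one grid (dims and affine)")
}

# One-based voxel indices (n x 3) of mask voxels that are TRUE/nonzero.
mask_indices <- function(mask) {
  which(mask$data != 0, arr.ind = TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} preserving the `vol3d` affine as the
#' sform (code 2).
#'
#' @param vol a `vol3d`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `vol3d`; `write_volume` returns `path`
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data * 1)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol3d(as.array(img), structure(RNifti::xform(img), code = NULL))
}
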