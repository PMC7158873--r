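#' Rigid world-coordinate transforms
#'
#' A 4x4 homogeneous matrix combining a proper rotation (orthonormal,
#' determinant +1) with a translation, acting on world mm coordinates.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @return a 4x4 matrix of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("`rotation` must be orthonormal with determinant +1")
  t4 <- diag(4)
  t4[1:3, 1:3] <- rotation
  t4[1:3, 4] <- translation
  structure(t4, class = c("rigid_transform", "matrix", "array"))
}

#' @rdname rigid_transform
#' @param axis rotation axis (3-vector, need not be unit).
#' @param angle rotation angle in radians.
#' @param center point the rotation pivots about (world mm).
#' @export
rotation_about_axis <- function(axis, angle, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rigid_transform(R, as.vector(center - R %*% center))
}

transform_points <- function(t4, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  t(t4[1:3, 1:3] %*% t(pts) + t4[1:3, 4])
}

#' Resample a volume under a rigid transform
#'
#' Resamples `x` into the `reference` grid after moving its content by `t`
#' (`t` maps input world coordinates to output world coordinates). Binary
#' masks use nearest-neighbour interpolation; visitation maps use trilinear.
#'
#' @param x a `vol3d` (mask) or `visitation_map`.
#' @param t a [rigid_transform()].
#' @param reference a `vol3d` defining the output grid (default: `x`).
#' @param interpolation `"auto"` picks NN for plain volumes and trilinear
#'   for visitation maps; override with `"nearest"` or `"trilinear"`.
#' @return a volume of the same class as `x` on the reference grid.
#' @export
apply_transform <- function(x, t, reference = x,
                            interpolation = c("auto", "nearest", "trilinear")) {
  stopifnot(inherits(x, "vol3d"))
  interpolation <- match.arg(interpolation)
  if (interpolation == "auto")
    interpolation <- if (inherits(x, "visitation_map")) "trilinear" else "nearest"
  d <- dim(reference$data)
  out_world <- grid_world(reference)
  src_world <- transform_points(solve(t), out_world)
  src_vox <- world_to_vox(x$affine, src_world)
  sd <- dim(x$data)
  vals <- if (interpolation == "nearest") {
    v <- floor(src_vox + 0.5)
    inside <- v[, 1] >= 1 & v[, 1] <= sd[1] & v[, 2] >= 1 & v[, 2] <= sd[2] &
      v[, 3] >= 1 & v[, 3] <= sd[3]
    out <- numeric(nrow(v))
    out[inside] <- x$data[v[inside, , drop = FALSE]]
    out
  } else {
    trilinear_sample(x$data, src_vox)
  }
  if (any(x$data != 0) && !any(vals != 0))
    stop("transform maps all content outside the reference grid")
  res <- vol3d(array(vals, d), reference$affine)
  class(res) <- class(x)
  res
}

# Trilinear interpolation of a 3-D array at continuous one-based indices;
# zero outside.
trilinear_sample <- function(arr, idx) {
  d <- dim(arr)
  i0 <- floor(idx)
  f <- idx - i0
  out <- numeric(nrow(idx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    inside <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
      ii[, 3] >= 1 & ii[, 3] <= d[3]
    if (any(inside))
      out[inside] <- out[inside] + w[inside] * arr[ii[inside, , drop = FALSE]]
  }
  out
}
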