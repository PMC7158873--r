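#' Principal axis of a binary mask
#'
#' First principal component of the world coordinates of the mask's voxel
#' centres — the main axis along which a thresholded tract map is oriented.
#' The sign is fixed so the axis points from the anterior toward the
#' posterior end of the mask (positive projection on world -Y); if the axis
#' is perpendicular to Y the +X component breaks the tie (then +Z).
#'
#' @param mask a binary `vol3d` with at least 3 voxels.
#' @return a list with `axis` (unit 3-vector) and `centroid` (world mm).
#' @export
principal_axis <- function(mask) {
  idx <- mask_indices(mask)
  if (nrow(idx) < 3L) stop("principal axis needs >= 3 mask voxels")
  w <- vox_to_world(mask$affine, idx)
  centroid <- colMeans(w)
  cv <- stats::cov(w)
  e <- eigen(cv, symmetric = TRUE)
  if (!(e$values[1] > 1e-12))
    stop("degenerate mask: voxel coordinates have no spatial extent")
  v <- e$vectors[, 1]
  tol <- 1e-9
  if (v[2] > tol) v <- -v                    # point posterior (-Y)
  else if (abs(v[2]) <= tol) {
    if (v[1] < -tol) v <- -v                 # tie: +X wins
    else if (abs(v[1]) <= tol && v[3] < 0) v <- -v
  }
  list(axis = v, centroid = centroid)
}

#' Rotate a tract mask (and companions) to the canonical orientation
#'
#' Builds the minimal-angle rotation about the tract centroid that takes the
#' tract's principal axis onto the world anterior-posterior (Y) axis, and
#' applies the identical rigid transform to the tract and every volume in
#' `others`. After rotation, slicing planes perpendicular to Y are coronal
#' with respect to the tract.
#'
#' @param tract a binary `vol3d` tract mask.
#' @param others list of companion volumes (masks or visitation maps) to
#'   co-rotate; they must share the tract's grid.
#' @param reference output grid (default: the tract grid).
#' @return a list with `tract`, `others` (both resampled) and `transform`
#'   (the [rigid_transform()] used).
#' @export
rotate_to_canonical <- function(tract, others = list(), reference = tract) {
  pa <- principal_axis(tract)
  target <- c(0, -1, 0)
  cosang <- sum(pa$axis * target)
  if (cosang > 1 - 1e-12) {
    t4 <- rigid_transform()
  } else if (cosang < -1 + 1e-12) {
    t4 <- rotation_about_axis(c(0, 0, 1), pi, pa$centroid)
  } else {
    axis <- c(pa$axis[2] * target[3] - pa$axis[3] * target[2],
              pa$axis[3] * target[1] - pa$axis[1] * target[3],
              pa$axis[1] * target[2] - pa$axis[2] * target[1])
    t4 <- rotation_about_axis(axis, acos(pmin(pmax(cosang, -1), 1)),
                              pa$centroid)
  }
  list(tract = apply_transform(tract, t4, reference),
       others = lapply(others, apply_transform, t = t4, reference = reference),
       transform = t4)
}

#' Cross-sectional disconnection score
#'
#' Scores how much of a tract a resection transects. On masks already
#' rotated so the tract runs along world Y (see [rotate_to_canonical()]),
#' each coronal slice `s` contributes an overlap count
#' `n_s = |tract & resection in s|`. Two denominator conventions are
#' provided: `"whole_volume"` divides by the total tract volume (the
#' fraction of all tract voxels lost at the worst slice), `"slice"` divides
#' by the tract voxels in that slice (the fraction of the local tract
#' cross-section transected; empty tract slices score 0). The score is the
#' maximum over slices; ties go to the smallest slice index.
#'
#' @param tract,resection binary `vol3d` masks on one grid; `tract`
#'   non-empty. An empty resection is valid and scores 0.
#' @param mode `"whole_volume"` (default) or `"slice"`.
#' @return an object of class `disconnection_result`: a list with `score`,
#'   `argmax_slice`, `mode`, `axis` (the voxel axis sliced over) and
#'   `profile` (a tibble with per-slice counts and fractions).
#' @export
overlap_score <- function(tract, resection, mode = c("whole_volume", "slice")) {
  mode <- match.arg(mode)
  stopifnot_same_grid(tract, resection, "tract and resection")
  tmask <- tract$data != 0
  rmask <- resection$data != 0
  n_tract <- sum(tmask)
  if (n_tract == 0L) stop("tract mask is empty")
  # slice along the voxel axis most aligned with world Y
  ax <- which.max(abs(tract$affine[2, 1:3]))
  d <- dim(tract$data)
  n_slices <- d[ax]
  slice_of <- slice.index(tract$data, ax)
  n_s <- tabulate(slice_of[tmask & rmask], nbins = n_slices)
  t_s <- tabulate(slice_of[tmask], nbins = n_slices)
  frac <- if (mode == "whole_volume") n_s / n_tract
          else ifelse(t_s > 0, n_s / t_s, 0)
  best <- which.max(frac)          # first maximum: smallest slice index
  structure(list(score = frac[best], argmax_slice = best, mode = mode,
                 axis = ax,
                 profile = tibble::tibble(slice = seq_len(n_slices),
                                          overlap = n_s, tract = t_s,
                                          fraction = frac)),
            class = "disconnection_result")
}

#' @export
print.disconnection_result <- function(x, ...) {
  cat("<disconnection_result> score ", signif(x$score, 4), " (",
      x$mode, " denominator) at slice ", x$argmax_slice, "\n", sep = "")
  invisible(x)
}

#' @rdname overlap_score
#' @param result a `disconnection_result`.
#' @param tol score threshold; overlap is called present when
#'   `score > tol` (default 0: any shared voxel counts).
#' @return `classify_overlap`: a logical.
#' @export
classify_overlap <- function(result, tol = 0) {
  stopifnot(inherits(result, "disconnection_result"))
  result$score > tol
}

#' @export
tidy.disconnection_result <- function(x, ...) x$profile

#' @export
glance.disconnection_result <- function(x, ...) {
  tibble::tibble(score = x$score, argmax_slice = x$argmax_slice,
                 mode = x$mode, n_tract = sum(x$profile$tract),
                 n_overlap = sum(x$profile$overlap))
}
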