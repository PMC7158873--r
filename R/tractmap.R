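# Map polyline points to one-based voxel indices on `grid`; rows outside
# the grid are dropped (attr "n_outside" records how many).
points_to_voxels <- function(points, grid) {
  v <- round(world_to_vox(grid$affine, points))
  d <- dim(grid$data)
  inside <- v[, 1] >= 1 & v[, 1] <= d[1] &
            v[, 2] >= 1 & v[, 2] <= d[2] &
            v[, 3] >= 1 & v[, 3] <= d[3]
  structure(v[inside, , drop = FALSE], n_outside = sum(!inside))
}

poly_hits_mask <- function(poly, mask) {
  v <- points_to_voxels(poly, mask)
  if (!nrow(v)) return(FALSE)
  any(mask$data[v] != 0)
}

#' Filter streamlines by inclusion and exclusion regions
#'
#' Keeps exactly the polylines that touch both the seed and the target mask
#' and never touch the exclusion mask. A polyline touches a mask when any of
#' its points, mapped to the mask grid by world-to-voxel rounding, falls in
#' a nonzero voxel.
#'
#' @param s a [streamlines()] set (world mm).
#' @param seed,target non-empty binary `vol3d` masks on one grid.
#' @param exclude optional binary `vol3d` exclusion mask on the same grid.
#' @return the filtered `streamlines` set.
#' @export
filter_streamlines <- function(s, seed, target, exclude = NULL) {
  stopifnot(inherits(s, "streamlines"))
  stopifnot_same_grid(seed, target, "seed/target masks")
  if (!any(seed$data != 0)) stop("seed mask is empty")
  if (!any(target$data != 0)) stop("target mask is empty")
  if (!is.null(exclude)) stopifnot_same_grid(seed, exclude, "seed/exclude masks")
  keep <- vapply(s$polylines, function(p) {
    poly_hits_mask(p, seed) && poly_hits_mask(p, target) &&
      (is.null(exclude) || !poly_hits_mask(p, exclude))
  }, logical(1))
  streamlines(s$polylines[keep], step = s$step)
}

# Linearly resample a polyline so that no segment exceeds `max_step`.
densify_polyline <- function(p, max_step) {
  seg <- sqrt(rowSums(diff(p)^2))
  if (!any(seg > max_step)) return(p)
  tt <- c(0, cumsum(seg))
  n <- ceiling(tt[length(tt)] / max_step)
  ti <- seq(0, tt[length(tt)], length.out = n + 1)
  cbind(approx(tt, p[, 1], ti)$y, approx(tt, p[, 2], ti)$y,
        approx(tt, p[, 3], ti)$y)
}

#' Streamline visitation map
#'
#' Rasterises a streamline set onto a reference grid: per voxel, the
#' fraction of distinct streamlines with at least one point in the voxel.
#' Counting distinct streamlines (not points) keeps the map independent of
#' the tracking step size; polylines are resampled to half the smallest
#' voxel edge beforehand so fast-moving segments cannot skip voxels.
#'
#' @param s a non-empty [streamlines()] set.
#' @param grid a reference `vol3d` defining the output grid.
#' @return a `vol3d` of visitation fractions in `[0, 1]`, with class
#'   `c("visitation_map", "vol3d")`.
#' @export
visitation_map <- function(s, grid) {
  stopifnot(inherits(s, "streamlines"), inherits(grid, "vol3d"))
  if (s$count < 1L) stop("streamline set is empty")
  d <- dim(grid$data)
  counts <- numeric(prod(d))
  max_step <- min(voxel_size(grid)) / 2
  n_out <- 0L
  for (p in s$polylines) {
    v <- points_to_voxels(densify_polyline(p, max_step), grid)
    n_out <- n_out + attr(v, "n_outside")
    if (!nrow(v)) next
    lin <- unique((v[, 3] - 1) * d[1] * d[2] + (v[, 2] - 1) * d[1] + v[, 1])
    counts[lin] <- counts[lin] + 1
  }
  if (n_out > 0)
    warning(n_out, " resampled streamline points fell outside the grid and were ignored")
  out <- vol3d(array(counts / s$count, d), grid$affine)
  class(out) <- c("visitation_map", class(out))
  out
}

#' Threshold a visitation map to a tract mask
#'
#' Voxels whose visitation fraction is at least `q` form the tract mask.
#' With `mode = "total"` (the default) `q` is a fraction of the total
#' streamline count, so `q = 0.05` keeps voxels visited by at least 5% of
#' streamlines; with `mode = "max"` the threshold is `q` times the map
#' maximum.
#'
#' @param v a visitation map (`vol3d`).
#' @param q threshold fraction in (0, 1); default 0.05.
#' @param mode `"total"` or `"max"`.
#' @return a binary `vol3d` mask.
#' @export
threshold_map <- function(v, q = 0.05, mode = c("total", "max")) {
  mode <- match.arg(mode)
  if (!(q > 0 && q < 1)) stop("`q` must lie in (0, 1)")
  cut <- if (mode == "total") q else q * max(v$data)
  m <- (v$data >= cut) * 1
  if (!any(m != 0)) stop("thresholding removed the whole tract")
  vol3d(array(m, dim(v$data)), v$affine)
}

#' Tract-weighted average of a metric map
#'
#' The visitation-weighted mean `sum(w * m) / sum(w)` of a scalar map over
#' the tract, with the visitation fractions as weights — one number per
#' metric per tract, the quantity carried into the group-level model.
#' Voxels with undefined metric values are excluded from both sums and
#' counted in the `n_excluded` attribute. With `weighted = FALSE` an
#' unweighted mean over the positive-visitation support is returned.
#'
#' @param v a visitation map (`vol3d`) with positive mass.
#' @param metric a scalar `vol3d` on the same grid.
#' @param weighted use visitation fractions as weights (default) or not.
#' @return a single numeric value, with attribute `n_excluded`.
#' @export
tract_weighted_average <- function(v, metric, weighted = TRUE) {
  stopifnot_same_grid(v, metric, "map and metric")
  w <- as.vector(v$data)
  m <- as.vector(metric$data)
  if (!weighted) w <- (w > 0) * 1
  ok <- is.finite(m)
  excl <- sum(w > 0 & !ok)
  w <- w * ok
  tw <- sum(w)
  if (!(tw > 0)) stop("total visitation weight is zero")
  structure(sum(w * ifelse(ok, m, 0)) / tw, n_excluded = excl)
}
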