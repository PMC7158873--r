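#' Specification of a tract/resection geometry phantom
#'
#' Describes a tube-like white-matter bundle (a smooth centreline with
#' Gaussian radial jitter), a small label parcellation anchored to its two
#' ends, and an ellipsoidal resection cavity. The default centreline bends
#' anteriorly before sweeping back, emulating the anterior loop of the optic
#' radiation that is most at risk in temporal-lobe surgery.
#'
#' @param grid_shape voxel counts per axis (each >= 16).
#' @param voxel_size voxel edge length(s) in mm.
#' @param tract_centerline control points of the centreline (n x 3, world
#'   mm); a smooth spline is interpolated through them.
#' @param tract_radius bundle radius in mm (> 0).
#' @param n_streamlines number of streamlines to generate (>= 1).
#' @param resection_center,resection_radii centre (world mm) and semi-axes
#'   (mm) of the ellipsoidal resection mask.
#' @param seed integer RNG seed; identical seeds give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 64, 48), voxel_size = 2,
                         tract_centerline = default_centerline(),
                         tract_radius = 6, n_streamlines = 500,
                         resection_center = c(30, 8, 2),
                         resection_radii = c(10, 12, 10),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("`grid_shape` must have 3 entries, each >= 16")
  if (tract_radius <= 0) stop("`tract_radius` must be > 0")
  if (n_streamlines < 1L) stop("`n_streamlines` must be >= 1")
  tract_centerline <- as.matrix(tract_centerline)
  if (ncol(tract_centerline) != 3L || nrow(tract_centerline) < 2L)
    stop("`tract_centerline` must be an n x 3 matrix with n >= 2")
  structure(list(grid_shape = grid_shape,
                 voxel_size = rep_len(voxel_size, 3L),
                 tract_centerline = tract_centerline,
                 tract_radius = tract_radius,
                 n_streamlines = as.integer(n_streamlines),
                 resection_center = resection_center,
                 resection_radii = rep_len(resection_radii, 3L),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_centerline <- function() {
  # LGN-like origin, anterior-lateral loop, then posterior run to occipital
  rbind(c(12, -6, 4),
        c(26, 10, 2),
        c(34, -4, 0),
        c(32, -24, 0),
        c(26, -42, 2))
}

# Dense resampling of the control polygon with a natural cubic spline,
# parameterised by cumulative chord length.
resample_centerline <- function(ctrl, step) {
  d <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  tt <- seq(0, d[length(d)], by = step)
  if (nrow(ctrl) == 2L) {
    out <- cbind(approx(d, ctrl[, 1], tt)$y, approx(d, ctrl[, 2], tt)$y,
                 approx(d, ctrl[, 3], tt)$y)
  } else {
    out <- cbind(splinefun(d, ctrl[, 1], "natural")(tt),
                 splinefun(d, ctrl[, 2], "natural")(tt),
                 splinefun(d, ctrl[, 3], "natural")(tt))
  }
  out
}

# Axis-aligned box of labelled voxels around a world-space centre.
label_box <- function(labels, world, affine, center, half, id) {
  inside <- abs(world[, 1] - center[1]) <= half[1] &
            abs(world[, 2] - center[2]) <= half[2] &
            abs(world[, 3] - center[3]) <= half[3]
  labels[inside] <- id
  labels
}

#' Label ids of the phantom parcellation
#'
#' Mapping from anatomical role to integer label in the phantom's label
#' volume; matches the layout produced by [make_tract_phantom()] and plugs
#' directly into [parcellation_scheme()].
#' @return a `parcellation_scheme`.
#' @export
phantom_scheme <- function() {
  parcellation_scheme(
    thalamus = c(left = 11, right = 1),
    lingual = c(left = 12, right = 2),
    pericalcarine = c(left = 13, right = 3),
    lateral_occipital = c(left = 14, right = 4),
    gray_matter = c(left = 15, right = 5))
}

#' Generate a tract phantom with parcellation and resection mask
#'
#' Builds, on one shared grid and affine: (i) `n_streamlines` polylines
#' jittered around the centreline with per-streamline Gaussian radial
#' offsets (sd = `tract_radius/2`, rejection-truncated at `tract_radius`, so
#' every point lies within `tract_radius` of the centreline); (ii) a label
#' volume with a "thalamus" box at the centreline's first (anterior) end,
#' three occipital boxes (lingual / pericalcarine / lateral-occipital) at
#' its last end and a contralateral grey-matter slab; (iii) the ellipsoidal
#' resection mask.
#'
#' The phantom is laid out in the right hemisphere (x > 0); the
#' contralateral grey matter sits at x < 0.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `streamlines`, `labels` (integer `vol3d`),
#'   `resection` (binary `vol3d`), `centerline` (the resampled curve) and
#'   `affine`.
#' @export
make_tract_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  affine <- affine_scale(spec$voxel_size, spec$grid_shape)
  grid <- vol3d(array(0, spec$grid_shape), affine)
  bbox <- grid_bbox(grid)
  curve <- resample_centerline(spec$tract_centerline, min(spec$voxel_size) / 2)
  margin <- spec$tract_radius
  if (any(sweep(curve, 2, bbox[1, ] + margin) < 0) ||
      any(sweep(curve, 2, bbox[2, ] - margin) > 0))
    stop("tract centerline (plus radius) leaves the grid")

  # unit tangents along the resampled curve
  tang <- rbind(curve[2, ] - curve[1, ], diff(curve, lag = 2) / 2,
                curve[nrow(curve), ] - curve[nrow(curve) - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))

  polys <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_streamlines), function(i) {
      repeat {
        off <- rnorm(3, sd = spec$tract_radius / 2)
        if (sqrt(sum(off^2)) <= spec$tract_radius) break
      }
      # remove the tangential component pointwise: offset stays radial
      proj <- tang %*% off
      curve + matrix(off, nrow(curve), 3, byrow = TRUE) - tang * as.vector(proj)
    })
  })
  s <- streamlines(polys, step = min(spec$voxel_size) / 2)

  world <- grid_world(grid)
  labels <- numeric(nrow(world))
  a_end <- curve[1, ]; p_end <- curve[nrow(curve), ]
  # thalamus box biased anteriorly so the curve's start point falls in the
  # retained (posterior) half of the box
  labels <- label_box(labels, world, affine, a_end + c(0, 4, 0),
                      c(8, 10, 8), 1)
  # three stacked occipital labels at the posterior end
  labels <- label_box(labels, world, affine, p_end + c(0, -4, -6), c(8, 8, 3), 2)
  labels <- label_box(labels, world, affine, p_end + c(0, -4, 0), c(8, 8, 3), 3)
  labels <- label_box(labels, world, affine, p_end + c(0, -4, 6), c(8, 8, 3), 4)
  # contralateral (left, x < 0) grey matter slab
  ctr <- labels == 0 & world[, 1] < -abs(a_end[1]) / 2
  labels[ctr] <- 15
  label_vol <- vol3d(array(labels, spec$grid_shape), affine)

  rr <- pmax(spec$resection_radii, 1e-6)
  u <- sweep(world, 2, spec$resection_center)
  inside <- (u[, 1] / rr[1])^2 + (u[, 2] / rr[2])^2 + (u[, 3] / rr[3])^2 <= 1
  if (!any(inside)) {
    # degenerate radii: fall back to the voxel containing the centre
    cv <- round(world_to_vox(affine, spec$resection_center))
    if (any(cv < 1) || any(cv > spec$grid_shape))
      stop("resection lies entirely outside the grid")
    res <- array(0, spec$grid_shape)
    res[cv[1], cv[2], cv[3]] <- 1
  } else {
    res <- array(as.numeric(inside), spec$grid_shape)
  }

  list(streamlines = s, labels = label_vol,
       resection = vol3d(res, affine), centerline = curve, affine = affine)
}
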