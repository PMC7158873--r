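# Shared builders for small in-code fixtures.

# A straight-tube phantom spec along +Y (start anterior, end posterior).
straight_spec <- function(n_streamlines = 100, seed = 1L, radius = 4,
                          resection_center = c(0, 0, 0),
                          resection_radii = c(6, 6, 6)) {
  phantom_spec(grid_shape = c(24, 40, 24), voxel_size = 2,
               tract_centerline = rbind(c(0, 20, 0), c(0, -20, 0)),
               tract_radius = radius, n_streamlines = n_streamlines,
               resection_center = resection_center,
               resection_radii = resection_radii, seed = seed)
}

# Distance of points to the infinite line through a and b.
dist_to_line <- function(pts, a, b) {
  u <- (b - a) / sqrt(sum((b - a)^2))
  d <- sweep(pts, 2, a)
  proj <- d %*% u
  sqrt(rowSums((d - proj %*% t(u))^2))
}

# A blob mask: ellipsoid at `center` with semi-axes `radii` on `grid`.
ellipsoid_mask <- function(grid, center, radii) {
  w <- ortract:::grid_world(grid)
  u <- sweep(w, 2, center)
  inside <- (u[, 1] / radii[1])^2 + (u[, 2] / radii[2])^2 +
    (u[, 3] / radii[3])^2 <= 1
  vol3d(array(as.numeric(inside), dim(grid$data)), grid$affine)
}

empty_grid <- function(dims = c(24, 24, 24), voxel = 2) {
  vol3d(array(0, dims), affine_scale(voxel, dims))
}

# Brute-force per-slice overlap enumeration: the independent oracle for
# overlap_score, written as explicit set operations per slice.
oracle_overlap <- function(tract, resection, mode, axis = 2) {
  d <- dim(tract$data)
  tv <- which(tract$data != 0)
  rv <- which(resection$data != 0)
  slice_id <- as.vector(slice.index(tract$data, axis))
  prof <- numeric(d[axis])
  for (s in seq_len(d[axis])) {
    in_s <- which(slice_id == s)
    n_s <- length(intersect(intersect(tv, rv), in_s))
    prof[s] <- if (mode == "whole_volume") n_s / length(tv)
               else { ts <- length(intersect(tv, in_s)); if (ts > 0) n_s / ts else 0 }
  }
  list(score = max(prof), slice = which.max(prof), profile = prof)
}

# Null-effect table (fixed effects zeroed, intercept/age/gender kept).
null_effects <- function() {
  eff <- cohort_effect_defaults()
  eff$group <- 0
  eff$timepoint <- 0
  eff
}

# Expected arrow calls implied by an effect table.
expected_pattern <- function(eff) {
  rbind(
    data.frame(metric = eff$metric, effect = "group",
               call = ifelse(eff$group == 0, "none",
                             ifelse(eff$group > 0, "up", "down"))),
    data.frame(metric = eff$metric, effect = "timepoint",
               call = ifelse(eff$timepoint == 0, "none",
                             ifelse(eff$timepoint > 0, "up", "down"))))
}

pattern_matches <- function(pat, expected) {
  m <- merge(as.data.frame(pat[c("metric", "effect", "call")]), expected,
             by = c("metric", "effect"))
  nrow(m) == nrow(expected) && all(m$call.x == m$call.y)
}
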