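test_that("rigid transforms resample as expected", {
  grid <- empty_grid(c(20, 20, 20), voxel = 1)
  blob <- ellipsoid_mask(grid, c(1, -2, 2), c(8, 6, 7))
  # identity: voxelwise identical
  id <- rigid_transform()
  expect_identical(apply_transform(blob, id)$data, blob$data)
  # one-voxel lattice translation preserves the voxel count
  tr <- rigid_transform(translation = c(1, 0, 0))
  shifted <- apply_transform(blob, tr)
  inb <- sum(blob$data[-20, , ])   # voxels not pushed off the grid
  expect_equal(sum(shifted$data), inb)
  expect_equal(shifted$data[10, , ], blob$data[9, , ])
  # rotate forward and back: high Dice with the original
  rot <- rotation_about_axis(c(0, 0, 1), pi / 6, center = c(1, -2, 2))
  back <- rotation_about_axis(c(0, 0, 1), -pi / 6, center = c(1, -2, 2))
  rt <- apply_transform(apply_transform(blob, rot), back)
  dice <- 2 * sum(rt$data * blob$data) / (sum(rt$data) + sum(blob$data))
  expect_gte(dice, 0.95)
  # moving everything off-grid errors
  far <- rigid_transform(translation = c(500, 0, 0))
  expect_error(apply_transform(blob, far), "outside the reference")
  expect_error(rigid_transform(rotation = diag(c(1, 1, -1))), "determinant")
})

test_that("the principal axis matches geometry and an independent covariance oracle", {
  grid <- empty_grid(c(30, 30, 30))
  # straight line of voxels along X: axis = +X by the tie-break
  line <- grid
  line$data[5:25, 15, 15] <- 1
  pa <- principal_axis(line)
  expect_equal(pa$axis, c(1, 0, 0), tolerance = 1e-9)
  # tube at 30 degrees to -Y in the XY plane
  t30 <- c(sin(pi / 6), -cos(pi / 6), 0)
  w <- ortract:::grid_world(grid)
  dl <- dist_to_line(w, c(0, 0, 0), t30 * 10)
  along <- w %*% t30
  tube <- grid
  tube$data[] <- as.numeric(dl <= 4 & abs(along) <= 22)
  pa2 <- principal_axis(tube)
  ang <- acos(abs(sum(pa2$axis * t30)))
  expect_lt(ang * 180 / pi, 2)
  expect_gt(sum(pa2$axis * c(0, -1, 0)), 0)     # oriented posterior
  # L-shaped mask equals the eigenvector of a directly computed covariance
  L <- grid
  L$data[5:25, 15, 15] <- 1
  L$data[25, 15:22, 15] <- 1
  paL <- principal_axis(L)
  idx <- which(L$data != 0, arr.ind = TRUE)
  wl <- ortract:::vox_to_world(L$affine, idx)
  ev <- eigen(cov(wl), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(paL$axis * ev)), 1, tolerance = 1e-9)
  # degenerate inputs
  two <- grid; two$data[1, 1, 1] <- 1; two$data[2, 1, 1] <- 1
  expect_error(principal_axis(two), ">= 3")
})

test_that("canonical rotation aligns the tract axis with anterior-posterior", {
  grid <- empty_grid(c(30, 30, 30))
  w <- ortract:::grid_world(grid)
  # already along Y: identity
  tubeY <- grid
  tubeY$data[] <- as.numeric(sqrt(w[, 1]^2 + w[, 3]^2) <= 4 & abs(w[, 2]) <= 20)
  rotY <- rotate_to_canonical(tubeY)
  expect_equal(unclass(rotY$transform), diag(4), ignore_attr = TRUE,
               tolerance = 1e-9)
  # along X: 90-degree rotation, post-rotation axis within 2 degrees of Y
  tubeX <- grid
  tubeX$data[] <- as.numeric(sqrt(w[, 2]^2 + w[, 3]^2) <= 4 & abs(w[, 1]) <= 20)
  rotX <- rotate_to_canonical(tubeX)
  ang <- acos(pmin(abs(rotX$transform[1:3, 1:3][1, 1]), 1))
  pa <- principal_axis(rotX$tract)
  expect_lt(acos(abs(pa$axis[2])) * 180 / pi, 2)
  # co-rotated companion keeps its overlap with the tract (within resampling)
  blob <- ellipsoid_mask(grid, c(10, 0, 0), c(6, 6, 6))
  both <- rotate_to_canonical(tubeX, list(blob))
  before <- sum(tubeX$data * blob$data)
  after <- sum(both$tract$data * both$others[[1]]$data)
  expect_lt(abs(after - before) / before, 0.05)
})

test_that("overlap scores follow the slice-enumeration definition in both modes", {
  # tract: 10 voxels per coronal slice x 10 slices; resection: 5 voxels in
  # slice 3 and 2 voxels in slice 4
  grid <- empty_grid(c(12, 12, 12), voxel = 1)
  tract <- grid
  for (s in 2:11) tract$data[2:11, s, 6] <- 1      # 10 voxels per slice j
  resection <- grid
  resection$data[2:6, 3, 6] <- 1                   # 5 voxels in slice 3
  resection$data[2:3, 4, 6] <- 1                   # 2 voxels in slice 4
  rw <- overlap_score(tract, resection, mode = "whole_volume")
  expect_equal(rw$score, 5 / 100)
  expect_equal(rw$argmax_slice, 3)
  rs <- overlap_score(tract, resection, mode = "slice")
  expect_equal(rs$score, 5 / 10)
  expect_equal(rs$argmax_slice, 3)
  # disjoint masks: zero score, all-zero profile
  far <- grid; far$data[1, 1, 1] <- 1
  r0 <- overlap_score(tract, far)
  expect_equal(r0$score, 0)
  expect_true(all(r0$profile$fraction == 0))
  expect_false(classify_overlap(r0))
  # resection covering the tract: slice mode scores 1
  all_r <- grid; all_r$data[] <- 1
  expect_equal(overlap_score(tract, all_r, mode = "slice")$score, 1)
  expect_error(overlap_score(grid, resection), "tract mask is empty")
})

test_that("growing the resection never decreases the score", {
  set.seed(5)
  grid <- empty_grid(c(24, 24, 24), voxel = 1)
  tract <- ellipsoid_mask(grid, c(0, 0, 0), c(4, 10, 4))
  small <- ellipsoid_mask(grid, c(2, 3, 0), c(3, 3, 3))
  big <- ellipsoid_mask(grid, c(2, 3, 0), c(5, 6, 5))
  for (m in c("whole_volume", "slice")) {
    expect_gte(overlap_score(tract, big, mode = m)$score,
               overlap_score(tract, small, mode = m)$score)
  }
  # whole-volume score is bounded by the global overlap fraction
  r <- overlap_score(tract, small)
  expect_lte(r$score, sum(tract$data * small$data) / sum(tract$data))
})

test_that("classify_overlap applies its threshold to grazing contact", {
  grid <- empty_grid(c(16, 16, 16), voxel = 1)
  tract <- ellipsoid_mask(grid, c(0, 0, 0), c(3, 6, 3))
  graze <- grid
  edge <- which(tract$data != 0, arr.ind = TRUE)
  pick <- edge[which.max(edge[, 1]), ]
  graze$data[pick[1], pick[2], pick[3]] <- 1
  r <- overlap_score(tract, graze)
  expect_true(classify_overlap(r))
  expect_true(any(tract$data != 0 & graze$data != 0))  # membership oracle
  expect_false(classify_overlap(r, tol = 0.5))
})
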