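test_that("phantom streamlines stay within the tract radius of a straight centreline", {
  spec <- straight_spec(n_streamlines = 100, seed = 1)
  ph <- make_tract_phantom(spec)
  expect_equal(ph$streamlines$count, 100)
  for (p in ph$streamlines$polylines) {
    d <- dist_to_line(p, c(0, 20, 0), c(0, -20, 0))
    expect_true(all(d <= spec$tract_radius + 1e-9))
  }
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- make_tract_phantom(straight_spec(seed = 42))
  b <- make_tract_phantom(straight_spec(seed = 42))
  expect_identical(a$streamlines$polylines, b$streamlines$polylines)
  expect_identical(a$labels$data, b$labels$data)
  c_ <- make_tract_phantom(straight_spec(seed = 43))
  expect_false(identical(a$streamlines$polylines, c_$streamlines$polylines))
})

test_that("streamline points stay inside the grid bounding box", {
  ph <- make_tract_phantom(phantom_spec(seed = 5))
  bbox <- ortract:::grid_bbox(ph$labels)
  for (p in ph$streamlines$polylines) {
    expect_true(all(sweep(p, 2, bbox[1, ]) >= 0))
    expect_true(all(sweep(p, 2, bbox[2, ]) <= 0))
  }
})

test_that("out-of-grid phantom geometry errors", {
  expect_error(make_tract_phantom(
    phantom_spec(grid_shape = c(16, 16, 16), voxel_size = 2,
                 tract_centerline = rbind(c(0, 0, 0), c(0, 200, 0)))),
    "leaves the grid")
  expect_error(make_tract_phantom(
    straight_spec(resection_center = c(500, 500, 500),
                  resection_radii = c(1e-7, 1e-7, 1e-7))),
    "outside the grid")
})

test_that("a degenerate single-voxel resection inside the tract still scores overlap", {
  spec <- straight_spec(resection_center = c(0, 0, 0),
                        resection_radii = c(1e-7, 1e-7, 1e-7))
  ph <- make_tract_phantom(spec)
  expect_equal(sum(ph$resection$data), 1)
  vm <- visitation_map(ph$streamlines, ph$labels)
  tm <- threshold_map(vm, 0.05)
  res <- overlap_score(tm, ph$resection)
  expect_gt(res$score, 0)
  expect_true(classify_overlap(res))
  # oracle: the resection voxel is a tract voxel
  expect_true(any(tm$data != 0 & ph$resection$data != 0))
})

test_that("isotropic diffusion gives the orientation-free exponential signal", {
  p <- default_protocol()
  s <- simulate_multishell_signal(
    signal_sim_spec(p, lambda_par = 1e-3, lambda_perp = 1e-3,
                    dispersion_kappa = 3), 1)
  sig <- ortract:::sv_matrix(s)[1, ]
  expect_equal(sig[p$bvals <= 50], rep(1, sum(p$bvals <= 50)))
  expect_equal(sig[p$bvals == 1000], rep(exp(-1), 60), tolerance = 1e-9)
  expect_equal(sig[p$bvals == 2200], rep(exp(-2.2), 60), tolerance = 1e-9)
})

test_that("per-shell spherical means are invariant to orientation dispersion", {
  p <- default_protocol()
  ms <- sapply(c(0.5, 1, 5, 50), function(k) {
    s <- simulate_multishell_signal(signal_sim_spec(p, dispersion_kappa = k), 1)
    shell_spherical_mean(s, p)$means[1, ]
  })
  # variation across kappa below 0.5% of the mean, per shell
  for (sh in 1:2)
    expect_lt(diff(range(ms[sh, ])) / mean(ms[sh, ]), 0.005)
  # and each agrees with the closed-form prediction
  pred <- smt_mean_model(1.7e-3, 0.3e-3, c(1000, 2200))
  expect_equal(as.vector(ms[, 2]), pred, tolerance = 1e-3)
})

test_that("Rician noise matches its analytic mean at snr 30", {
  p <- default_protocol()
  s <- simulate_multishell_signal(signal_sim_spec(p, snr = 30, seed = 3),
                                  12000)
  b0 <- ortract:::sv_matrix(s)[, which(p$bvals <= 50)[1]]
  expect_equal(mean(b0), rician_mean(1, 1 / 30), tolerance = 0.01)
})

test_that("signal simulation validates its inputs", {
  p <- default_protocol()
  expect_error(signal_sim_spec(p, lambda_par = 1e-3, lambda_perp = 2e-3),
               "lambda_perp <= lambda_par")
  expect_error(signal_sim_spec(p, snr = 0), "positive")
  bad <- p
  bad$bvecs[20, ] <- c(2, 0, 0)
  expect_error(diffusion_protocol(bad$bvals, bad$bvecs), "unit vectors")
})

test_that("cohort table reduces to the fixed effects when noise is zero", {
  eff <- cohort_effect_defaults()
  eff$age <- 0
  eff$gender <- 0
  spec <- cohort_sim_spec(4, 4, effects = eff, subject_sd = 0,
                          hemisphere_sd = 0, residual_sd = 0, seed = 2)
  tab <- simulate_cohort_table(spec)
  # patients x 2 timepoints x 2 hemis x 9 metrics + controls x 1 x 2 x 9
  expect_equal(nrow(tab), 4 * 2 * 2 * 9 + 4 * 1 * 2 * 9)
  md <- tab[tab$metric == "MD", ]
  base_c <- md$value[md$group == "control"]
  expect_equal(base_c, rep(eff$intercept[eff$metric == "MD"], length(base_c)))
  base_p <- md$value[md$group == "patient" & md$timepoint == "baseline"]
  expect_equal(base_p,
               rep(eff$intercept[eff$metric == "MD"] +
                     eff$group[eff$metric == "MD"], length(base_p)))
  post_p <- md$value[md$group == "patient" & md$timepoint == "after_surgery"]
  expect_equal(post_p, base_p + eff$timepoint[eff$metric == "MD"])
})

test_that("cohort simulation is deterministic in the seed and encodes hemispheres by group", {
  a <- simulate_cohort_table(cohort_sim_spec(5, 5, seed = 9))
  b <- simulate_cohort_table(cohort_sim_spec(5, 5, seed = 9))
  expect_identical(a, b)
  expect_setequal(unique(a$hemisphere[a$group == "patient"]),
                  c("ipsi", "contra"))
  expect_setequal(unique(a$hemisphere[a$group == "control"]),
                  c("left", "right"))
  expect_false(any(a$timepoint[a$group == "control"] == "after_surgery"))
})

test_that("the packaged clinical fixture is intact", {
  fx <- clinical_fixture()
  expect_equal(nrow(fx$patients), 43)
  expect_equal(
    fx$patients$surgery[fx$patients$patient == "Patient13"],
    "L temporal lobectomy and amygdalo-hippocampectomy (extended)")
  expect_equal(
    fx$patients$seizure_freedom[fx$patients$patient == "Patient37"],
    "Unavailable")
  expect_equal(nrow(fx$concordance), 12)
  expect_setequal(
    fx$concordance$patient[fx$concordance$overlap == "yes"],
    paste0("Patient", c("04", "13", "15", "18", "39", "42", "43")))
})
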