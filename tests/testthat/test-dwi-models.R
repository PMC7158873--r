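single_tensor_signal <- function(protocol, evals, R = diag(3)) {
  D <- R %*% diag(evals) %*% t(R)
  exp(-protocol$bvals * rowSums((protocol$bvecs %*% D) * protocol$bvecs))
}

test_that("the tensor fit reproduces analytic tensors on noise-free signals", {
  p <- default_protocol()
  # isotropic
  s_iso <- single_tensor_signal(p, rep(1e-3, 3))
  f <- fit_dti(signal_volume(matrix(s_iso, 1)), p)
  expect_equal(f$FA, 0, tolerance = 1e-10)
  expect_equal(f$MD, 1e-3, tolerance = 1e-10)
  # axisymmetric along +Y: closed-form FA
  Ry <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))  # eigvec order x,z,y
  s <- single_tensor_signal(p, c(0.3e-3, 0.3e-3, 1.7e-3),
                            diag(3)[, c(1, 3, 2)])
  f <- fit_dti(signal_volume(matrix(s, 1)), p)
  l <- c(1.7e-3, 0.3e-3, 0.3e-3)
  md <- mean(l)
  fa_ref <- sqrt(1.5 * sum((l - md)^2) / sum(l^2))
  expect_equal(f$AD, 1.7e-3, tolerance = 1e-10 * 1.7e-3)
  expect_equal(f$RD, 0.3e-3, tolerance = 1e-10 * 0.3e-3)
  expect_equal(f$MD, md, tolerance = 1e-10 * md)
  expect_equal(f$FA, fa_ref, tolerance = 1e-10)
  expect_equal(abs(f$V1[1, 2]), 1, tolerance = 1e-6)
  # rotated oblique tensor: eigenvalues recovered to machine accuracy
  ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(0.7) * K + (1 - cos(0.7)) * K %*% K
  s <- single_tensor_signal(p, c(1.7e-3, 0.5e-3, 0.2e-3), R)
  f <- fit_dti(signal_volume(matrix(s, 1)), p)
  expect_equal(c(f$L1, f$L2, f$L3), c(1.7e-3, 0.5e-3, 0.2e-3),
               tolerance = 1e-10)
})

test_that("tensor fitting rejects unusable protocols and signals", {
  b0_only <- diffusion_protocol(rep(0, 10), matrix(0, 10, 3))
  expect_error(fit_dti(signal_volume(matrix(1, 1, 10)), b0_only),
               ">= 6 unique")
  p <- default_protocol()
  s <- single_tensor_signal(p, rep(1e-3, 3))
  s[5] <- -1
  f <- fit_dti(signal_volume(matrix(s, 1)), p)
  expect_true(f$excluded[1])
  expect_true(is.na(f$FA[1]))
})

test_that("spherical means follow the defining arithmetic", {
  # constant DW signal 0.5 across both shells, b0s at (1.0, 1.2)
  bv <- c(0, 0, rep(1000, 20), rep(2200, 20))
  g <- rbind(matrix(0, 2, 3), fibonacci_sphere(20), fibonacci_sphere(20))
  p <- diffusion_protocol(bv, g)
  sig <- c(1.0, 1.2, rep(0.55, 40))
  sm <- shell_spherical_mean(signal_volume(matrix(sig, 1)), p)
  expect_equal(as.vector(sm$means), rep(0.55 / 1.1, 2))
  # too few directions per shell is an error
  bv2 <- c(0, rep(1000, 10), rep(2200, 10))
  p2 <- diffusion_protocol(bv2, rbind(matrix(0, 1, 3), fibonacci_sphere(10),
                                      fibonacci_sphere(10)))
  expect_error(shell_spherical_mean(signal_volume(matrix(1, 1, 21)), p2),
               ">= 15 directions")
})

test_that("the spherical-mean closed form matches its limits and oracle value", {
  expect_equal(smt_mean_model(1.7e-3, 0.3e-3, 0), 1)
  expect_equal(smt_mean_model(1e-3, 1e-3, 1000), exp(-1), tolerance = 1e-12)
  # independently evaluated: exp(-b*lp)*sqrt(pi)*erf(sqrt(b*dl))/(2*sqrt(b*dl))
  expect_equal(smt_mean_model(1.7e-3, 0.3e-3, 1000), 0.502567107424739,
               tolerance = 1e-12)
  expect_equal(smt_mean_model(1.7e-3, 0.3e-3, 2200), 0.257586348042453,
               tolerance = 1e-12)
  # continuity across the small-d series switch
  d_lo <- smt_mean_model(1e-3 + 9e-13, 1e-3, 1000)
  d_hi <- smt_mean_model(1e-3 + 1.1e-12, 1e-3, 1000)
  expect_equal(d_lo, d_hi, tolerance = 1e-9)
  expect_error(smt_mean_model(1e-3, 2e-3, 1000), "exceed")
})

test_that("the SMT fit recovers ground-truth diffusivities independent of dispersion", {
  p <- default_protocol()
  for (k in c(1, 50)) {
    s <- simulate_multishell_signal(signal_sim_spec(p, dispersion_kappa = k), 1)
    f <- fit_smt(s, p)
    expect_lt(abs(f$Long[1] - 1.7e-3) / 1.7e-3, 0.02)
    expect_lt(abs(f$Trans[1] - 0.3e-3) / 0.3e-3, 0.02)
    expect_equal(f$muMD[1], (f$Long[1] + 2 * f$Trans[1]) / 3)
  }
  # isotropic voxel: muFA ~ 0
  si <- simulate_multishell_signal(
    signal_sim_spec(p, lambda_par = 1e-3, lambda_perp = 1e-3), 1)
  fi <- fit_smt(si, p)
  expect_lt(fi$muFA[1], 0.02)
  # single shell is rejected
  bv <- c(0, rep(1000, 30))
  p1 <- diffusion_protocol(bv, rbind(c(0, 0, 0), fibonacci_sphere(30)))
  expect_error(fit_smt(signal_volume(matrix(1, 1, 31)), p1), ">= 2 distinct")
})

test_that("muFA attains its limiting values", {
  # Trans = 0 => muFA = 1; Long = Trans => muFA = 0 (via the formula)
  long <- 2e-3; trans <- 0
  expect_equal(abs(long - trans) / sqrt(long^2 + 2 * trans^2), 1)
  long <- 1.5e-3; trans <- 1.5e-3
  expect_equal(abs(long - trans) / sqrt(long^2 + 2 * trans^2), 0)
})

test_that("orientation dispersion entropy behaves like a coherence measure", {
  p <- default_protocol()
  # uniform orientations: entropy of the uniform density, ODEntropy ~ 0
  s0 <- simulate_multishell_signal(signal_sim_spec(p, dispersion_kappa = 0), 1)
  f0 <- fit_smt(s0, p)
  expect_lt(od_entropy(s0, p, f0)$ODEntropy[1], 0.01)
  # crossing fibres are less coherent than a single bundle at equal kappa
  sx <- simulate_multishell_signal(
    signal_sim_spec(p, dispersion_kappa = 20,
                    mu = rbind(c(0, 0, 1), c(1, 0, 0))), 1)
  fx <- fit_smt(sx, p)
  s1 <- simulate_multishell_signal(signal_sim_spec(p, dispersion_kappa = 20), 1)
  f1 <- fit_smt(s1, p)
  expect_lt(od_entropy(sx, p, fx)$ODEntropy[1],
            od_entropy(s1, p, f1)$ODEntropy[1])
  # near-isotropic kernel: flagged, entropy 0
  si <- simulate_multishell_signal(
    signal_sim_spec(p, lambda_par = 1e-3, lambda_perp = 1e-3), 1)
  fi <- fit_smt(si, p)
  oi <- od_entropy(si, p, fi)
  expect_true(oi$flagged[1])
  expect_equal(oi$ODEntropy[1], 0)
})
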