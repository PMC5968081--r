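# Synthetic phantom: Rician noise, geometry, and forward simulation.

test_that("Rician noise has the analytic second moment and high-SNR mean", {
  x <- array(runif(100, 10, 20), c(10, 10, 1))
  expect_identical(add_rician_noise(x, 0), x)
  expect_error(add_rician_noise(x, -1), "sigma")
  # E[m^2] = v^2 + 2 sigma^2 (exact second moment of the Rice distribution)
  v <- 5; sigma <- 2
  noisy <- add_rician_noise(rep(v, 1e6), sigma, rng_seed = 99L)
  expect_equal(mean(noisy^2), v^2 + 2 * sigma^2, tolerance = 0.01)
  # v/sigma = 10: Gaussian limit, mean within 1%
  noisy <- add_rician_noise(rep(10, 1e5), 1, rng_seed = 100L)
  expect_equal(mean(noisy), 10, tolerance = 0.01)
})

test_that("the phantom partitions the tissue, carries 22 labels, and is reproducible", {
  spec <- phantom_spec(rng_seed = 3L)
  truth <- build_phantom(spec)
  expect_setequal(setdiff(unique(as.vector(truth$labels$labels)), 0L), 1:22)
  # labels partition the tissue mask; background is 0 outside
  expect_identical(truth$labels$labels > 0, truth$tissue)
  expect_true(all(truth$labels$labels[!truth$tissue] == 0L))
  # free-water rim
  expect_true(all(truth$f_iso[truth$rim] == 1))
  # crossing block carries two populations with weights summing to 1
  expect_gt(sum(truth$crossing), 0)
  expect_true(all(truth$w1[truth$crossing] == 0.5))
  expect_true(all(is.finite(truth$mu2[which(truth$crossing)])))
  # determinism
  truth2 <- build_phantom(phantom_spec(rng_seed = 3L))
  expect_identical(truth$labels$labels, truth2$labels$labels)
  expect_identical(truth$f_ic_star, truth2$f_ic_star)
  expect_error(build_phantom(phantom_spec(grid = volume_grid(c(4, 4, 4)))), "small")
})

test_that("a positive slope makes anterior grey matter denser than posterior", {
  truth <- build_phantom(phantom_spec(gradient_slope = 0.01))
  leg <- hippocampus_legend()
  white <- leg$label[leg$structure %in% c("Alveus", "Fimbria")]
  grey <- truth$tissue &
    !array(truth$labels$labels %in% white, dim(truth$tissue)) & !truth$crossing
  nz <- dim(grey)[3]
  ant <- grey; ant[, , (nz %/% 3 + 1):nz] <- FALSE
  post <- grey; post[, , 1:(2 * nz %/% 3)] <- FALSE
  expect_gt(mean(truth$f_ic_star[ant]), mean(truth$f_ic_star[post]))
  # white matter runs the other way
  wm <- truth$tissue & array(truth$labels$labels %in% white, dim(truth$tissue))
  ant_w <- wm; ant_w[, , (nz %/% 3 + 1):nz] <- FALSE
  post_w <- wm; post_w[, , 1:(2 * nz %/% 3)] <- FALSE
  expect_lt(mean(truth$f_ic_star[ant_w]), mean(truth$f_ic_star[post_w]))
})

test_that("the noiseless forward simulation honours the closed forms", {
  spec <- phantom_spec(grid = volume_grid(c(12, 12, 18)), rng_seed = 1L)
  truth <- build_phantom(spec)
  sch <- hydi_scheme(n_dir = 12, n_b0 = 2)
  dwi <- simulate_dwi(truth, sch, snr_per_shell = NULL, use_t2 = FALSE)
  # b = 0 returns exactly S0
  b0 <- which(sch$b == 0)
  for (j in b0) {
    expect_equal(dwi$signal[, , , j][truth$mask], truth$s0[truth$mask],
                 tolerance = 1e-12)
  }
  # attenuations within [0, 1]
  att <- sweep(matrix(dwi$signal, ncol = length(sch))[which(truth$mask), ], 1,
               truth$s0[truth$mask], "/")
  expect_true(all(att <= 1 + 1e-12 & att >= 0))
  # free-water rim voxel at b = 4500: e^-9
  rimv <- which(truth$rim)[1]
  j <- which(sch$b == 4500)[1]
  expect_equal(dwi$signal[, , , j][rimv] / truth$s0[rimv], exp(-9), tolerance = 1e-9)
  # TE weighting multiplies by exp(-TE/T2)
  dwt <- simulate_dwi(truth, sch, snr_per_shell = NULL, use_t2 = TRUE)
  expect_equal(dwt$signal[, , , b0[1]][truth$mask],
               (truth$s0 * exp(-sch$TE[b0[1]] / truth$t2))[truth$mask],
               tolerance = 1e-12)
  # same seed, same noise
  n1 <- simulate_dwi(truth, sch, snr_per_shell = c(9.9, 7.6, 4.2), rng_seed = 5L)
  n2 <- simulate_dwi(truth, sch, snr_per_shell = c(9.9, 7.6, 4.2), rng_seed = 5L)
  expect_identical(n1$signal, n2$signal)
  expect_error(simulate_dwi(truth, sch, snr_per_shell = c(9.9, 7.6)), "SNR")
})

test_that("stationary and stick compartments behave as the model states", {
  sch <- hydi_scheme(n_dir = 30, n_b0 = 2)
  # all-stationary voxel: no attenuation at any b
  p_stat <- noddi_params(0, 1, 0.5, odi = 0.3)
  expect_equal(noddi_forward(p_stat, sch), rep(1, length(sch)))
  # near-coherent stick (kappa -> inf): parallel vs perpendicular closed form
  dirs <- rbind(c(0, 0, 1), c(1, 0, 0))
  schs <- gradient_scheme(c(0, 4500, 4500), rbind(c(0, 0, 0), dirs),
                          14.4, 4.3, 24.2)
  p_stick <- noddi_params(0, 0, 1, kappa = 1e6, mu = c(0, 0, 1))
  A <- noddi_forward(p_stick, schs)
  expect_equal(A[2], exp(-4500 * D_PAR_EXVIVO), tolerance = 2e-3)
  expect_equal(A[3], 1, tolerance = 2e-3)
})

test_that("MSME simulation round-trips through the T2 fit", {
  g <- volume_grid(c(4, 4, 2))
  t2 <- array(runif(32, 30, 90), c(4, 4, 2))
  s0 <- array(800, c(4, 4, 2))
  series <- simulate_msme(t2, s0, g, snr = 0)
  expect_equal(series$echo_times, seq(6.4, 76.8, length.out = 12))
  fit <- fit_t2_map(series)
  expect_equal(fit$t2, t2, tolerance = 1e-3)
  expect_error(simulate_msme(array(-1, c(4, 4, 2)), s0, g,
                             mask = array(TRUE, c(4, 4, 2))), "nonpositive")
})
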