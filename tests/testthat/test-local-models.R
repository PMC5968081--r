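# DTI fitting, tensor metrics, analytical Q-ball, and peak extraction.

test_that("noiseless tensor is recovered essentially exactly", {
  g <- volume_grid(c(1, 1, 1))
  sch <- single_shell_scheme()
  D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
  att <- exp(-sch$b * rowSums((sch$directions %*% D) * sch$directions))
  dwi <- uniform_dwi(g, sch, att)
  f <- fit_dti(dwi)
  expect_true(f$valid[1, 1, 1])
  expect_equal(f$tensors[1, 1, 1, ], c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0),
               tolerance = 1e-9)
  m <- tensor_metrics(f)
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  fa_true <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(m$md[1, 1, 1], mean(lam), tolerance = 1e-9)
  expect_equal(m$fa[1, 1, 1], fa_true, tolerance = 1e-9)
  # CED: principal axis x -> red channel = FA
  expect_equal(m$ced[1, 1, 1, ], c(fa_true, 0, 0), tolerance = 1e-6)
})

test_that("isotropic signal gives FA 0 and degenerate inputs error", {
  g <- volume_grid(c(1, 1, 1))
  sch <- single_shell_scheme(n_dir = 15)
  dwi <- uniform_dwi(g, sch, exp(-sch$b * 0.16e-3))
  m <- tensor_metrics(fit_dti(dwi))
  expect_lt(m$fa[1, 1, 1], 1e-6)
  expect_equal(m$md[1, 1, 1], 0.16e-3, tolerance = 1e-9)
  b0_only <- gradient_scheme(c(0, 0), matrix(0, 2, 3), 14.4, 4.3, 24.2)
  dwi0 <- uniform_dwi(g, b0_only, c(1, 1))
  expect_error(fit_dti(dwi0), "diffusion-weighted|directions")
})

test_that("tensor metric edge cases match hand values", {
  lam <- rbind(c(1, 1, 1), c(1, 0, 0))
  fa <- hdmri:::fa_from_evals(lam)
  expect_equal(fa[1], 0)
  expect_equal(fa[2], 1, tolerance = 1e-12)
})

test_that("aQBI of an isotropic signal is (numerically) a constant ODF", {
  g <- volume_grid(c(1, 1, 1))
  sch <- single_shell_scheme()
  dwi <- uniform_dwi(g, sch, exp(-sch$b * 0.16e-3))
  f <- fit_aqbi(dwi)
  cs <- f$coefficients[1, 1, 1, ]
  expect_equal(cs[1], 1 / sqrt(4 * pi), tolerance = 1e-9)
  expect_lt(max(abs(cs[-1])) / cs[1], 1e-8)
  # constant ODF has no strict local maximum: 0 peaks by decision
  pk <- extract_peaks(f)
  expect_identical(pk$n_peaks[1, 1, 1], 0L)
})

test_that("single-stick ODF peaks align with the stick axis", {
  g <- volume_grid(c(1, 1, 1))
  sch <- single_shell_scheme()
  u <- c(0, 0, 1)
  dwi <- uniform_dwi(g, sch, stick_attenuation(sch, u, d = 1.6e-4))
  pk <- extract_peaks(fit_aqbi(dwi))
  expect_identical(pk$n_peaks[1, 1, 1], 1L)
  ang <- acos(min(1, abs(sum(pk$directions[1, 1, 1, 1, ] * u)))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("90-degree crossings resolve into exactly two peaks; DTI cannot", {
  g <- volume_grid(c(1, 1, 1))
  sch <- single_shell_scheme()
  u1 <- c(0, 0, 1); u2 <- c(1, 0, 0)
  dwi <- uniform_dwi(g, sch, stick_attenuation(sch, u1, u2 = u2, w1 = 0.5))
  pk <- extract_peaks(fit_aqbi(dwi))
  expect_identical(pk$n_peaks[1, 1, 1], 2L)
  for (i in 1:2) {
    d <- pk$directions[1, 1, 1, i, ]
    err <- min(acos(min(1, abs(sum(d * u1)))), acos(min(1, abs(sum(d * u2))))) * 180 / pi
    expect_lt(err, 10)
  }
  # the tensor fit of the same voxel is planar: two comparable eigenvalues
  fd <- fit_dti(dwi)
  ev <- fd$evals[1, 1, 1, ]
  expect_lt((ev[1] - ev[2]) / ev[1], 0.2)
})

test_that("amplitude-ratio threshold semantics keep only dominant lobes", {
  g <- volume_grid(c(1, 1, 1))
  sch <- single_shell_scheme()
  # 0.85/0.15 mixture: secondary ODF lobe falls below half the primary
  dwi <- uniform_dwi(g, sch, stick_attenuation(sch, c(0, 0, 1),
                                               u2 = c(1, 0, 0), w1 = 0.85))
  f <- fit_aqbi(dwi)
  pk_all <- extract_peaks(f, relative_threshold = 0)
  pk_half <- extract_peaks(f, relative_threshold = 0.5)
  expect_gte(pk_all$n_peaks[1, 1, 1], 2L)
  a <- pk_all$amplitudes[1, 1, 1, 1:2]
  expect_lt(a[2] / a[1], 0.5)   # the secondary lobe sits below the cutoff
  expect_identical(pk_half$n_peaks[1, 1, 1], 1L)
})

test_that("lambda = 0 SH fit reproduces bandlimited signals exactly", {
  set.seed(8)
  dirs <- uniform_directions(60)
  cs_true <- rnorm(sh_n_coef(8), sd = 0.2)
  sig <- as.vector(sh_basis(dirs, 8) %*% cs_true)
  cs_fit <- sh_fit_signal(sig, dirs, order = 8, lambda_reg = 0)
  expect_equal(cs_fit, cs_true, tolerance = 1e-9)
})

test_that("aQBI peak geometry is rotation-equivariant", {
  g <- volume_grid(c(1, 1, 1))
  base_dirs <- uniform_directions(60)
  set.seed(21)
  for (k in 1:10) {
    # random rotation from a QR decomposition
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    u <- as.vector(R %*% c(0, 0, 1))
    dirs_r <- base_dirs %*% t(R)
    sch_r <- gradient_scheme(c(0, rep(4500, 60)), rbind(c(0, 0, 0), dirs_r),
                             14.4, 4.3, 24.2)
    dwi <- uniform_dwi(g, sch_r, stick_attenuation(sch_r, u))
    pk <- extract_peaks(fit_aqbi(dwi))
    expect_identical(pk$n_peaks[1, 1, 1], 1L)
    ang <- acos(min(1, abs(sum(pk$directions[1, 1, 1, 1, ] * u)))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("the tessellation is antipodal with the promised resolution", {
  sph <- sphere_tessellation(4L)
  expect_gte(sum(sph$hemi), 724L)
  expect_equal(sqrt(rowSums(sph$vertices^2)), rep(1, nrow(sph$vertices)),
               tolerance = 1e-12)
  expect_equal(sph$vertices[sph$antipode, ], -sph$vertices, tolerance = 1e-12)
})
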