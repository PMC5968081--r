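# Four-compartment ex vivo NODDI: forward model, fraction algebra, fitting,
# and region statistics.

test_that("forward model closed forms hold", {
  sch <- hydi_scheme(n_dir = 20, n_b0 = 2)
  # b = 0 -> A = 1 for any parameters
  p <- noddi_params(0.3, 0.2, 0.6, odi = 0.4, mu = c(1, 0, 0))
  A <- noddi_forward(p, sch)
  expect_true(all(A[sch$b == 0] == 1))
  expect_true(all(A >= 0 & A <= 1))
  # pure free water at b = 4500: e^-9
  p_iso <- noddi_params(1, 0, 0, odi = 0.5)
  expect_equal(noddi_forward(p_iso, sch)[which(sch$b == 4500)[1]], exp(-9),
               tolerance = 1e-12)
  # pure stationary water: A = 1 at every b
  p_stat <- noddi_params(0, 1, 0, odi = 0.5)
  expect_equal(noddi_forward(p_stat, sch), rep(1, length(sch)))
})

test_that("Watson stick limits: coherent stick and uniform dispersion", {
  bd <- 4500 * D_PAR_EXVIVO
  # kappa = 1000 is within 1e-3 of the single-stick closed form
  ca <- c(1, 0.5, 0)
  stick <- exp(-bd * ca^2)
  expect_equal(watson_stick_attenuation(bd, ca, 1e3), stick, tolerance = 1e-3)
  # kappa = 0: direction-independent
  a0 <- watson_stick_attenuation(rep(bd, 3), ca, 0)
  expect_lt(diff(range(a0)), 1e-6)
  # kappa = 64 (ODI ~ 0.01), g parallel to mu: within 2% of e^-0.72
  a64 <- watson_stick_attenuation(0.72, 1, 64)
  expect_equal(a64, exp(-0.72), tolerance = 0.02)
})

test_that("Watson quadrature matches a Monte-Carlo oracle", {
  # Watson(kappa = 4) sampled by rejection; stick at 60 degrees from mu
  set.seed(2)
  n <- 4e5
  t <- runif(n, -1, 1)
  t <- t[runif(n) < exp(4 * (t^2 - 1))]
  phi <- runif(length(t), 0, 2 * pi)
  u <- cbind(sqrt(1 - t^2) * cos(phi), sqrt(1 - t^2) * sin(phi), t)
  g <- c(sin(pi / 3), 0, cos(pi / 3))
  mc <- mean(exp(-0.72 * (u %*% g)^2))
  qd <- watson_stick_attenuation(0.72, cos(pi / 3), 4)
  expect_equal(qd, mc, tolerance = 0.005)
  expect_equal(watson_tau1(4), mean(t^2), tolerance = 0.005)
  expect_equal(watson_tau1(0), 1 / 3, tolerance = 1e-9)
})

test_that("attenuation is non-increasing in b at fixed direction", {
  bs <- seq(0, 12000, by = 1000)
  sch <- gradient_scheme(c(0, bs[-1]), rbind(c(0, 0, 0),
                                             matrix(rep(c(0, 0, 1), length(bs) - 1),
                                                    ncol = 3, byrow = TRUE)),
                         45, 4.3, 54.8)
  for (odi in c(0.05, 0.3, 0.8)) {
    p <- noddi_params(0.1, 0.1, 0.5, odi = odi)
    A <- noddi_forward(p, sch)
    expect_true(all(diff(A[order(sch$b)]) <= 1e-12))
  }
})

test_that("nested fractions expand to closed global fractions", {
  expect_equal(derive_fractions(0, 0, 0.4), list(f_ic = 0.4, f_ec = 0.6, f_stat = 0))
  expect_equal(derive_fractions(1, 0.3, 0.9), list(f_ic = 0, f_ec = 0, f_stat = 0))
  fr <- derive_fractions(0.2, 0.25, 0.5)
  expect_equal(fr$f_stat, 0.2)
  expect_equal(fr$f_ic, 0.3)
  expect_equal(fr$f_ec, 0.3)
  expect_equal(fr$f_ic + fr$f_ec + fr$f_stat + 0.2, 1, tolerance = 1e-15)
  expect_error(derive_fractions(1.2, 0, 0))
  # closure across a parameter sweep
  for (fi in c(0, 0.33, 1)) for (fs in c(0, 0.5, 1)) for (ff in c(0, 0.7, 1)) {
    fr <- derive_fractions(fi, fs, ff)
    expect_equal(fr$f_ic + fr$f_ec + fr$f_stat + fi, 1, tolerance = 1e-12)
  }
})

test_that("noddi_params validates and derives kappa/ODI consistently", {
  p <- noddi_params(0.1, 0.2, 0.5, odi = 0.25)
  expect_equal(kappa_to_odi(p$kappa), 0.25, tolerance = 1e-12)
  expect_equal(odi_to_kappa(kappa_to_odi(3.7)), 3.7, tolerance = 1e-12)
  expect_error(noddi_params(-0.1, 0, 0.5, odi = 0.2), "fractions")
  expect_error(noddi_params(0.1, 0, 0.5), "odi or kappa")
})

test_that("a noiseless voxel is recovered by the full fit", {
  sch <- hydi_scheme()
  mu <- c(1, 2, 2) / 3
  p <- noddi_params(0.15, 0.3, 0.55, odi = 0.25, mu = mu)
  y <- noddi_forward(p, sch)
  fit <- hdmri:::fit_noddi_voxel(y, sch, c(0, 0, 1), noddi_fit_config())
  expect_equal(fit$f_iso, 0.15, tolerance = 0.01)
  expect_equal(fit$f_stat_prime, 0.3, tolerance = 0.01)
  expect_equal(fit$f_ic_star, 0.55, tolerance = 0.01)
  expect_equal(fit$odi, 0.25, tolerance = 0.01)
  expect_lt(acos(min(1, abs(sum(fit$mu * mu)))) * 180 / pi, 1)
})

test_that("fit_noddi maps a small volume with diagnostics and closure", {
  g <- volume_grid(c(2, 2, 1))
  sch <- hydi_scheme(n_dir = 30, n_b0 = 2)
  params <- list(
    noddi_params(0.05, 0.1, 0.6, odi = 0.1, mu = c(0, 0, 1)),   # white-like
    noddi_params(0.05, 0.45, 0.15, odi = 0.35, mu = c(0, 1, 0)), # pyramidal-like
    noddi_params(1, 0, 0, odi = 0.5),                            # free water
    noddi_params(0.1, 0.2, 0.4, odi = 0.5, mu = c(1, 0, 0))      # dispersed
  )
  sig <- array(0, c(2, 2, 1, length(sch)))
  for (i in 1:4) {
    sig[arrayInd(i, c(2, 2, 1))[1], arrayInd(i, c(2, 2, 1))[2], 1, ] <-
      1000 * noddi_forward(params[[i]], sch)
  }
  dwi <- dwi_dataset(g, sig, sch, array(TRUE, c(2, 2, 1)))
  fit <- fit_noddi(dwi)
  expect_true(all(fit$mask))
  expect_true(all(is.finite(fit$rss[fit$mask])))
  # closure within 1e-12 everywhere
  closure <- fit$f_ic + fit$f_ec + fit$f_stat + fit$f_iso
  expect_true(all(abs(closure[fit$mask] - 1) < 1e-12))
  # free-water voxel identified
  expect_gte(fit$f_iso[3], 0.95)
  # white-like voxel fractions near truth
  expect_equal(fit$f_iso[1], 0.05, tolerance = 0.02)
  expect_equal(fit$f_ic_star[1], 0.6, tolerance = 0.02)
  # single-shell input warns about identifiability
  keep <- dwi$scheme$b < 5000
  dwi1 <- dwi_dataset(g, dwi$signal[, , , keep, drop = FALSE],
                      hdmri:::subset_scheme(dwi$scheme, keep), dwi$mask)
  expect_warning(fit_noddi(dwi1, noddi_fit_config(refine = FALSE)), "single-shell")
})

test_that("region statistics follow the 22-row legend schema", {
  g <- volume_grid(c(4, 4, 2))
  labels <- array(0L, c(4, 4, 2))
  labels[1:2, , 1] <- 3L   # head CA1
  labels[3:4, , 1] <- 10L  # body CA1
  lm <- label_map(g, labels)
  m <- array(0.5, c(4, 4, 2))
  st <- region_statistics(m, lm)
  expect_identical(nrow(st), 22L)
  expect_identical(st$structure[st$label == 3], "CA1")
  expect_equal(st$mean[st$label == 3], 0.5)
  expect_equal(st$sd[st$label == 3], 0)
  expect_identical(st$n_voxels[st$label == 3], 8L)
  expect_true(all(is.na(st$mean[!st$label %in% c(3, 10)])))
  # distinct constant regions keep their means
  m[labels == 10L] <- 0.8
  st2 <- region_statistics(m, lm)
  expect_equal(st2$mean[st2$label == 10], 0.8)
  expect_error(region_statistics(array(0, c(2, 2, 2)), lm), "grid")
})
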