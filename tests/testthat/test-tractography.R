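# Streamline tracking: seeding, the deterministic and probabilistic engines,
# and their termination/gating contracts.

test_that("seed generation is dense, in-voxel, and reproducible", {
  g <- volume_grid(c(5, 4, 3))
  mask <- array(FALSE, c(5, 4, 3))
  mask[cbind(c(1, 3, 5, 2, 4, 1, 2, 3, 4, 5),
             c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2),
             c(1, 1, 2, 2, 3, 3, 1, 2, 3, 1))] <- TRUE
  cfg <- tracking_config(seeds_per_voxel = 8L, rng_seed = 11L)
  seeds <- generate_seeds(mask, g, cfg)
  expect_identical(nrow(seeds), 8L * sum(mask))
  vox <- round(world_to_voxel(g, seeds))
  expect_true(all(mask[vox + 1]))
  seeds2 <- generate_seeds(mask, g, cfg)
  expect_identical(seeds, seeds2)
  expect_error(tracking_config(seeds_per_voxel = 0L), NA) # construction is fine
  expect_error(generate_seeds(mask, g, tracking_config(seeds_per_voxel = 0L)),
               "seeds_per_voxel")
  expect_error(generate_seeds(array(FALSE, c(5, 4, 3)), g, cfg), "empty")
})

test_that("tracking_config enforces its invariants", {
  expect_error(tracking_config(step = 0), "step")
  expect_error(tracking_config(max_angle = 120), "max_angle")
  expect_error(tracking_config(min_length = 100, max_length = 1), "min_length")
  expect_error(tracking_config(inertia_weight = 1), "inertia")
})

test_that("SRD on a straight field runs face to face with exact spacing", {
  ph <- straight_odf_field(shape = c(6, 6, 30))
  cfg <- tracking_config(seeds_per_voxel = 1L, rng_seed = 4L)
  seeds <- generate_seeds(array(TRUE, c(6, 6, 30)), ph$grid, cfg)
  tg <- track_srd(ph$field, seeds, cfg)
  expect_gt(length(tg$streamlines), 0.9 * nrow(seeds))
  lens <- streamline_lengths(tg)
  # slab depth 9 mm: tracks span it within 5%
  expect_equal(mean(lens), 9, tolerance = 0.05)
  expect_true(all(lens >= 0.5 & lens <= 100))
  # consecutive spacing equals the step within 1e-6 mm
  sp_ok <- vapply(tg$streamlines, function(p) {
    max(abs(sqrt(rowSums(diff(p)^2)) - cfg$step)) < 1e-6
  }, TRUE)
  expect_true(all(sp_ok))
  # per-step curvature bound
  expect_lt(max_step_angle(tg), cfg$max_angle + 1e-6)
  # endpoints within a voxel of the z faces
  ends_ok <- vapply(tg$streamlines, function(p) {
    z <- range(p[, 3]); z[1] < 0.45 && z[2] > 8.7 - 0.45 + 0.3
  }, TRUE)
  expect_gt(mean(ends_ok), 0.95)
})

test_that("a field below the amplitude threshold produces no streamlines", {
  ph <- straight_odf_field(shape = c(4, 4, 8))
  fld <- ph$field
  fld$amp[] <- 0
  cfg <- tracking_config(seeds_per_voxel = 2L, rng_seed = 1L)
  seeds <- generate_seeds(array(TRUE, c(4, 4, 8)), ph$grid, cfg)
  tg <- track_srd(fld, seeds, cfg)
  expect_identical(length(tg$streamlines), 0L)
})

test_that("SRP is seed-reproducible and respects the curvature bound", {
  ph <- straight_odf_field(shape = c(6, 6, 20))
  cfg <- tracking_config(seeds_per_voxel = 1L, rng_seed = 9L)
  seeds <- generate_seeds(array(TRUE, c(6, 6, 20)), ph$grid, cfg)
  t1 <- track_srp(ph$field, seeds, cfg)
  t2 <- track_srp(ph$field, seeds, cfg)
  expect_identical(t1$streamlines, t2$streamlines)
  expect_lt(max_step_angle(t1), cfg$max_angle + 1e-6)
  expect_true(all(streamline_lengths(t1) <= cfg$max_length))
})

test_that("SRD equals SRP when a single direction is admissible (tensor field)", {
  g <- volume_grid(c(5, 5, 16))
  sch <- single_shell_scheme(n_dir = 30)
  D <- diag(c(0.05, 0.05, 1.6)) * 1e-3
  att <- exp(-sch$b * rowSums((sch$directions %*% D) * sch$directions))
  dwi <- uniform_dwi(g, sch, att)
  fld <- dti_direction_field(fit_dti(dwi))
  cfg <- tracking_config(seeds_per_voxel = 1L, rng_seed = 2L)
  seeds <- generate_seeds(array(TRUE, c(5, 5, 16)), g, cfg)
  td <- track_srd(fld, seeds, cfg)
  tp <- track_srp(fld, seeds, cfg)
  expect_identical(td$streamlines, tp$streamlines)
  expect_gt(length(td$streamlines), 0L)
})

test_that("tracks are truncated at the maximum length", {
  # long thin slab with a tight length cap
  ph <- straight_odf_field(shape = c(4, 4, 40))
  cfg <- tracking_config(seeds_per_voxel = 1L, rng_seed = 3L,
                         min_length = 0.5, max_length = 6)
  seeds <- generate_seeds(array(TRUE, c(4, 4, 40)), ph$grid, cfg)
  tg <- track_srd(ph$field, seeds, cfg)
  expect_gt(length(tg$streamlines), 0L)
  expect_true(all(streamline_lengths(tg) <= 6 + 1e-9))
})
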