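# Shared data types, format readers/writers, and the command-line front end.

test_that("volume_grid validates its invariants and maps coordinates", {
  g <- volume_grid(c(4, 5, 6), voxel_size = c(0.3, 0.3, 0.3))
  expect_equal(voxel_to_world(g, c(0, 0, 0)), matrix(g$affine[1:3, 4], 1))
  p <- matrix(c(1.5, 2, 3), 1)
  expect_equal(world_to_voxel(g, voxel_to_world(g, p)), p)
  expect_error(volume_grid(c(4, 5, 6), voxel_size = c(0, 0.3, 0.3)))
  expect_error(volume_grid(c(4, 5, 6), affine = matrix(0, 4, 4)), "singular")
})

test_that("NIfTI writer/reader round-trips data, grid and datatypes", {
  tmp <- withr::local_tempdir()
  g <- volume_grid(c(3, 4, 5), voxel_size = c(0.3, 0.4, 0.5))
  set.seed(1)
  vol <- array(rnorm(60), c(3, 4, 5))
  for (ext in c(".nii", ".nii.gz")) {
    p <- file.path(tmp, paste0("x", ext))
    write_nifti(vol, g, p, datatype = "float64")
    rt <- read_nifti(p)
    expect_equal(rt$data, vol)
    expect_equal(rt$grid$affine, g$affine, tolerance = 1e-6)
    expect_equal(rt$grid$voxel_size, g$voxel_size, tolerance = 1e-6)
  }
  # float32 keeps declared precision
  p <- file.path(tmp, "f32.nii")
  write_nifti(vol, g, p, datatype = "float32")
  expect_equal(read_nifti(p)$data, vol, tolerance = 1e-6)
  # integer labels and masks
  lab <- array(sample(0:22, 60, replace = TRUE), c(3, 4, 5))
  write_nifti(lab, g, file.path(tmp, "lab.nii"), datatype = "int32")
  expect_identical(read_nifti(file.path(tmp, "lab.nii"))$data, array(as.double(lab), dim(lab)))
  # 4-D
  vol4 <- array(runif(120), c(3, 4, 5, 2))
  write_nifti(vol4, g, file.path(tmp, "v4.nii"))
  expect_equal(dim(read_nifti(file.path(tmp, "v4.nii"))$data), c(3L, 4L, 5L, 2L))
})

test_that("gradient scheme TSV and FSL import round-trip at float64 precision", {
  tmp <- withr::local_tempdir()
  sch <- hydi_scheme()
  p <- file.path(tmp, "scheme.tsv")
  write_scheme(sch, p)
  rt <- read_scheme(p)
  expect_equal(rt$b, sch$b)
  expect_equal(rt$directions, sch$directions)
  expect_equal(rt$TE, sch$TE)
  expect_equal(rt$Delta, sch$Delta)
  # FSL import with timing supplied by flags
  writeLines(paste(sch$b, collapse = " "), file.path(tmp, "bval"))
  writeLines(c(paste(sch$directions[, 1], collapse = " "),
               paste(sch$directions[, 2], collapse = " "),
               paste(sch$directions[, 3], collapse = " ")),
             file.path(tmp, "bvec"))
  fsl <- read_fsl_scheme(file.path(tmp, "bval"), file.path(tmp, "bvec"),
                         Delta = sch$Delta, delta = sch$delta, TE = sch$TE)
  expect_equal(fsl$b, sch$b)
  expect_equal(fsl$directions, sch$directions, tolerance = 1e-12)
  # validation errors
  expect_error(gradient_scheme(c(0, 4500), rbind(c(0, 0, 0), c(0, 0, 0)),
                               14.4, 4.3, 24.2), "non-unit")
  expect_error(gradient_scheme(c(0, 4500), rbind(c(0, 0, 0), c(0, 0, 1)),
                               4, 4.3, 24.2), "delta")
  expect_error(gradient_scheme(rep(4500, 2), rbind(c(0, 0, 1), c(0, 1, 0)),
                               14.4, 4.3, 24.2), "b = 0")
})

test_that("read_dwi round-trips and rejects inconsistent inputs", {
  tmp <- withr::local_tempdir()
  g <- volume_grid(c(2, 2, 2))
  sch <- single_shell_scheme(n_dir = 6)
  dwi <- uniform_dwi(g, sch, stick_attenuation(sch, c(0, 0, 1)))
  write_dwi(dwi, file.path(tmp, "d.nii"), file.path(tmp, "s.tsv"), file.path(tmp, "m.nii"))
  rt <- read_dwi(file.path(tmp, "d.nii"), file.path(tmp, "s.tsv"), file.path(tmp, "m.nii"))
  expect_equal(dim(rt$signal), dim(dwi$signal))
  expect_equal(rt$signal, dwi$signal, tolerance = 1e-6)
  expect_equal(rt$scheme$b, dwi$scheme$b)
  expect_true(all(rt$mask))
  # scheme row count must match volume count
  bad <- hdmri:::subset_scheme(dwi$scheme, seq_len(length(dwi$scheme) - 1))
  write_scheme(bad, file.path(tmp, "bad.tsv"))
  expect_error(read_dwi(file.path(tmp, "d.nii"), file.path(tmp, "bad.tsv")), "volumes")
  # default mask: first b0 > 0
  sig <- dwi$signal
  sig[1, 1, 1, ] <- 0
  d2 <- dwi_dataset(g, sig, dwi$scheme)
  expect_false(d2$mask[1, 1, 1])
  expect_true(d2$mask[2, 2, 2])
})

test_that("TCK writer/reader round-trips streamlines in world mm", {
  tmp <- withr::local_tempdir()
  tg <- toy_tractogram(list(list(c(0, 0, 0), c(1, 2, 3)),
                            list(c(-1, 0.5, 2), c(4, 4, 4))), n_pts = 7)
  p <- file.path(tmp, "t.tck")
  write_tck(tg, p)
  rt <- read_tck(p)
  expect_equal(length(rt$streamlines), 2L)
  for (i in 1:2) expect_equal(rt$streamlines[[i]], tg$streamlines[[i]], tolerance = 1e-6)
})

test_that("connectivity matrix TSV writes 23 lines and round-trips", {
  tmp <- withr::local_tempdir()
  counts <- matrix(0, 22, 22)
  counts[3, 7] <- counts[7, 3] <- 5
  m <- connectivity_matrix(counts)
  p <- file.path(tmp, "m.tsv")
  write_matrix_tsv(m, p)
  expect_length(readLines(p), 23L)
  rt <- read_matrix_tsv(p)
  expect_equal(rt$counts, m$counts)
  # incomplete legend rejected
  leg <- hippocampus_legend()
  leg$structure[4] <- NA
  m_bad <- m; m_bad$legend <- leg
  expect_error(write_matrix_tsv(m_bad, p), "legend")
})

test_that("run_cli dispatches, prints the calibration bounds, and fails cleanly", {
  out <- capture.output(status <- run_cli(c("calibrate", "--t2", "46", "--d", "0.00016")))
  expect_identical(status, 0L)
  expect_true(any(grepl("TE_max = 69 ms", out)))
  expect_true(any(grepl("b_max = 9361", out)))
  expect_identical(suppressMessages(run_cli(c("nosuchcmd"))), 1L)
  expect_identical(suppressMessages(run_cli(character(0))), 1L)
  out_b <- capture.output(status <- run_cli(c("calibrate-b", "--G", "0.512",
                                              "--delta", "0.0043", "--Delta", "0.0144")))
  expect_identical(status, 0L)
  expect_true(any(grepl("^b = 44", out_b)))
})

test_that("the phantom stage is bit-reproducible under a fixed seed", {
  tmp <- withr::local_tempdir()
  d1 <- file.path(tmp, "run1"); d2 <- file.path(tmp, "run2")
  st1 <- suppressMessages(run_cli(c("phantom", "--out-dir", d1, "--seed", "7",
                                    "--shape", "12,12,18")))
  st2 <- suppressMessages(run_cli(c("phantom", "--out-dir", d2, "--seed", "7",
                                    "--shape", "12,12,18")))
  expect_identical(st1, 0L)
  expect_identical(st2, 0L)
  for (f in c("dwi.nii", "labels.nii", "msme.nii", "scheme.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
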