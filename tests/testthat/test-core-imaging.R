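# Imaging data model and NIfTI I/O.

test_that("write/read roundtrip is the identity on values and voxel sizes", {
  tmp <- withr::local_tempdir()
  vol <- image_volume(array(1, c(4, 4, 1)), voxel_size_mm = c(1.33, 1.33, 4),
                      series_id = "ones")
  p <- file.path(tmp, "ones.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(dim(back), c(4L, 4L, 1L))
  expect_equal(back$data, vol$data)
  # the NIfTI header stores pixdim as float32, so compare at that precision
  expect_equal(back$voxel_size_mm, vol$voxel_size_mm, tolerance = 1e-6)

  # a structured map roundtrips with zero error at stored (double) precision
  arr <- array(seq(300, 1600, length.out = 64), c(8, 8, 1))
  p2 <- file.path(tmp, "t1.nii.gz")
  write_volume(image_volume(arr), p2)
  expect_equal(max(abs(read_volume(p2)$data - arr)), 0)
})

test_that("magnitude non-negativity is enforced at read and construction", {
  tmp <- withr::local_tempdir()
  arr <- array(1, c(4, 4, 1)); arr[2, 3, 1] <- -0.5
  expect_error(image_volume(arr), "negative")
  # write it as a signed map, then read it through the magnitude path
  p <- file.path(tmp, "neg.nii.gz")
  write_volume(image_volume(arr, check_nonneg = FALSE), p)
  expect_error(read_volume(p), "negative")
  expect_silent(v <- read_volume(p, signed = TRUE))
  expect_equal(v$data, arr)
})

test_that("complex volumes roundtrip through paired files with phase <= 1e-6", {
  tmp <- withr::local_tempdir()
  ph <- array(runif(64, -3, 3), c(8, 8, 1))
  z <- array(exp(1i * ph), c(8, 8, 1))
  vol <- image_volume(z, is_complex = TRUE)
  stem <- file.path(tmp, "bs.nii.gz")
  write_volume(vol, stem)
  expect_true(file.exists(file.path(tmp, "bs_real.nii.gz")))
  expect_true(file.exists(file.path(tmp, "bs_imag.nii.gz")))
  back <- read_volume(stem, expect_complex = TRUE)
  expect_true(back$is_complex)
  expect_lt(max(abs(Arg(back$data) - ph)), 1e-6)
})

test_that("complex Bloch-Siegert pair roundtrips with unchanged phase difference", {
  tmp <- withr::local_tempdir()
  gt <- uniform_gel_gt(1000, f = 1)
  pair <- simulate_bs_pair(gt, constant_pulse_far())
  pd0 <- phase_difference(pair)$data
  pp <- file.path(tmp, "plus.nii.gz"); pm <- file.path(tmp, "minus.nii.gz")
  write_volume(pair$img_plus, pp)
  write_volume(pair$img_minus, pm)
  pair2 <- bs_phase_pair(read_volume(pp, expect_complex = TRUE),
                         read_volume(pm, expect_complex = TRUE),
                         pair$offset_hz)
  expect_equal(phase_difference(pair2)$data, pd0, tolerance = 1e-12)
})

test_that("unwritable/missing paths error", {
  vol <- image_volume(array(1, c(4, 4, 1)))
  expect_error(write_volume(vol, "/nonexistent-dir-xyz/a.nii.gz"), "directory")
  expect_error(read_volume("/nonexistent-file-xyz.nii.gz"), "not found")
  ro <- withr::local_tempdir()
  Sys.chmod(ro, "0555")
  withr::defer(Sys.chmod(ro, "0755"))
  if (file.access(ro, 2L) != 0L) {  # not running as a permission-exempt user
    expect_error(write_volume(vol, file.path(ro, "a.nii.gz")), "writable")
  } else {
    expect_no_error(write_volume(vol, file.path(ro, "a.nii.gz")))
  }
})

test_that("series_from_volumes dispatches on metadata and validates", {
  mk <- function(n) lapply(seq_len(n), function(i) image_volume(array(i, c(4, 4, 1))))
  angles <- seq(2, 20, by = 2)
  vfa <- series_from_volumes(mk(10), list(flip_angles_deg = angles,
                                          tr_ms = 7.9, te_ms = 4.6))
  expect_s3_class(vfa, "vfa_series")
  expect_equal(vfa$flip_angles_deg, angles)

  tis <- c(25, 50, 75, 100, 200, 300, 400, 500, 1000, 2000, 4000, 10000)
  ir <- series_from_volumes(mk(12), list(ti_ms = tis, td_ms = 2500))
  expect_s3_class(ir, "ir_series")
  expect_equal(ir$ti_ms, tis)
  expect_equal(ir$inv_flip_deg, 180)

  expect_error(series_from_volumes(mk(9), list(flip_angles_deg = angles,
                                               tr_ms = 7.9)),
               "does not match")
  expect_error(series_from_volumes(mk(2), list()), "does not identify")
})

test_that("series constructors reject invariant violations", {
  mk <- function(n) lapply(seq_len(n), function(i) image_volume(array(1, c(4, 4, 1))))
  expect_error(vfa_series(mk(3), c(0, 5, 10), tr_ms = 7.9), "\\(0, 90\\]")
  expect_error(vfa_series(mk(3), c(10, 5, 15), tr_ms = 7.9), "increasing")
  expect_error(vfa_series(mk(3), c(5, 10, 95), tr_ms = 7.9), "\\(0, 90\\]")
  expect_error(vfa_series(mk(3), c(5, 10, 15), tr_ms = -1), "tr_ms")
  expect_error(ir_series(mk(3), c(100, 100, 200), td_ms = 2500), "increasing")
  expect_error(ir_series(mk(3), c(-5, 100, 200), td_ms = 2500), "positive")
  # mixed grids rejected
  vols <- c(mk(2), list(image_volume(array(1, c(5, 4, 1)))))
  expect_error(vfa_series(vols, c(5, 10, 15), tr_ms = 7.9), "one grid")
  # complex flag mismatch in a BS pair
  re <- image_volume(array(1, c(4, 4, 1)))
  cx <- image_volume(array(1 + 0i, c(4, 4, 1)), is_complex = TRUE)
  expect_error(bs_phase_pair(re, cx, 4000), "complex")
})

test_that("t1_map enforces validity invariants", {
  t1 <- array(1000, c(4, 4, 1)); s0 <- array(1, c(4, 4, 1))
  rss <- array(0, c(4, 4, 1)); ok <- array(TRUE, c(4, 4, 1))
  m <- t1_map(t1, s0, rss, method = "VFA", valid_mask = ok)
  expect_s3_class(m, "t1_map")
  bad <- t1; bad[1, 1, 1] <- -5
  expect_error(t1_map(bad, s0, rss, "VFA", ok), "positive")
  # invalid voxels get the NA sentinel
  ok2 <- ok; ok2[1, 1, 1] <- FALSE
  t1b <- t1; t1b[1, 1, 1] <- -5
  m2 <- t1_map(t1b, s0, rss, "IR", ok2)
  expect_true(is.na(m2$t1_ms[1, 1, 1]))
  expect_error(t1_map(t1, s0, rss, "bogus", ok))
})
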