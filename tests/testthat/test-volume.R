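test_that("NIfTI round trip preserves voxels, spacing and origin", {
  vol <- random_volume(c(10, 10, 10), seed = 3, spacing = c(1, 2, 3))
  vol$origin <- c(5, -4, 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, "PET")
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("non-canonical on-disk axis order is reoriented on read", {
  # asymmetric pattern so any axis mix-up is visible
  vol <- image_volume(array(seq_len(6 * 8 * 10), c(6, 8, 10)),
                      spacing = c(1, 2, 3), origin = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  img <- RNifti::readNifti(path)
  for (code in c("PSR", "LIA", "SRA")) {
    permuted <- img
    RNifti::orientation(permuted) <- code
    p2 <- withr::local_tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(permuted, p2)
    back <- read_volume(p2, "PET")
    expect_identical(back$voxels, vol$voxels)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  }
})

test_that("unreadable input raises an informative I/O error", {
  bad <- withr::local_tempfile(fileext = ".nii")
  writeLines("this is not an image", bad)
  expect_error(read_volume(bad, "CT"), "NIfTI|read")
  expect_error(read_volume(file.path(tempdir(), "absent.nii")),
               "does not exist")
})

test_that("resampling preserves identity, constants, and linear fields", {
  vol <- random_volume(c(8, 8, 8), seed = 2)
  same <- resample_isotropic(vol, 1.0)
  expect_equal(same$voxels, vol$voxels, tolerance = 1e-6)

  const <- image_volume(array(7, c(8, 8, 8)), spacing = c(2, 2, 2),
                        modality = "CT")
  fine <- resample_isotropic(const, 1.0)
  expect_equal(dim(fine$voxels), c(16L, 16L, 16L))
  expect_equal(range(fine$voxels), c(7, 7), tolerance = 1e-6)

  # values linear in physical x must be reproduced at the new grid centres
  lin <- array(rep(3 * (0:7) * 2 + 0.5, times = 64), c(8, 8, 8))
  lv <- image_volume(lin, spacing = c(2, 2, 2))
  lr <- resample_isotropic(lv, 1.0)
  n <- dim(lr$voxels)[1]
  expected <- 3 * (0:(n - 2)) + 0.5      # interior voxels
  err <- max(abs(sweep(lr$voxels[seq_len(n - 1), , , drop = FALSE], 1,
                       expected)))
  expect_lt(err, 1e-3)
})

test_that("order-1 resampling never exceeds the input range", {
  for (seed in 1:5) {
    vol <- random_volume(c(7, 9, 5), seed = seed, spacing = c(1.7, 0.9, 2.3))
    out <- resample_isotropic(vol, 1.0, spline_order = 1)
    expect_gte(min(out$voxels), min(vol$voxels))
    expect_lte(max(out$voxels), max(vol$voxels))
  }
})

test_that("resampling rejects degenerate input and bad parameters", {
  thin <- image_volume(array(1, c(1, 5, 5)))
  expect_error(resample_isotropic(thin), "degenerate")
  vol <- random_volume(c(5, 5, 5))
  expect_error(resample_isotropic(vol, -1), "positive")
  expect_error(resample_isotropic(vol, 1, spline_order = 2), "0, 1 or 3")
})

test_that("bone windowing clamps both tails and is idempotent", {
  ramp <- image_volume(array(seq(-1000, 3000, length.out = 4^3), c(4, 4, 4)),
                       modality = "CT")
  out <- clip_hu(ramp)
  # elementwise clamp oracle
  expect_equal(as.vector(out$voxels),
               pmin(pmax(as.vector(ramp$voxels), 700), 2000))
  expect_equal(min(out$voxels), 700)
  expect_equal(max(out$voxels), 2000)
  inr <- ramp$voxels > 700 & ramp$voxels < 2000
  expect_identical(out$voxels[inr], ramp$voxels[inr])
  expect_identical(clip_hu(out)$voxels, out$voxels)

  floor_mode <- clip_hu(ramp, mode = "floor")
  expect_true(all(floor_mode$voxels[!inr] == 700))

  expect_error(clip_hu(ramp, lo = 10, hi = 5), "smaller")
  pet <- random_volume(c(4, 4, 4))
  expect_error(clip_hu(pet), "CT")
})
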