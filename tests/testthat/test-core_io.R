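test_that("NIfTI volume round-trip preserves data and affine", {
  vol <- toy_volume()
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f, datatype = "double")
  back <- read_volume(f)
  expect_equal(back$data, vol$data)
  expect_equal(back$affine, vol$affine, tolerance = 1e-6)
  unlink(f)
})

test_that("anisotropic clinical spacing survives a round-trip", {
  vol <- toy_volume(spacing = c(1.11, 1.11, 2.65))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f, datatype = "double")
  back <- read_volume(f)
  expect_equal(back$spacing, c(1.11, 1.11, 2.65), tolerance = 1e-5)
  unlink(f)
})

test_that("degenerate volumes are rejected", {
  expect_error(new_volume(array(0, c(4, 4)), diag(4)), "3D")
  A <- diag(4); A[1, 1] <- 0
  expect_error(new_volume(array(0, c(4, 4, 4)), A), "singular")
  expect_error(new_volume(array(NA_real_, c(4, 4, 4)), diag(4)), "finite")
  expect_error(read_volume(tempfile()), "not found")
})

test_that("4D NIfTI input is rejected with advice to split", {
  img <- RNifti::asNifti(array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3)))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "split")
  unlink(f)
})

test_that("displacement field round-trip is bit-exact", {
  geom <- toy_volume()
  set.seed(2)
  fld <- new_field(array(rnorm(prod(geom$dim) * 3), c(geom$dim, 3L)), geom)
  f <- tempfile(fileext = ".nii.gz")
  write_field(fld, f)
  back <- read_field(f)
  expect_identical(dim(back$u), dim(fld$u))
  expect_equal(back$u, fld$u)
  expect_equal(back$affine, fld$affine, tolerance = 1e-6)
  unlink(f)
})

test_that("landmark CSV round-trip preserves records and flags", {
  lm <- toy_landmarks()
  lm$uncertain[5:6] <- TRUE
  lm$fx <- lm$fx + 0.12345678
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(nrow(back), 6L)
  expect_equal(back$fx, lm$fx, tolerance = 1e-7)
  expect_identical(back$uncertain, lm$uncertain)
  unlink(f)

  # empty table with header
  f2 <- tempfile(fileext = ".csv")
  write_landmarks(lm[0, ], f2)
  expect_equal(nrow(read_landmarks(f2)), 0L)
  unlink(f2)
})

test_that("malformed landmark tables are rejected", {
  lm <- toy_landmarks()
  expect_error(validate_landmarks <- dcemoco:::validate_landmarks(lm[, -4]),
               "missing columns")
  lm2 <- toy_landmarks()
  lm2$mx <- as.character(lm2$mx)
  lm2$mx[2] <- "not-a-number"
  f <- tempfile(fileext = ".csv")
  utils::write.csv(lm2, f, row.names = FALSE)
  expect_error(read_landmarks(f), "non-numeric")
  unlink(f)
})

test_that("resampling onto the same grid is the identity in both modes", {
  vol <- toy_volume()
  for (mode in c("linear", "nearest")) {
    out <- resample_to_reference(vol, vol, interpolation = mode)
    expect_equal(out$data, vol$data, tolerance = 1e-12)
  }
})

test_that("constant image resamples to a constant inside the overlap", {
  vol <- new_volume(array(7, c(8, 8, 6)), make_affine(c(2, 2, 3)))
  ref <- new_volume(array(0, c(5, 5, 4)), make_affine(c(2, 2, 3), c(2, 2, 3)))
  out <- resample_to_reference(vol, ref)
  expect_true(all(out$data == 7))
})

test_that("downsampled ramp matches the analytic ramp at new voxel centers", {
  dims <- c(16, 14, 12)
  geom <- new_volume(array(0, dims), make_affine(c(2, 2, 3)))
  w <- dcemoco:::grid_world_coords(geom)
  vol <- new_volume(array(3 + 0.5 * w[, 1] - 0.25 * w[, 2] + 0.1 * w[, 3], dims),
                    geom$affine)
  # 2x coarser reference, voxel centers strictly inside the source domain
  ref <- new_volume(array(0, c(7, 6, 5)), make_affine(c(4, 4, 6), c(1, 1, 1.5)))
  out <- resample_to_reference(vol, ref)
  wr <- dcemoco:::grid_world_coords(ref)
  expected <- 3 + 0.5 * wr[, 1] - 0.25 * wr[, 2] + 0.1 * wr[, 3]
  expect_equal(as.numeric(out$data), expected, tolerance = 1e-10)
})

test_that("out-of-field-of-view voxels receive the configured fill value", {
  vol <- new_volume(array(5, c(4, 4, 4)), make_affine(c(1, 1, 1)))
  ref <- new_volume(array(0, c(4, 4, 4)), make_affine(c(1, 1, 1), c(10, 0, 0)))
  out <- resample_to_reference(vol, ref, fill = -1)
  expect_true(all(out$data == -1))
})

test_that("series construction enforces a shared grid and valid fixed phase", {
  v1 <- toy_volume(seed = 1)
  v2 <- toy_volume(seed = 2)
  s <- dce_series(list(v1, v2))
  expect_equal(s$fixed_index, 2L)
  expect_error(dce_series(list(v1)), "at least 2")
  v3 <- toy_volume(spacing = c(1, 1, 1))
  expect_error(dce_series(list(v1, v3)), "share one grid")
  expect_error(dce_series(list(v1, v2), fixed_index = 9), "fixed_index")
  s5 <- dce_series(rep(list(v1), 5))
  expect_equal(s5$labels[5], "late-venous")
})

test_that("map_points with no field or a zero field is the identity", {
  geom <- toy_volume()
  pts <- matrix(c(3, 4, 5, 10, 8, 9), ncol = 3, byrow = TRUE)
  expect_equal(map_points(NULL, pts), pts)
  expect_equal(map_points(zero_field(geom), pts), pts)
})
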