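test_that("resampling an already-isotropic grid is the identity", {
  set.seed(5)
  vol <- image_volume(array(rnorm(8 * 7 * 6), c(8, 7, 6)), c(2, 2, 2))
  msk <- roi_mask(array(1L, c(8, 7, 6)), c(2, 2, 2))
  rs <- resample_isotropic(vol, msk, 2)
  expect_equal(dim(rs$volume$values), c(8L, 7L, 6L))
  expect_lt(max(abs(rs$volume$values - vol$values)), 1e-6)
  expect_identical(rs$mask$values, msk$values)
})

test_that("resampling a constant volume stays constant", {
  vol <- image_volume(array(3.5, c(9, 9, 5)), c(1, 1, 3))
  msk <- roi_mask(array(1L, c(9, 9, 5)), c(1, 1, 3))
  rs <- resample_isotropic(vol, msk, 2)
  expect_lt(max(abs(rs$volume$values - 3.5)), 1e-9)
  expect_equal(rs$volume$spacing, c(2, 2, 2))
})

test_that("resampled sphere mask volume stays within 5% of the analytic value", {
  spec <- phantom_spec(noise_reference = 0,
                       fov_mm = c(48, 48, 48))
  proto <- data.frame(name = "iso1", mA = 100, thickness_mm = 1,
                      inplane_mm = 1, contrast = FALSE)
  g <- generate_phantom_volume(spec, proto, seed = 1)
  rs <- resample_isotropic(g$volume, g$mask, 2)
  vol_mm3 <- sum(rs$mask$values) * 8
  expect_lt(abs(vol_mm3 - 26521.85) / 26521.85, 0.05)
  expect_error(resample_isotropic(g$volume, g$mask, -1), "positive")
})

test_that("threshold segmentation matches the partial-volume oracle on the phantom", {
  spec <- phantom_spec(noise_reference = 0, fov_mm = c(48, 48, 48))
  proto <- layout_phantom()$protocols[1, ]
  g <- generate_phantom_volume(spec, proto, seed = 1)
  seg <- threshold_segment(g$volume, 0.40)
  # threshold 0.4 * 400 = 160 sits between background (100) and sphere (400):
  # selected voxels are exactly those with membership fraction >= 0.2
  expected <- g$volume$values >= 160
  expect_identical(seg$values == 1L, expected)
  # the segmented region contains the voxelized interior
  expect_true(all(seg$values[g$mask$values == 1L &
                             g$volume$values == 400] == 1L))
})

test_that("threshold segmentation keeps only the largest 26-connected blob", {
  arr <- array(0, c(12, 6, 6))
  arr[2:4, 2:4, 2:4] <- 10    # 27 voxels
  arr[9:10, 2:3, 2:3] <- 10   # 8 voxels
  vol <- image_volume(arr, c(1, 1, 1))
  seg <- threshold_segment(vol, 0.5)
  expect_equal(sum(seg$values), 27L)
  expect_true(all(seg$values[2:4, 2:4, 2:4] == 1L))
  # brute-force labeling oracle agrees on the component structure
  zones <- brute_zones(array(as.integer(arr > 5), dim(arr)))
  expect_equal(sort(zones[, "size"]), c(8L, 27L))
  # near-1 fraction with a unique maximum -> single voxel
  arr[3, 3, 3] <- 99
  seg1 <- threshold_segment(image_volume(arr, c(1, 1, 1)), 0.999)
  expect_equal(sum(seg1$values), 1L)
  expect_equal(which(seg1$values == 1L), which(arr == 99))
  expect_error(threshold_segment(vol, 1.2), "between 0 and 1")
})

test_that("discretization follows the min-anchored floor rule", {
  vol <- image_volume(array(c(0, 10, 24, 25, 60, 0, 0, 0), c(2, 2, 2)),
                      c(1, 1, 1))
  msk <- roi_mask(array(c(1, 1, 1, 1, 1, 0, 0, 0), c(2, 2, 2)), c(1, 1, 1))
  d <- discretize(vol, msk, 25)
  expect_equal(d$levels, c(1L, 1L, 1L, 2L, 3L))
  expect_equal(d$n_levels, 3L)
  # constant ROI
  cr <- constant_roi()
  d0 <- discretize(cr$volume, cr$mask, 25)
  expect_true(all(d0$levels == 1L))
  expect_equal(d0$n_levels, 1L)
  # shift invariance
  vol2 <- image_volume(vol$values + 1234.5, c(1, 1, 1))
  expect_identical(discretize(vol2, msk, 25)$levels, d$levels)
  expect_error(discretize(vol, msk, 0), "positive")
})

test_that("NRRD round trip preserves volumes, masks and metadata", {
  set.seed(2)
  vol <- image_volume(array(rnorm(60), c(5, 4, 3)), c(0.9, 0.9, 2.5),
                      origin = c(-10, 5, 2))
  f <- tempfile(fileext = ".nrrd")
  write_nrrd(vol, f)
  back <- read_nrrd(f)
  expect_identical(back$values, vol$values)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
  msk <- roi_mask(array(rbinom(60, 1, 0.5) | c(1, rep(0, 59)), c(5, 4, 3)),
                  c(0.9, 0.9, 2.5))
  fm <- tempfile(fileext = ".nrrd")
  write_nrrd(msk, fm)
  backm <- as_roi_mask(read_nrrd(fm))
  expect_identical(backm$values, msk$values)
  # ascii encoding round trip
  fa <- tempfile(fileext = ".nrrd")
  write_nrrd(vol, fa, encoding = "ascii")
  expect_equal(read_nrrd(fa)$values, vol$values, tolerance = 1e-12)
  expect_error(read_nrrd(f1 <- {writeLines("not nrrd", f2 <- tempfile()); f2}),
               "not an NRRD")
})
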