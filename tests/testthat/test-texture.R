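test_that("single-gray-level ROI takes the analytic texture limits", {
  cr <- constant_roi(dims = c(4, 4, 4))
  droi <- discretize(cr$volume, cr$mask, 25)
  g <- glcm_features(droi)
  expect_equal(unname(g["JointEnergy"]), 1)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["Correlation"]), 1)
  r <- glrlm_features(droi)
  expect_equal(unname(r["GrayLevelNonUniformityNormalized"]), 1)
  n <- ngtdm_features(droi)
  expect_equal(unname(n["Contrast"]), 0)
  z <- glszm_features(droi)
  expect_equal(unname(z["ZonePercentage"]), 1 / 64)  # one zone of 64 voxels
})

test_that("GLCM contrast on a 4x4x1 checkerboard matches pair counting", {
  arr <- array(0, c(4, 4, 1))
  arr[] <- (outer(1:4, 1:4, "+") %% 2) * 25  # levels 1 and 2 after binning
  vol <- image_volume(arr, c(1, 1, 1))
  msk <- roi_mask(array(1L, c(4, 4, 1)), c(1, 1, 1))
  droi <- discretize(vol, msk, 25)
  got <- glcm_features(droi)
  # oracle: average per-direction contrast from exhaustively counted pairs
  per_dir <- apply(oracle_dirs, 1, function(d) {
    C <- brute_glcm_dir(droi$level_array, d, droi$n_levels)
    C <- C + t(C)
    if (sum(C) == 0) return(NA_real_)
    P <- C / sum(C)
    sum(outer(1:2, 1:2, function(i, j) (i - j)^2) * P)
  })
  expect_equal(unname(got["Contrast"]), mean(per_dir, na.rm = TRUE))
})

test_that("GLRLM on a single row matches the hand-tallied run matrix", {
  arr <- array(0, c(1, 6, 1))
  arr[1, , 1] <- c(1, 1, 1, 2, 2, 3)
  vol <- image_volume(arr, c(1, 1, 1))
  msk <- roi_mask(array(1L, c(1, 6, 1)), c(1, 1, 1))
  droi <- discretize(vol, msk, 1)
  # along the row: runs {level 1: length 3, level 2: length 2, level 3: length 1}
  P <- brute_glrlm_dir(droi$level_array, c(0, 1, 0), 3)
  expect_equal(P[1, 3], 1)
  expect_equal(P[2, 2], 1)
  expect_equal(P[3, 1], 1)
  sre_row <- (1 / 9 + 1 / 4 + 1) / 3
  # the other 12 directions see 6 unit runs each (SRE = 1)
  expect_equal(unname(glrlm_features(droi)["ShortRunEmphasis"]),
               (12 * 1 + sre_row) / 13)
})

test_that("texture matrices equal exhaustive brute-force counts on random ROIs", {
  for (seed in c(101, 202, 303)) {
    rd <- random_droi(seed, dims = c(6, 5, 4), ngray = 4)
    lev <- rd$lev
    ng <- rd$ngray
    dims <- dim(lev)
    # GLCM per direction
    counts <- radstab:::cpp_glcm(lev, dims, ng)
    for (a in 1:13)
      expect_equal(counts[, , a], brute_glcm_dir(lev, oracle_dirs[a, ], ng),
                   ignore_attr = TRUE)
    # GLRLM per direction
    rlm <- radstab:::cpp_glrlm(lev, dims, ng)
    for (a in 1:13) {
      want <- brute_glrlm_dir(lev, oracle_dirs[a, ], ng)
      got <- rlm[[a]]
      expect_equal(got[, seq_len(ncol(want))], want, ignore_attr = TRUE)
      if (ncol(got) > ncol(want))
        expect_true(all(got[, -seq_len(ncol(want))] == 0))
    }
    # GLSZM zones
    zones <- brute_zones(lev)
    want <- matrix(0, ng, max(zones[, "size"]))
    for (r in seq_len(nrow(zones)))
      want[zones[r, "level"], zones[r, "size"]] <-
        want[zones[r, "level"], zones[r, "size"]] + 1
    expect_equal(radstab:::cpp_glszm(lev, dims, ng), want, ignore_attr = TRUE)
    # GLDM
    expect_equal(radstab:::cpp_gldm(lev, dims, ng, 0L), brute_gldm(lev, ng, 0),
                 ignore_attr = TRUE)
    # NGTDM
    expect_equal(radstab:::cpp_ngtdm(lev, dims, ng), brute_ngtdm(lev, ng),
                 ignore_attr = TRUE)
  }
})

test_that("texture features are invariant to intensity shifts", {
  set.seed(77)
  arr <- array(sample(0:120, 5^3, replace = TRUE), c(5, 5, 5))
  msk <- roi_mask(array(1L, c(5, 5, 5)), c(1, 1, 1))
  d1 <- discretize(image_volume(arr, c(1, 1, 1)), msk, 25)
  d2 <- discretize(image_volume(arr - 512.5, c(1, 1, 1)), msk, 25)
  for (fn in list(glcm_features, glrlm_features, glszm_features,
                  ngtdm_features, gldm_features))
    expect_identical(fn(d1), fn(d2))
})
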