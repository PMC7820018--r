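test_that("variance components validate and define the true ICC", {
  vc <- variance_components(2, 1, 2)
  expect_equal(true_icc(vc), 0.5)
  expect_error(variance_components(-1, 0, 0), "subject_var")
  expect_error(variance_components(1, -2, 0), "rater_var")
  expect_equal(true_icc(components_for_icc(0.9)), 0.9)
})

test_that("simulated tables are deterministic and complete", {
  lay <- layout_rider(subjects = 10)
  t1 <- simulate_feature_table(lay, variance_components(1, 0.2, 1), 5, seed = 4)
  t2 <- simulate_feature_table(lay, variance_components(1, 0.2, 1), 5, seed = 4)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 10 * 2 * 5)
  expect_false(anyNA(t1$value))
  expect_error(simulate_feature_table(lay, variance_components(1, 0, 1), 0),
               "n_features")
})

test_that("zero residual variance gives ICC exactly 1 despite rater offsets", {
  lay <- layout_rider(subjects = 8)
  tab <- simulate_feature_table(lay, variance_components(2, 50, 0), 3, seed = 9)
  for (f in unique(tab$feature)) {
    m <- matrix(tab$value[tab$feature == f], 8, 2)
    expect_equal(icc3(m)$icc, 1)
  }
})

test_that("consistency ICC distribution ignores arbitrarily large rater variance", {
  lay <- layout_rider(subjects = 30)
  a <- simulate_feature_table(lay, variance_components(1, 0, 1), 20, seed = 5)
  b <- simulate_feature_table(lay, variance_components(1, 1e4, 1), 20, seed = 5)
  icc_of <- function(tab) vapply(unique(tab$feature), function(f)
    icc3(matrix(tab$value[tab$feature == f], 30, 2))$icc, numeric(1))
  expect_equal(icc_of(a), icc_of(b), tolerance = 1e-10)
})

test_that("Monte-Carlo mean ICC matches the closed form s/(s+e)", {
  lay <- layout_rider(subjects = 100)
  tab <- simulate_feature_table(lay, variance_components(1, 0.3, 1), 200,
                                seed = 21)
  est <- vapply(unique(tab$feature), function(f)
    icc3(matrix(tab$value[tab$feature == f], 100, 2))$icc, numeric(1))
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * mc_se + 1e-3)
})

test_that("noise-free phantom hits the 4:1 ratio and the analytic sphere volume", {
  spec <- phantom_spec(noise_reference = 0)
  proto <- layout_phantom()$protocols[1, ]
  g <- generate_phantom_volume(spec, proto, seed = 1)
  expect_equal(max(g$volume$values), 4 * spec$background_level)
  expect_equal(g$volume$values[1, 1, 1], spec$background_level)
  vox <- prod(g$mask$spacing)
  analytic <- 4 / 3 * pi * (37 / 2)^3
  # one supersampled-voxel shell of tolerance around the sphere surface
  shell <- 4 * pi * (37 / 2)^2 * max(g$mask$spacing) / 3
  expect_lt(abs(sum(g$mask$values) * vox - analytic), shell)
})

test_that("phantom volumes are seed-deterministic and noise-only across timepoints", {
  spec <- phantom_spec()
  proto <- layout_phantom()$protocols[3, ]
  a <- generate_phantom_volume(spec, proto, timepoint = "T1", seed = 2)
  b <- generate_phantom_volume(spec, proto, timepoint = "T1", seed = 2)
  expect_identical(a$volume$values, b$volume$values)
  d <- generate_phantom_volume(spec, proto, timepoint = "T2", seed = 2)
  expect_false(identical(a$volume$values, d$volume$values))
  expect_identical(a$mask$values, d$mask$values)  # geometry unchanged
  expect_error(generate_phantom_volume(
    phantom_spec(sphere_diameter_mm = 80), proto), "does not fit")
})

test_that("phantom noise sd scales as 1/sqrt(mA x slice thickness)", {
  spec <- phantom_spec()
  protos <- layout_phantom()$protocols
  sds <- mas <- numeric(nrow(protos))
  for (i in seq_len(nrow(protos))) {
    g <- generate_phantom_volume(spec, protos[i, ], seed = 8)
    bg <- g$volume$values[1:10, 1:10, ]  # corner: pure background
    sds[i] <- stats::sd(bg)
    mas[i] <- protos$mA[i] * protos$thickness_mm[i]
  }
  fit <- stats::lm(log(sds) ~ log(mas))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 0.5), 0.05 * 0.5)
})

test_that("study fixtures reproduce the designed layouts", {
  fx <- make_study_fixture("phantom", seed = 1,
                           spec = phantom_spec(fov_mm = c(48, 48, 48)))
  expect_length(fx, 36L)
  slots <- unique(vapply(fx, function(s)
    paste(s$scanner, s$protocol, s$timepoint), character(1)))
  expect_length(slots, 36L)
  clin <- make_study_fixture("clinical", seed = 1, n_features = 40)
  expect_equal(length(unique(clin$subject)), 104L)
  expect_equal(length(unique(clin$protocol)), 3L)
  d <- attr(clin, "design")
  expect_equal(sum(d$volume_proxy), 4L)
  expect_length(attr(clin, "gtv_cm3"), 104L)
  rider <- make_study_fixture("rider", seed = 1, n_features = 10)
  expect_equal(length(unique(rider$subject)), 32L)
  expect_equal(length(unique(rider$timepoint)), 2L)
  expect_error(make_study_fixture("nema"), "phantom, clinical, rider")
})

test_that("fixture tables carry exact designed sample ICCs", {
  clin <- make_study_fixture("clinical", seed = 13, n_features = 30)
  d <- attr(clin, "design")
  for (f in d$feature[!d$volume_proxy][1:10]) {
    m <- matrix(clin$value[clin$feature == f], 104, 3)
    expect_equal(icc3(m)$icc, d$true_icc[d$feature == f], tolerance = 1e-9)
  }
})
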