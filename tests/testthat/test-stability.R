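# Small helper: long table from a per-feature list of n x k matrices with
# columns interpreted as protocols (single scanner, single timepoint).
table_from_matrices <- function(mats, protocols = NULL) {
  do.call(rbind, lapply(names(mats), function(f) {
    m <- mats[[f]]
    k <- ncol(m)
    prot <- if (is.null(protocols)) paste0("P", seq_len(k)) else protocols
    data.frame(subject = rep(sprintf("S%02d", seq_len(nrow(m))), k),
               scanner = "sc1", protocol = rep(prot, each = nrow(m)),
               timepoint = "T1", feature = f, value = as.vector(m),
               stringsAsFactors = FALSE)
  }))
}

test_that("identical-timepoint tables give ICC exactly 1", {
  rider <- make_study_fixture("rider", seed = 2, n_features = 12)
  # overwrite the retest with the test values: perfect repeatability
  t1 <- rider[rider$timepoint == "T1", ]
  t2 <- t1
  t2$timepoint <- "T2"
  rr <- repeatability(rbind(t1, t2))
  expect_true(all(rr$icc == 1))
  expect_true(all(rr$classification == "good"))
})

test_that("repeatability recovers a true ICC of 0.9 with small bias", {
  lay <- layout_rider(subjects = 100)
  tab <- simulate_feature_table(lay, components_for_icc(0.9), 200, seed = 31)
  rr <- repeatability(tab)
  expect_equal(mean(rr$icc), 0.9, tolerance = 0.03)
})

test_that("pure-noise features are classified poor", {
  lay <- layout_rider(subjects = 60)
  tab <- simulate_feature_table(lay, variance_components(0, 0.1, 1), 5,
                                seed = 17)
  rr <- repeatability(tab)
  expect_true(all(rr$classification == "poor"))
})

test_that("repeatability demands two timepoints and names missing slots", {
  clin <- make_study_fixture("clinical", seed = 3, n_features = 4)
  expect_error(repeatability(clin), "2 timepoints")
})

test_that("offset protocol columns give pairwise ICC 1", {
  set.seed(23)
  x <- rnorm(20)
  # a constant per-column offset is invisible to the consistency ICC
  tab <- table_from_matrices(list(fA = cbind(x, x + 10)))
  res <- clinical_reproducibility(tab, pair = c("P1", "P2"))
  expect_equal(res$icc, 1)
  expect_error(clinical_reproducibility(tab, pair = c("P1", "NOPE")),
               "unknown protocol")
})

test_that("tiered clinical fixture recovers designed classification counts", {
  clin <- make_study_fixture("clinical", seed = 5, n_features = 200)
  d <- attr(clin, "design")
  res <- clinical_reproducibility(clin)
  m <- merge(res, d, by = "feature")
  expect_equal(sum(m$classification == "good"),
               sum(d$tier %in% c("good", "proxy")))
  expect_equal(sum(m$classification == "moderate"), sum(d$tier == "moderate"))
  expect_equal(sum(m$classification == "poor"), sum(d$tier == "poor"))
  expect_true(all(m$classification[m$tier == "moderate"] == "moderate"))
})

test_that("identically permuting subjects leaves every ICC unchanged", {
  clin <- make_study_fixture("clinical", seed = 6, n_features = 8)
  res1 <- clinical_reproducibility(clin)
  set.seed(1)
  perm <- sample(unique(clin$subject))
  clin2 <- clin
  clin2$subject <- perm[match(clin$subject, unique(clin$subject))]
  res2 <- clinical_reproducibility(clin2)
  expect_equal(res1$icc, res2$icc, tolerance = 1e-12)
})

test_that("intra- and inter-scanner experiments report the median ICC", {
  fx <- make_study_fixture("phantom", seed = 1,
                           spec = phantom_spec(fov_mm = c(44, 44, 44)))
  ft <- extract_fixture(fx, extraction_config(filters = "original"))
  intra <- intra_scanner(ft)
  expect_setequal(unique(intra$experiment),
                  c("intra_scanner1", "intra_scanner2", "intra_scanner3",
                    "intra_scanner_median"))
  med <- intra[intra$experiment == "intra_scanner_median", ]
  f1 <- med$feature[1]
  per <- intra$icc[intra$feature == f1 &
                   intra$experiment != "intra_scanner_median"]
  expect_equal(med$icc[med$feature == f1], median(per, na.rm = TRUE))
  inter <- inter_scanner(ft)
  expect_equal(sum(grepl("^inter_P", unique(inter$experiment))), 6L)
  expect_true("inter_scanner_median" %in% inter$experiment)
})

test_that("volume collinearity flags monotone volume functions", {
  clin <- make_study_fixture("clinical", seed = 9, n_features = 40)
  gtv <- attr(clin, "gtv_cm3")
  d <- attr(clin, "design")
  # append two hand-built features: volume squared and negated volume
  extra <- clin[clin$feature %in% d$feature[1], ]
  sq <- extra; sq$feature <- "vol_sq"; sq$value <- gtv[sq$subject]^2
  ng <- extra; ng$feature <- "vol_neg"; ng$value <- -gtv[ng$subject]
  vc <- volume_collinearity(rbind(clin, sq, ng), gtv)
  expect_equal(vc$rho[vc$feature == "vol_sq"], 1)
  expect_equal(vc$rho[vc$feature == "vol_neg"], -1)
  expect_true(all(vc$rho[vc$feature %in% d$feature[d$volume_proxy]] > 0.9))
  expect_error(volume_collinearity(clin, gtv[-1]), "missing tumor volume")
})

test_that("commonality enumerates Venn regions correctly", {
  r <- commonality(list(A = c("f1", "f2"), B = c("f3", "f4")))
  expect_equal(unname(r$counts["A&B"]), 0L)
  r2 <- commonality(list(A = c("f1", "f2"), B = c("f1", "f2")))
  expect_equal(unname(r2$counts["A&B"]), 2L)
  # three designed sets vs hand enumeration
  r3 <- commonality(list(A = c("a", "ab", "abc", "ac"),
                         B = c("b", "ab", "abc", "bc"),
                         C = c("c", "ac", "bc", "abc")))
  expect_equal(unname(r3$counts[c("A", "B", "C", "A&B", "A&C", "B&C",
                                  "A&B&C")]),
               c(1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(r3$regions[["A&B&C"]], "abc")
  # classification-level input
  df <- data.frame(feature = c("x", "y"), classification = c("good", "poor"))
  r4 <- commonality(list(E1 = df, E2 = "x"))
  expect_equal(unname(r4$counts["E1&E2"]), 1L)
})

test_that("select_stable returns the designed stable set and honors thresholds", {
  clin <- make_study_fixture("clinical", seed = 4, n_features = 100)
  rider <- make_study_fixture("rider", seed = 4, n_features = 100)
  d <- attr(clin, "design")
  rep_res <- repeatability(rider)
  rpr_res <- clinical_reproducibility(clin)
  vc <- volume_collinearity(clin, attr(clin, "gtv_cm3"))
  sel <- select_stable(rep_res, rpr_res, vc)
  expect_s3_class(sel, "stable_set")
  expect_setequal(sel$feature, d$feature[d$tier == "good"])
  expect_true(all(diff(sel$median_icc) <= 0))  # decreasing order
  # no collinearity filter: good-repeatability proxies stay in
  d_rider <- attr(rider, "design")
  sel_nofilter <- select_stable(rep_res, rpr_res, NULL)
  expect_setequal(sel_nofilter$feature,
                  d_rider$feature[d_rider$tier == "good"])
  expect_true(any(d$volume_proxy[match(sel_nofilter$feature, d$feature)]))
  # unreachable threshold: empty set
  expect_equal(nrow(select_stable(rep_res, rpr_res, vc,
                                  icc_threshold = 1.01)), 0L)
})

test_that("category summary matches hand-computed statistics", {
  st <- data.frame(feature = c("original_gldm_DependenceNonUniformity",
                               "original_glrlm_RunLengthNonUniformity",
                               "original_gldm_SmallDependenceEmphasis"),
                   category = "TA",
                   median_icc = c(0.9571, 0.9333, 0.9084))
  cs <- category_summary(st)
  expect_equal(round(cs$median_icc, 3), 0.933)
  expect_equal(round(cs$sd_icc, 3), 0.024)
  # single member: sd 0 with a note
  expect_message(cs1 <- category_summary(
    data.frame(category = "WF", median_icc = 0.91, feature = "f")),
    "single member")
  expect_equal(cs1$sd_icc, 0)
  # identical values
  cs2 <- category_summary(data.frame(category = "LOG",
                                     median_icc = rep(0.92, 4),
                                     feature = letters[1:4]))
  expect_equal(cs2$median_icc, 0.92)
  expect_equal(cs2$sd_icc, 0)
})

test_that("feature correlation matrix is a valid Spearman matrix", {
  set.seed(15)
  x <- rnorm(30)
  f1m <- cbind(x, x + rnorm(30, 0, 0.1))
  mats <- list(f1 = f1m,
               f2 = exp(f1m),  # observation-wise monotone map of f1
               f3 = cbind(rnorm(30), rnorm(30)))
  tab <- table_from_matrices(mats)
  cm <- feature_correlation_matrix(tab)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # f2 is a monotone map of f1 observation-wise -> Spearman 1
  expect_equal(cm["f1", "f2"], 1)
  # hand-checked 3-observation rank case
  tab2 <- table_from_matrices(list(a = matrix(c(1, 2, 3), 3),
                                   b = matrix(c(30, 10, 20), 3)))
  # need k >= 1 column each; correlation across the 3 observations
  cm2 <- feature_correlation_matrix(tab2)
  expect_equal(cm2["a", "b"],
               cor(c(1, 2, 3), c(30, 10, 20), method = "spearman"))
})
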