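#' Extraction configuration
#'
#' Collects the preprocessing and extraction settings: isotropic resampling
#' target (2 mm), fixed bin width for gray-level discretization (25),
#' Laplacian-of-Gaussian scales (1, 2, 3 mm) and the wavelet family
#' (Coiflet-1, single level, undecimated). Discretization is applied
#' independently to the original and to each filtered image, since filters
#' change the dynamic range.
#'
#' @param bin_width discretization bin width (intensity units).
#' @param resample_mm isotropic voxel target in mm; `NULL` skips resampling.
#' @param sigmas_mm LoG scales in mm.
#' @param wavelet wavelet family for [wavelet_decompose()].
#' @param filters which image types to extract from.
#' @export
extraction_config <- function(bin_width = 25, resample_mm = 2,
                              sigmas_mm = c(1, 2, 3), wavelet = "coif1",
                              filters = c("original", "log", "wavelet")) {
  stopifnot(bin_width > 0, is.null(resample_mm) || resample_mm > 0,
            all(sigmas_mm > 0))
  filters <- match.arg(filters, several.ok = TRUE)
  structure(list(bin_width = bin_width, resample_mm = resample_mm,
                 sigmas_mm = sigmas_mm, wavelet = wavelet, filters = filters),
            class = "extraction_config")
}

texture_class_extractors <- function() list(
  glcm = glcm_features, glrlm = glrlm_features, glszm = glszm_features,
  ngtdm = ngtdm_features, gldm = gldm_features)

filter_image_labels <- function(config = extraction_config()) {
  labs <- character(0)
  if ("original" %in% config$filters) labs <- "original"
  if ("log" %in% config$filters)
    labs <- c(labs, sprintf("log-sigma-%d-0-mm-3D", config$sigmas_mm))
  if ("wavelet" %in% config$filters)
    labs <- c(labs, paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                         "HLL", "HLH", "HHL", "HHH")))
  labs
}

#' Canonical feature-id roster
#'
#' Feature ids are `<filter>_<class>_<Name>` with filter one of `original`,
#' `log-sigma-{1,2,3}-0-mm-3D` or `wavelet-{LLL..HHH}` and class one of
#' `firstorder, glcm, glrlm, glszm, ngtdm, gldm`. The full roster has
#' 90 features per image x 12 images = 1080 ids.
#'
#' @param config an [extraction_config()].
#' @return character vector of feature ids.
#' @export
feature_name_roster <- function(config = extraction_config()) {
  droi_names <- list(
    firstorder = c("Energy", "Entropy", "Minimum", "10Percentile",
                   "90Percentile", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                   "Skewness", "Kurtosis", "Variance", "Uniformity"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
             "Id", "Idn", "InverseVariance", "MaximumProbability",
             "SumEntropy", "SumSquares"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
              "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "GrayLevelVariance", "RunVariance", "RunEntropy",
              "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
              "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
              "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
             "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis"))
  unlist(lapply(filter_image_labels(config), function(f)
    unlist(lapply(names(droi_names), function(cl)
      paste(f, cl, droi_names[[cl]], sep = "_")), use.names = FALSE)),
    use.names = FALSE)
}

#' Feature category (TA / LOG / WF)
#'
#' `TA` = original-image (texture-analysis) features, `LOG` = any
#' Laplacian-of-Gaussian scale, `WF` = any wavelet sub-band.
#'
#' @param feature_ids character vector of canonical feature ids.
#' @return character vector of categories.
#' @export
feature_category <- function(feature_ids) {
  ifelse(startsWith(feature_ids, "log-sigma"), "LOG",
         ifelse(startsWith(feature_ids, "wavelet"), "WF", "TA"))
}

#' Extract the full radiomic feature vector
#'
#' Pipeline: isotropic resampling -> filter images (original, LoG at each
#' sigma, 8 wavelet sub-bands) -> per-image fixed-bin-width discretization
#' -> first-order + GLCM/GLRLM/GLSZM/NGTDM/GLDM extraction. With the default
#' configuration the result has exactly 1080 named entries.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] aligned to `volume`.
#' @param config an [extraction_config()].
#' @return named numeric vector (the feature vector).
#' @export
extract_all <- function(volume, mask, config = extraction_config()) {
  check_aligned(volume, mask)
  if (!is.null(config$resample_mm)) {
    rs <- resample_isotropic(volume, mask, config$resample_mm)
    volume <- rs$volume
    mask <- rs$mask
  }
  images <- list()
  if ("original" %in% config$filters) images$original <- volume
  if ("log" %in% config$filters)
    for (s in config$sigmas_mm)
      images[[sprintf("log-sigma-%d-0-mm-3D", s)]] <- tryCatch(
        log_filter(volume, s),
        error = function(e)
          stop("log-sigma-", s, "-0-mm-3D: ", conditionMessage(e)))
  if ("wavelet" %in% config$filters) {
    wb <- tryCatch(wavelet_decompose(volume, config$wavelet),
                   error = function(e)
                     stop("wavelet: ", conditionMessage(e)))
    for (lab in names(wb)) images[[paste0("wavelet-", lab)]] <- wb[[lab]]
  }
  out <- numeric(0)
  for (lab in names(images)) {
    img <- images[[lab]]
    fo <- tryCatch(firstorder_features(img, mask, config$bin_width),
                   error = function(e)
                     stop(lab, "_firstorder: ", conditionMessage(e)))
    droi <- discretize(img, mask, config$bin_width)
    vals <- c(stats::setNames(fo, paste(lab, "firstorder", names(fo), sep = "_")))
    extractors <- texture_class_extractors()
    for (cl in names(extractors)) {
      fv <- tryCatch(extractors[[cl]](droi),
                     error = function(e)
                       stop(lab, "_", cl, ": ", conditionMessage(e)))
      vals <- c(vals, stats::setNames(fv, paste(lab, cl, names(fv), sep = "_")))
    }
    out <- c(out, vals)
  }
  out
}

#' Extract features for every slot of a phantom fixture
#'
#' Runs [extract_all()] on each (scanner, protocol, timepoint) slot and
#' returns the long-format feature table used by the stability analyses.
#'
#' @param fixture a `"phantom"` [make_study_fixture()] result (or any list
#'   of slots with `volume`, `mask`, `scanner`, `protocol`, `timepoint`).
#' @param config an [extraction_config()].
#' @param subject subject label for the phantom (single physical object).
#' @return long-format `data.frame` with columns
#'   `subject, scanner, protocol, timepoint, feature, value`.
#' @export
extract_fixture <- function(fixture, config = extraction_config(),
                            subject = "phantom") {
  rows <- lapply(fixture, function(s) {
    fv <- extract_all(s$volume, s$mask, config)
    data.frame(subject = subject, scanner = s$scanner, protocol = s$protocol,
               timepoint = s$timepoint, feature = names(fv), value = unname(fv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
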