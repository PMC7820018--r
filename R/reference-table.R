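#' Published reference list of stable radiomic features
#'
#' The consensus list of 108 radiomic features reported as both repeatable
#' and reproducible across a multi-scanner image-quality-phantom study and
#' an NSCLC clinical cohort, after removing features strongly correlated
#' (|rho| > 0.9) with tumor volume: feature id, category (TA =
#' original-image, LOG = Laplacian-of-Gaussian, WF = wavelet) and the
#' overall median ICC, ordered by decreasing median ICC. Shipped as plain
#' CSV under `extdata`.
#'
#' @return `data.frame` with columns `feature`, `category`, `median_icc`
#'   (108 rows).
#' @export
stable_feature_reference <- function() {
  path <- system.file("extdata", "stable_features_reference.csv",
                      package = "radstab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
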