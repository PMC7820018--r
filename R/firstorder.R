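#' First-order intensity statistics
#'
#' The 17 first-order features of the conventional radiomics roster:
#' Energy, Entropy, Minimum, 10Percentile, 90Percentile, Maximum, Mean,
#' Median, InterquartileRange, Range, MeanAbsoluteDeviation,
#' RobustMeanAbsoluteDeviation, RootMeanSquared, Skewness, Kurtosis,
#' Variance, Uniformity. Entropy and Uniformity are computed on the
#' fixed-bin-width discretized histogram; everything else on the raw
#' in-mask intensities. Variance, skewness and kurtosis use the population
#' (1/N) moments; kurtosis is not excess-corrected. On a constant (or
#' single-voxel) ROI the variance-type features are 0 and skewness/kurtosis
#' are undefined and returned as `NaN`.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param bin_width histogram bin width for Entropy/Uniformity.
#' @return named numeric vector of length 17.
#' @export
firstorder_features <- function(volume, mask, bin_width = 25) {
  check_aligned(volume, mask)
  v <- volume$values[mask$values == 1L]
  n <- length(v)
  droi <- discretize(volume, mask, bin_width)
  p <- tabulate(droi$levels) / n
  p <- p[p > 0]
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  mu <- mean(v)
  vpop <- mean((v - mu)^2)
  sdp <- sqrt(vpop)
  robust <- v[v >= q[1] & v <= q[5]]
  c(Energy = sum(v^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(v),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (sdp > 0) mean((v - mu)^3) / sdp^3 else NaN,
    Kurtosis = if (sdp > 0) mean((v - mu)^4) / vpop^2 else NaN,
    Variance = vpop,
    Uniformity = sum(p^2))
}
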