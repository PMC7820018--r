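# Keys cubic-convolution interpolation kernel (a = -0.5), the standard
# interpolating cubic for image resampling.
keys_weights <- function(t) {
  a <- -0.5
  w <- function(x) {
    x <- abs(x)
    ifelse(x < 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  cbind(w(t + 1), w(t), w(t - 1), w(t - 2))
}

# Interpolate a 3D array along one axis at fractional (0-based) voxel
# positions `pos`, cubic ("keys") or nearest ("nn"), clamped at the border.
interp_axis <- function(arr, axis, pos, method = c("keys", "nn")) {
  method <- match.arg(method)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- d[axis]
  if (method == "nn") {
    i <- pmin(pmax(round(pos), 0), n - 1) + 1
    out <- m[i, , drop = FALSE]
  } else {
    i0 <- floor(pos)
    t <- pos - i0
    w <- keys_weights(t)
    out <- matrix(0, length(pos), ncol(m))
    for (tap in 0:3) {
      i <- pmin(pmax(i0 - 1 + tap, 0), n - 1) + 1
      out <- out + w[, tap + 1] * m[i, , drop = FALSE]
    }
  }
  newd <- d
  newd[axis] <- length(pos)
  aperm(array(out, dim = newd[perm]), order(perm))
}

#' Resample a volume and mask to an isotropic grid
#'
#' Intensities are interpolated with a separable cubic-convolution kernel;
#' the mask is resampled nearest-neighbor and re-binarized. The new grid
#' keeps the input origin and covers the physical extent of the input voxel
#' centers to within one voxel.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] aligned to `volume`.
#' @param target isotropic voxel size in mm (> 0); default 2.
#' @return `list(volume, mask)` on the new grid.
#' @export
resample_isotropic <- function(volume, mask, target = 2) {
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("'target' must be a single positive voxel size in mm")
  check_aligned(volume, mask)
  d <- dim(volume$values)
  extent <- (d - 1) * volume$spacing
  nnew <- pmax(2L, as.integer(floor(extent / target + 1e-9)) + 1L)
  vals <- volume$values
  mvals <- mask$values
  for (ax in 1:3) {
    pos <- (seq_len(nnew[ax]) - 1) * target / volume$spacing[ax]
    vals <- interp_axis(vals, ax, pos, "keys")
    mvals <- interp_axis(mvals, ax, pos, "nn")
  }
  mvals <- mvals >= 0.5
  if (sum(mvals) < 1)
    stop("ROI is empty after resampling to ", target, " mm (degenerate ROI)")
  list(volume = image_volume(vals, rep(target, 3), volume$origin),
       mask = roi_mask(mvals, rep(target, 3), volume$origin))
}

#' Threshold-based auto-segmentation
#'
#' Selects voxels with intensity at or above `fraction` of the global
#' maximum and keeps the largest 26-connected component, mirroring the
#' 40%-of-maximum auto-segmentation used to delineate an active phantom
#' insert or avid tumor.
#'
#' @param volume an [image_volume()].
#' @param fraction threshold as a fraction of the maximum, in (0, 1).
#' @return an [roi_mask()].
#' @export
threshold_segment <- function(volume, fraction = 0.4) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1")
  thr <- fraction * max(volume$values)
  cand <- volume$values >= thr
  if (!any(cand))
    stop("thresholding produced an empty region")
  lab <- cpp_label_components(as.integer(cand), dim(volume$values))
  counts <- tabulate(lab)
  keep <- which.max(counts)
  roi_mask(array(lab == keep, dim(volume$values)), volume$spacing,
           volume$origin)
}

#' Discretize ROI intensities with a fixed bin width
#'
#' Gray level of an in-mask voxel v is
#' `floor((I(v) - min_in_mask) / bin_width) + 1`, i.e. constant-width bins
#' anchored at the in-ROI minimum, so levels are invariant to any intensity
#' shift. Applied independently to the original and each filtered image.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param bin_width bin width in intensity units (> 0); default 25.
#' @return an object of class `discretized_roi`: in-mask `levels`, the full
#'   `level_array` (0 outside the ROI), `n_levels`, `bin_width`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a single positive width")
  check_aligned(volume, mask)
  inroi <- mask$values == 1L
  v <- volume$values[inroi]
  lev <- as.integer(floor((v - min(v)) / bin_width)) + 1L
  arr <- array(0L, dim(volume$values))
  arr[inroi] <- lev
  structure(list(levels = lev, level_array = arr,
                 n_levels = max(lev), bin_width = bin_width,
                 dims = dim(volume$values), spacing = volume$spacing),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi> %d voxels, %d gray levels (bin width %g)\n",
              length(x$levels), x$n_levels, x$bin_width))
  invisible(x)
}
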