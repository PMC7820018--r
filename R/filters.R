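# Separable 1D convolution along one axis of a 3D array. `kernel` is an
# odd-length tap vector indexed symmetrically around its center. Boundary:
# "reflect" mirrors at the edge (intensity filters), "periodic" wraps
# (wavelet sub-bands).
conv_axis <- function(arr, axis, kernel, boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  L <- length(kernel)
  h <- (L - 1L) %/% 2L
  d <- dim(arr)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- matrix(0, n, ncol(m))
  for (tap in seq_len(L)) {
    off <- tap - 1L - h
    i <- seq_len(n) + off
    i <- if (boundary == "reflect") {
      # whole-sample mirror with period 2n: ... 2 1 | 1 2 .. n | n n-1 ...
      j <- (i - 1L) %% (2L * n)
      j <- ifelse(j < 0L, j + 2L * n, j)
      ifelse(j < n, j + 1L, 2L * n - j)
    } else {
      (i - 1L) %% n + 1L
    }
    out <- out + kernel[tap] * m[i, , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

# Sampled Gaussian (sum-normalized) and its sampled second derivative
# (corrected to zero sum so a constant input maps to zero), both in voxel
# units, truncated at 4 sigma.
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g / sum(g)
}

gauss_d2_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
  k - mean(k)
}

#' Laplacian-of-Gaussian filter
#'
#' Scale-normalized LoG response (multiplied by sigma^2, so responses are
#' comparable across scales), computed as the sum over axes of a sampled
#' second-derivative-of-Gaussian kernel along that axis times Gaussian
#' smoothing along the others. `sigma` is physical (mm) and converted to
#' voxels per axis via the spacing. A sigma below half the smallest voxel
#' dimension is under-resolved on the grid and triggers a warning but is
#' still computed.
#'
#' @param volume an [image_volume()].
#' @param sigma filter scale in mm (> 0).
#' @return an [image_volume()] on the same grid.
#' @export
log_filter <- function(volume, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive scale in mm")
  if (sigma < min(volume$spacing) / 2)
    warning("sigma (", sigma, " mm) is under-resolved for voxel spacing ",
            paste(format(volume$spacing, digits = 3), collapse = "x"),
            " mm; computing anyway")
  sig_vox <- sigma / volume$spacing
  out <- array(0, dim(volume$values))
  for (ax in 1:3) {
    part <- volume$values
    for (a2 in 1:3) {
      k <- if (a2 == ax) gauss_d2_kernel(sig_vox[a2]) else gauss_kernel(sig_vox[a2])
      part <- conv_axis(part, a2, k, "reflect")
    }
    # sigma^2-normalization in the axis' voxel units
    out <- out + part * sig_vox[ax]^2
  }
  image_volume(out, volume$spacing, volume$origin)
}

# Coiflet-1 analysis filters (low-pass; high-pass by quadrature mirror).
coif1_lo <- c(-0.01565572813546454, -0.0727326195128539, 0.38486484686420286,
              0.8525720202122554, 0.3378976624578092, -0.0727326195128539)
wavelet_filters <- function(family = "coif1") {
  lo <- switch(family,
    coif1 = coif1_lo,
    haar = c(1, 1) / sqrt(2),
    stop("unsupported wavelet family: ", family))
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  # pad to odd length so conv_axis can center the kernel
  list(lo = c(lo, 0), hi = c(hi, 0))
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) wavelet transform, one level, eight
#' sub-bands labeled `LLL` ... `HHH`: letter i names the filter (L =
#' low-pass, H = high-pass) applied along array axis i. Circular (periodic)
#' boundary handling; all outputs stay on the input grid.
#'
#' @param volume an [image_volume()].
#' @param family wavelet family (default Coiflet-1).
#' @return named list of eight [image_volume()] objects.
#' @export
wavelet_decompose <- function(volume, family = "coif1") {
  f <- wavelet_filters(family)
  d <- dim(volume$values)
  if (any(d < length(f$lo)))
    stop("volume (", paste(d, collapse = "x"),
         ") is smaller than the wavelet filter support on some axis")
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- vector("list", 8L)
  names(out) <- labels
  for (lab in labels) {
    arr <- volume$values
    letters3 <- strsplit(lab, "")[[1]]
    for (ax in 1:3) {
      k <- if (letters3[ax] == "L") f$lo else f$hi
      arr <- conv_axis(arr, ax, k, "periodic")
    }
    out[[lab]] <- image_volume(arr, volume$spacing, volume$origin)
  }
  out
}
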