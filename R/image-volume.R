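#' 3D image volume
#'
#' Container for a 3D scalar grid with physical metadata. Grid indices are
#' 0-based in world-coordinate terms: the center of voxel (i, j, k) sits at
#' \code{origin + c(i, j, k) * spacing} (millimeters). Axis order is
#' (x, y, z) = array dimensions (1, 2, 3) throughout the package.
#'
#' @param values numeric 3D array of voxel intensities (finite).
#' @param spacing numeric length-3, voxel size in mm per axis (> 0).
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @return an object of class \code{image_volume}.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array, got ", length(dim(values)), " dims")
  if (!all(is.finite(values)))
    stop("'values' must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary region-of-interest mask
#'
#' A mask aligned to an [image_volume()]: same grid shape, spacing and origin,
#' voxel values strictly in \{0, 1\}, at least one foreground voxel.
#'
#' @param values 3D array coercible to 0/1.
#' @inheritParams image_volume
#' @return an object of class \code{roi_mask}.
#' @export
roi_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L)))
    stop("mask values must be 0 or 1")
  if (sum(values) < 1L)
    stop("mask has no foreground voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' @export
dim.roi_mask <- function(x) dim(x$values)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d foreground (%.1f mm^3)\n",
              paste(dim(x$values), collapse = "x"),
              sum(x$values), sum(x$values) * prod(x$spacing)))
  invisible(x)
}

# Shared alignment check used by every volume+mask operation.
check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values)))
    stop("volume and mask have different grid shapes")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9)
    stop("volume and mask have different spacing")
  invisible(TRUE)
}
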