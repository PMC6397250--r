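#' Calibrated image container
#'
#' A thin container pairing an intensity array with its spatial calibration.
#' 2D images are matrices indexed `[y, x]`; z-stacks are 3D arrays indexed
#' `[z, y, x]`. Pixel centres sit on the integer grid, so the physical
#' position of pixel `(i, j)` is `((i - 1) * pixel_size, (j - 1) * pixel_size)`
#' micrometres.
#'
#' @param pixels Numeric matrix (2D) or 3D array ordered `[z, y, x]`.
#' @param pixel_size Micrometres per pixel. A single value for 2D images, or
#'   a length-3 vector `(z, y, x)` for stacks.
#' @param roi Optional logical matrix with the same y/x footprint as
#'   `pixels`, marking the region of interest.
#' @param center Optional length-2 vector `(x, y)` in pixel coordinates
#'   (1-based), marking the optic-nerve-head analogue.
#' @param metadata Free-form list of provenance notes.
#'
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size, roi = NULL, center = NULL,
                             metadata = list()) {
  if (is.null(dim(pixels)) || !(length(dim(pixels)) %in% c(2L, 3L))) {
    abort("`pixels` must be a 2D matrix or a 3D array ordered (z, y, x).")
  }
  if (length(pixels) == 0L) abort("`pixels` must not be empty.")
  nd <- length(dim(pixels))
  expected_ps <- if (nd == 2L) 1L else 3L
  if (length(pixel_size) == 1L && nd == 3L) {
    pixel_size <- rep(pixel_size, 3L)
  }
  if (length(pixel_size) != expected_ps || any(!is.finite(pixel_size)) ||
      any(pixel_size <= 0)) {
    abort("`pixel_size` must be positive (one value for 2D, three (z, y, x) for 3D).")
  }
  footprint <- if (nd == 2L) dim(pixels) else dim(pixels)[2:3]
  if (!is.null(roi)) {
    roi <- roi_as_logical(roi)
    if (!identical(dim(roi), as.integer(footprint))) {
      abort("`roi` must have the same height/width as `pixels`.")
    }
  }
  if (!is.null(center)) {
    center <- as.numeric(center)
    if (length(center) != 2L || any(!is.finite(center))) {
      abort("`center` must be a finite (x, y) pair in pixel coordinates.")
    }
    if (center[1] < 1 || center[1] > footprint[2] ||
        center[2] < 1 || center[2] > footprint[1]) {
      abort("`center` must lie inside the image bounds.")
    }
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size), roi = roi,
         center = center, metadata = metadata),
    class = "calibrated_image"
  )
}

roi_as_logical <- function(roi) {
  d <- dim(roi)
  roi <- array(as.logical(roi != 0 & !is.na(roi)), dim = d)
  if (length(d) != 2L) abort("`roi` must be a 2D mask.")
  roi
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 2L) "2D image" else sprintf("z-stack (%d slices)", d[1])
  cat(sprintf("<calibrated_image> %s, %s px, %s um/px\n", kind,
              paste(d, collapse = " x "),
              paste(signif(x$pixel_size, 4), collapse = " x ")))
  if (!is.null(x$roi)) cat(sprintf("  roi: %d px in region\n", sum(x$roi)))
  if (!is.null(x$center)) {
    cat(sprintf("  center: (%.1f, %.1f) px\n", x$center[1], x$center[2]))
  }
  invisible(x)
}

#' Binary vessel mask
#'
#' The result of binarization: a logical matrix with spatial calibration and
#' an optional region-of-interest mask. Foreground (`TRUE`) marks vessel.
#'
#' @param pixels Logical matrix `[y, x]`.
#' @param pixel_size Micrometres per pixel.
#' @param roi Optional logical matrix of the same size.
#' @param center Optional `(x, y)` pixel coordinates of the network centre.
#'
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size, roi = NULL, center = NULL) {
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L) {
    abort("`pixels` must be a 2D matrix.")
  }
  m <- matrix(as.logical(pixels != 0 & !is.na(pixels)), nrow(pixels), ncol(pixels))
  if (length(pixel_size) != 1L || !is.finite(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number.")
  }
  if (!is.null(roi)) {
    roi <- roi_as_logical(roi)
    if (!identical(dim(roi), dim(m))) abort("`roi` must match the mask size.")
  }
  structure(list(pixels = m, pixel_size = as.numeric(pixel_size), roi = roi,
                 center = center),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, sum(x$pixels)))
  invisible(x)
}

#' Circular region-of-interest mask
#'
#' Convenience constructor for the disk-shaped ROI typical of retinal
#' flatmount analysis.
#'
#' @param dim Image size as `(n_rows, n_cols)`.
#' @param center Disk centre `(x, y)` in pixel coordinates (1-based).
#' @param radius_px Disk radius in pixels.
#'
#' @return Logical matrix marking pixels within `radius_px` of `center`.
#' @export
disk_roi <- function(dim, center, radius_px) {
  stopifnot(length(dim) == 2L, length(center) == 2L, radius_px > 0)
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c_ <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (r - center[2])^2 + (c_ - center[1])^2 <= radius_px^2
}
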