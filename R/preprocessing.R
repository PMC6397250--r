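#' Convert an image to 8-bit by linear rescaling
#'
#' Linearly rescales intensities to the range 0-255, as the first step of
#' the binarization chain. The minimum maps to 0 and the maximum to 255;
#' values are rounded half-away-from-zero to integers. A constant image maps
#' to all zeros.
#'
#' @param image A [calibrated_image()] (2D or 3D). Stacks are rescaled with
#'   a single global min/max so the z-profile is preserved.
#'
#' @return A `calibrated_image` with integer pixel values in 0-255.
#' @export
to_8bit <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  rng <- range(px, finite = TRUE)
  if (!all(is.finite(rng))) abort("image contains no finite intensities")
  out <- if (rng[2] > rng[1]) {
    round_half_away((px - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    array(0, dim = dim(px))
  }
  image$pixels <- array(out, dim = dim(px))
  image
}

# round half away from zero (R's round() is round-half-even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Adaptive local-mean threshold
#'
#' Binarizes a grayscale image against its local mean: a pixel is foreground
#' iff its intensity exceeds the mean over a `window_px` x `window_px`
#' neighbourhood (replicate-padded at the borders) by more than `offset`.
#' This is the standard adaptive binarization for unevenly illuminated
#' fluorescence flatmounts: vessels are locally bright, so a positive
#' `offset` suppresses flat background regardless of the illumination level.
#'
#' @param image A 2D [calibrated_image()], typically 8-bit (see [to_8bit()]).
#' @param window_px Odd window side in pixels (default 51).
#' @param offset Intensity a pixel must exceed its local mean by to be
#'   called vessel (default 10, on the 8-bit scale).
#'
#' @return A [binary_mask()] carrying the image's calibration, ROI and
#'   centre point.
#' @export
adaptive_threshold <- function(image, window_px = 51L, offset = 10) {
  stopifnot(inherits(image, "calibrated_image"))
  if (length(dim(image$pixels)) != 2L) {
    abort("`adaptive_threshold` operates on 2D images; project stacks first.")
  }
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L) {
    abort("`window_px` must be an odd integer >= 3.")
  }
  mu <- local_mean(image$pixels, window_px)
  binary_mask(image$pixels > mu + offset, pixel_size = image$pixel_size[1],
              roi = image$roi, center = image$center)
}

# box mean over a w x w window with replicate padding, via an integral image
local_mean <- function(m, w) {
  r <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  mp <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)),
          c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  s <- apply(mp, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  s <- rbind(0, cbind(0, s))
  ri <- seq_len(nr); ci <- seq_len(nc)
  tot <- s[ri + 2L * r + 1L, ci + 2L * r + 1L, drop = FALSE] -
    s[ri, ci + 2L * r + 1L, drop = FALSE] -
    s[ri + 2L * r + 1L, ci, drop = FALSE] +
    s[ri, ci, drop = FALSE]
  tot / (w * w)
}

#' Despeckle a binary mask with a radius-0.5 median filter
#'
#' Applies a median filter over the 5-pixel plus-shaped neighbourhood
#' (centre plus its 4-neighbours, replicate-padded at the borders). On a
#' binary mask this is a majority vote: isolated single pixels are removed
#' and single-pixel holes in solid regions are filled. One-pixel-wide
#' diagonal lines are erased by this kernel, which is why rasterized vessel
#' strokes must be at least 2 px wide to survive despeckling.
#'
#' @param mask A [binary_mask()].
#'
#' @return The despeckled [binary_mask()].
#' @export
median_despeckle <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$pixels
  nr <- nrow(m); nc <- ncol(m)
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  votes <- m + up + down + left + right
  mask$pixels <- matrix(votes >= 3L, nr, nc)
  mask
}

#' Restrict a mask to its region of interest
#'
#' Clears foreground outside the ROI. All densities computed downstream are
#' normalized by the ROI area, not the full image area.
#'
#' @param mask A [binary_mask()].
#' @param roi Logical matrix of the same size as the mask (defaults to the
#'   ROI already attached to the mask).
#'
#' @return A [binary_mask()] with foreground confined to the ROI and the
#'   ROI attached.
#' @export
apply_roi <- function(mask, roi = mask$roi) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(roi)) abort("no ROI supplied and none attached to the mask")
  roi <- roi_as_logical(roi)
  if (!identical(dim(roi), dim(mask$pixels))) {
    abort("`roi` must match the mask dimensions.")
  }
  if (!any(roi)) abort("ROI is empty")
  mask$pixels <- mask$pixels & roi
  mask$roi <- roi
  mask
}

#' Full binarization chain
#'
#' Convenience wrapper running the flatmount processing chain on a
#' grayscale image: 8-bit conversion, adaptive local-mean thresholding,
#' despeckling, and ROI masking (when an ROI is present).
#'
#' @inheritParams adaptive_threshold
#' @param despeckle Apply [median_despeckle()] after thresholding
#'   (default `TRUE`).
#'
#' @return A [binary_mask()].
#' @export
binarize <- function(image, window_px = 51L, offset = 10, despeckle = TRUE) {
  mask <- adaptive_threshold(to_8bit(image), window_px = window_px,
                             offset = offset)
  if (despeckle) mask <- median_despeckle(mask)
  if (!is.null(mask$roi)) mask <- apply_roi(mask)
  mask
}
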