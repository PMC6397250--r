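#' Vascular area fraction
#'
#' Ratio of foreground (vessel) pixels inside the region of interest to the
#' total number of ROI pixels. With no ROI attached, the whole image is the
#' ROI.
#'
#' @param mask A [binary_mask()].
#' @return Area fraction in `[0, 1]`.
#' @export
area_fraction <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  roi <- mask$roi %||% matrix(TRUE, nrow(mask$pixels), ncol(mask$pixels))
  n_roi <- sum(roi)
  if (n_roi == 0L) abort("ROI is empty")
  sum(mask$pixels & roi) / n_roi
}

#' ROI area in square millimetres
#'
#' @param mask A [binary_mask()] (its attached ROI, or the full image).
#' @return Area in mm^2.
#' @export
roi_area_mm2 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  roi <- mask$roi %||% matrix(TRUE, nrow(mask$pixels), ncol(mask$pixels))
  sum(roi) * (mask$pixel_size / 1000)^2
}

#' Vessel length density
#'
#' Total skeleton length, converted to millimetres, per square millimetre
#' of ROI.
#'
#' @param graph A [build_graph()] result.
#' @param roi_area ROI area in mm^2 (see [roi_area_mm2()]).
#' @return Length density in mm/mm^2.
#' @export
length_density <- function(graph, roi_area) {
  if (!is.finite(roi_area) || roi_area <= 0) abort("`roi_area` must be > 0")
  (total_length(graph) / 1000) / roi_area
}

#' Branch-point density
#'
#' Number of junction clusters per square millimetre of ROI.
#'
#' @inheritParams length_density
#' @return Branch density in 1/mm^2.
#' @export
branch_density <- function(graph, roi_area) {
  if (!is.finite(roi_area) || roi_area <= 0) abort("`roi_area` must be > 0")
  count_branch_points(graph) / roi_area
}

#' Nearest-neighbour distance between vessel segments
#'
#' Treats each positive-length skeleton segment as a particle located at
#' its centroid and computes, for each segment, the minimal Euclidean
#' distance to any other segment centroid. The mean measures capillary
#' spacing; the sample standard deviation (n - 1 denominator) measures the
#' regularity of the network.
#'
#' @param graph A [build_graph()] result with at least 2 positive-length
#'   segments.
#' @return A named list with `nnd_mean_um`, `nnd_sd_um`, `n` and the
#'   per-segment distances `d_um`.
#' @export
nnd <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  seg <- nnd_segments(graph)
  if (nrow(seg) < 2L) {
    abort("NND is undefined for fewer than 2 positive-length segments")
  }
  d <- nnd_from_centroids(cbind(seg$centroid_x_um, seg$centroid_y_um))
  list(nnd_mean_um = mean(d), nnd_sd_um = stats::sd(d), n = length(d), d_um = d)
}

# segments that act as NND particles: positive length, and not the
# internal wiring of a junction cluster
nnd_segments <- function(graph) {
  dplyr::filter(graph$segments, .data$length_um > 0,
                .data$kind != "cluster_internal")
}

# per-point nearest-neighbour distances, blockwise to bound memory
nnd_from_centroids <- function(xy) {
  n <- nrow(xy)
  out <- numeric(n)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    dx <- outer(xy[rows, 1], xy[, 1], `-`)
    dy <- outer(xy[rows, 2], xy[, 2], `-`)
    d2 <- dx * dx + dy * dy
    d2[cbind(seq_along(rows), rows)] <- Inf
    out[rows] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Radial vascular outgrowth
#'
#' Ratio of the radial extent of the vessel front to the radial extent of
#' the region of interest, both measured from the network centre (the
#' optic-nerve-head analogue): maximum Euclidean distance from the centre
#' to any foreground pixel, divided by the maximum distance from the centre
#' to any ROI pixel, clamped to `[0, 1]`.
#'
#' @param mask A [binary_mask()] with foreground inside the ROI.
#' @param center `(x, y)` pixel coordinates of the network centre; defaults
#'   to the centre attached to the mask.
#' @param roi Logical ROI matrix; defaults to the ROI attached to the mask.
#' @return Outgrowth fraction in `[0, 1]`.
#' @export
outgrowth <- function(mask, center = mask$center, roi = mask$roi) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(center)) {
    abort("outgrowth needs a network centre: supply `center = c(x, y)`")
  }
  roi <- roi %||% matrix(TRUE, nrow(mask$pixels), ncol(mask$pixels))
  if (!any(roi)) abort("ROI is empty")
  max_r <- function(sel) {
    idx <- which(sel)
    if (length(idx) == 0L) return(0)
    nr <- nrow(mask$pixels)
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    sqrt(max((cc - center[1])^2 + (r - center[2])^2))
  }
  denom <- max_r(roi)
  if (denom == 0) return(0)
  min(1, max_r(mask$pixels & roi) / denom)
}

#' Tiled area-fraction heatmap
#'
#' Partitions the bounding box of the ROI into square tiles of side
#' `tile_um` and computes the vascular area fraction within each tile.
#' Tiles with fewer than half of their pixels inside the ROI are marked
#' missing, which avoids artificially low fractions along the ROI border.
#' A 20-bin histogram of the valid tile values over `[0, 1]` summarises the
#' spatial distribution of vessel coverage.
#'
#' @param mask A [binary_mask()].
#' @param tile_um Tile side in micrometres (must exceed the pixel size).
#' @return An object of class `vessel_heatmap`: list with `tiles` (tibble:
#'   `tile_row`, `tile_col`, `x0_um`, `y0_um`, `area_fraction`, `valid`),
#'   `histogram` (tibble: `bin`, `lower`, `upper`, `count`), `tile_um`,
#'   `pixel_size`.
#' @export
vessel_heatmap <- function(mask, tile_um) {
  stopifnot(inherits(mask, "binary_mask"))
  psz <- mask$pixel_size
  if (!is.finite(tile_um) || tile_um <= psz) {
    abort("`tile_um` must exceed the pixel size")
  }
  roi <- mask$roi %||% matrix(TRUE, nrow(mask$pixels), ncol(mask$pixels))
  if (!any(roi)) abort("ROI is empty")
  rws <- range(which(rowSums(roi) > 0))
  cls <- range(which(colSums(roi) > 0))
  side <- max(1L, as.integer(round(tile_um / psz)))
  bh <- rws[2] - rws[1] + 1L
  bw <- cls[2] - cls[1] + 1L
  if (side >= max(bh, bw)) {
    warn("tile larger than the ROI: returning a single tile")
  }
  nty <- max(1L, ceiling(bh / side))
  ntx <- max(1L, ceiling(bw / side))
  grid <- tidyr::expand_grid(tile_row = seq_len(nty), tile_col = seq_len(ntx))
  vals <- purrr::pmap_dfr(grid, function(tile_row, tile_col) {
    r0 <- rws[1] + (tile_row - 1L) * side
    c0 <- cls[1] + (tile_col - 1L) * side
    rs <- r0:min(r0 + side - 1L, rws[2])
    cs <- c0:min(c0 + side - 1L, cls[2])
    in_roi <- roi[rs, cs, drop = FALSE]
    n_in <- sum(in_roi)
    valid <- n_in >= 0.5 * length(in_roi)
    frac <- if (valid && n_in > 0L) {
      sum(mask$pixels[rs, cs, drop = FALSE] & in_roi) / n_in
    } else {
      NA_real_
    }
    tibble::tibble(tile_row, tile_col,
                   x0_um = (c0 - 1) * psz, y0_um = (r0 - 1) * psz,
                   area_fraction = frac, valid = valid && n_in > 0L)
  })
  v <- vals$area_fraction[vals$valid]
  v_bin <- pmin(floor(v * 20) + 1L, 20L)
  bin_counts <- as.integer(tabulate(v_bin, nbins = 20L))
  hist_tbl <- tibble::tibble(
    bin = 1:20,
    lower = (0:19) / 20,
    upper = (1:20) / 20,
    count = bin_counts
  )
  structure(list(tiles = vals, histogram = hist_tbl, tile_um = tile_um,
                 pixel_size = psz),
            class = "vessel_heatmap")
}

#' @export
print.vessel_heatmap <- function(x, ...) {
  cat(sprintf("<vessel_heatmap> %d tiles (%d valid), tile %.0f um\n",
              nrow(x$tiles), sum(x$tiles$valid), x$tile_um))
  invisible(x)
}

#' @method tidy vessel_heatmap
#' @export
tidy.vessel_heatmap <- function(x, ...) {
  x$tiles
}

#' All six vascular parameters for one binary mask
#'
#' Runs skeletonization and graph extraction on the mask and returns the
#' full parameter set as a one-row tibble with unit-suffixed columns:
#' area fraction, length density (mm/mm^2), branch density (1/mm^2), NND
#' mean and standard deviation (um), and radial outgrowth (when a centre
#' point is available). NND is `NA` when the mask yields fewer than two
#' positive-length segments.
#'
#' @param mask A [binary_mask()] (already ROI-masked; see [apply_roi()]).
#' @param center Optional `(x, y)` centre in pixel coordinates for the
#'   outgrowth measure; defaults to the mask's attached centre.
#' @param label Optional label stored in the first column (image, plexus or
#'   timepoint identifier).
#'
#' @return A one-row tibble.
#' @export
morphometry <- function(mask, center = mask$center, label = NA_character_) {
  stopifnot(inherits(mask, "binary_mask"))
  graph <- build_graph(skeletonize(mask))
  area <- roi_area_mm2(mask)
  nnd_vals <- if (nrow(nnd_segments(graph)) >= 2L) {
    v <- nnd(graph)
    c(v$nnd_mean_um, v$nnd_sd_um)
  } else {
    c(NA_real_, NA_real_)
  }
  og <- if (!is.null(center)) outgrowth(mask, center = center) else NA_real_
  tibble::tibble(
    label = label,
    area_fraction = area_fraction(mask),
    length_density_mm_per_mm2 = length_density(graph, area),
    branch_density_per_mm2 = branch_density(graph, area),
    nnd_mean_um = nnd_vals[1],
    nnd_sd_um = nnd_vals[2],
    outgrowth = og,
    roi_area_mm2 = area,
    n_segments = nrow(graph$segments)
  )
}
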