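#' Maximum projection of a z-stack
#'
#' Per-pixel maximum over z ("collapsed" whole-retina view); calibration,
#' ROI and centre point are preserved.
#'
#' @param stack A 3D [calibrated_image()] ordered `(z, y, x)`.
#' @return A 2D [calibrated_image()].
#' @export
collapse_stack <- function(stack) {
  stopifnot(inherits(stack, "calibrated_image"))
  d <- dim(stack$pixels)
  if (length(d) == 2L) return(stack)
  if (d[1] < 1L) abort("stack has no slices")
  proj <- apply(stack$pixels, c(2L, 3L), max)
  calibrated_image(proj, stack$pixel_size[2], roi = stack$roi,
                   center = stack$center, metadata = stack$metadata)
}

#' Separate the three vascular plexuses of a z-stack
#'
#' Splits a high z-resolution stack into primary, intermediate and deep
#' plexus projections. In `"auto"` mode the per-slice vessel content is
#' measured (foreground count after adaptive thresholding of the 8-bit
#' stack), smoothed with a 3-slice moving average, and the three highest
#' local maxima above 10\% of the peak count are taken as the plexus
#' depths; the stack is cut at the count minima between adjacent peaks.
#' If a different number of qualifying peaks is found, an error asks the
#' caller to supply `"manual"` z-ranges. Each plexus is then
#' maximum-projected over its z-range; the three ranges partition the
#' stack without overlap.
#'
#' @param stack A 3D [calibrated_image()].
#' @param mode `"auto"` or `"manual"`.
#' @param z_ranges For `"manual"`: list of three `c(from, to)` slice index
#'   pairs (1-based, inclusive).
#' @param window_px,offset Thresholding parameters for the per-slice
#'   vessel-content profile (auto mode).
#' @param smooth_window Moving-average window in slices (default 3).
#' @return A named list of three 2D [calibrated_image()] projections
#'   (`primary`, `intermediate`, `deep`), with the slice ranges in each
#'   projection's metadata.
#' @export
separate_plexuses <- function(stack, mode = c("auto", "manual"),
                              z_ranges = NULL, window_px = 51L, offset = 10,
                              smooth_window = 3L) {
  stopifnot(inherits(stack, "calibrated_image"))
  mode <- match.arg(mode)
  d <- dim(stack$pixels)
  if (length(d) != 3L) abort("`stack` must be a 3D z-stack")
  nz <- d[1]
  if (mode == "auto") {
    eight <- to_8bit(stack)
    counts <- vapply(seq_len(nz), function(z) {
      sl <- calibrated_image(eight$pixels[z, , ], stack$pixel_size[2])
      sum(adaptive_threshold(sl, window_px = window_px,
                             offset = offset)$pixels)
    }, numeric(1))
    sm <- moving_average(counts, smooth_window)
    peaks <- local_maxima(sm)
    peaks <- peaks[sm[peaks] >= 0.1 * max(sm)]
    # a flat-topped z-band can put two qualifying maxima inside one band;
    # keep only the highest peak within any 8-slice neighbourhood
    if (length(peaks) > 1L) {
      keep <- integer(0)
      for (pk in peaks[order(-sm[peaks])]) {
        if (all(abs(pk - keep) >= 8L)) keep <- c(keep, pk)
      }
      peaks <- sort(keep)
    }
    if (length(peaks) != 3L) {
      abort(sprintf(paste0(
        "auto plexus separation found %d peak(s), not 3; ",
        "supply manual z-ranges"), length(peaks)))
    }
    peaks <- sort(peaks)
    valley <- function(a, b) {
      if (b - a < 2L) return(a)
      a + which.min(sm[(a + 1L):(b - 1L)])
    }
    cut1 <- valley(peaks[1], peaks[2])
    cut2 <- valley(peaks[2], peaks[3])
    z_ranges <- list(c(1L, cut1), c(cut1 + 1L, cut2), c(cut2 + 1L, nz))
  } else {
    if (is.null(z_ranges) || length(z_ranges) != 3L) {
      abort("manual mode needs `z_ranges`: a list of three c(from, to) pairs")
    }
    z_ranges <- lapply(z_ranges, function(r) as.integer(r))
    ok <- all(vapply(z_ranges, function(r) {
      length(r) == 2L && r[1] >= 1L && r[2] <= nz && r[1] <= r[2]
    }, logical(1)))
    if (!ok) abort("each z-range must be c(from, to) within the stack")
    starts <- vapply(z_ranges, `[`, integer(1), 1L)
    ends <- vapply(z_ranges, `[`, integer(1), 2L)
    if (any(starts[-1] <= ends[-3])) {
      abort("z-ranges must not overlap and must be in increasing order")
    }
  }
  names <- c("primary", "intermediate", "deep")
  out <- lapply(1:3, function(i) {
    r <- z_ranges[[i]]
    sub <- stack$pixels[r[1]:r[2], , , drop = FALSE]
    proj <- apply(sub, c(2L, 3L), max)
    calibrated_image(proj, stack$pixel_size[2], roi = stack$roi,
                     center = stack$center,
                     metadata = list(plexus = names[i], z_range = r))
  })
  setNames(out, names)
}

moving_average <- function(x, w) {
  r <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  vapply(seq_len(n), function(i) mean(xp[i:(i + 2L * r)]), numeric(1))
}

# local maxima that dominate a +/- half_window neighbourhood, so ripples
# within one z-band do not register as separate peaks
local_maxima <- function(x, half_window = 3L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_window)
    hi <- min(n, i + half_window)
    w <- x[lo:hi]
    x[i] == max(w) && (lo - 1L + which.max(w)) == i
  }, logical(1)))
}

#' Percent deviation of single-plexus from whole-retina values
#'
#' `(single - whole) / whole * 100`, rounded half-away-from-zero to two
#' decimals, matching the tabular convention for comparing aggregated
#' single-plexus values with the collapsed whole-retina analysis.
#'
#' @param whole Whole-retina (collapsed) value; must be non-zero.
#' @param single Aggregated single-plexus value.
#' @return Percent deviation (vectorized).
#' @export
percent_deviation <- function(whole, single) {
  if (any(whole == 0)) abort("percent deviation is undefined for whole = 0")
  round_half_away((single - whole) / whole * 100, 2)
}

#' Percent change between two timepoints (reduction positive)
#'
#' `(early - late) / early * 100`, rounded half-away-from-zero to one
#' decimal: the convention used to report developmental remodeling, where
#' a positive value is a reduction from the early to the late timepoint.
#'
#' @param early Value at the earlier timepoint; must be non-zero.
#' @param late Value at the later timepoint.
#' @return Percent reduction (vectorized).
#' @export
percent_change <- function(early, late) {
  if (any(early == 0)) abort("percent change is undefined for early = 0")
  round_half_away((early - late) / early * 100, 1)
}

#' Whole-retina versus single-plexus analysis of a z-stack
#'
#' Runs the full pipeline twice on one stack: (i) collapsed analysis of
#' the all-slice maximum projection, and (ii) single-plexus analysis of
#' the three per-plexus projections (see [separate_plexuses()]). The
#' per-plexus results are combined into one aggregated record: length and
#' branch densities are summed (vessels in different layers are distinct
#' vessels), while area fraction, NND mean/SD and outgrowth are averaged
#' across the plexuses. Percent deviations of the aggregated values from
#' the collapsed values quantify how much a collapsed analysis
#' underestimates the three-dimensional network.
#'
#' @param stack A 3D [calibrated_image()], with ROI/centre attached if
#'   available.
#' @param mode,z_ranges Passed to [separate_plexuses()].
#' @param window_px,offset Binarization parameters (see
#'   [adaptive_threshold()]).
#' @param despeckle Apply [median_despeckle()] (default `TRUE`).
#'
#' @return An object of class `plexus_comparison`: list with `per_plexus`
#'   (3-row tibble), `aggregated` and `collapsed` (1-row tibbles), and
#'   `deviations` (tibble: `parameter`, `whole`, `single`,
#'   `deviation_pct`).
#' @export
analyze_plexuses <- function(stack, mode = c("auto", "manual"),
                             z_ranges = NULL, window_px = 51L, offset = 10,
                             despeckle = TRUE) {
  stopifnot(inherits(stack, "calibrated_image"))
  mode <- match.arg(mode)
  run_one <- function(img, label) {
    mask <- binarize(img, window_px = window_px, offset = offset,
                     despeckle = despeckle)
    morphometry(mask, center = img$center, label = label)
  }
  collapsed <- with_stage("collapsed projection",
                          run_one(collapse_stack(stack), "whole_retina"))
  plex <- with_stage("plexus separation",
                     separate_plexuses(stack, mode = mode,
                                       z_ranges = z_ranges,
                                       window_px = window_px,
                                       offset = offset))
  per_plexus <- purrr::imap_dfr(plex, function(img, nm) {
    with_stage(paste("plexus", nm), run_one(img, nm))
  })
  aggregated <- tibble::tibble(
    label = "single_plexus_aggregated",
    area_fraction = mean(per_plexus$area_fraction),
    length_density_mm_per_mm2 = sum(per_plexus$length_density_mm_per_mm2),
    branch_density_per_mm2 = sum(per_plexus$branch_density_per_mm2),
    nnd_mean_um = mean(per_plexus$nnd_mean_um),
    nnd_sd_um = mean(per_plexus$nnd_sd_um),
    outgrowth = mean(per_plexus$outgrowth),
    roi_area_mm2 = per_plexus$roi_area_mm2[1],
    n_segments = sum(per_plexus$n_segments)
  )
  params <- c("outgrowth", "area_fraction", "length_density_mm_per_mm2",
              "branch_density_per_mm2", "nnd_mean_um", "nnd_sd_um")
  whole <- as.numeric(collapsed[1, params])
  single <- as.numeric(aggregated[1, params])
  dev <- ifelse(is.finite(whole) & whole != 0 & is.finite(single),
                round_half_away((single - whole) / whole * 100, 2),
                NA_real_)
  structure(
    list(per_plexus = per_plexus, aggregated = aggregated,
         collapsed = collapsed,
         deviations = tibble::tibble(parameter = params, whole = whole,
                                     single = single, deviation_pct = dev)),
    class = "plexus_comparison"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)), parent = e)
  })
}

#' @export
print.plexus_comparison <- function(x, ...) {
  cat("<plexus_comparison>\n")
  cat("  per-plexus results:\n")
  print(x$per_plexus)
  cat("  deviations (single vs whole):\n")
  print(x$deviations)
  invisible(x)
}

#' @method tidy plexus_comparison
#' @export
tidy.plexus_comparison <- function(x, ...) {
  dplyr::bind_rows(x$per_plexus, x$aggregated, x$collapsed)
}

#' @method glance plexus_comparison
#' @export
glance.plexus_comparison <- function(x, ...) {
  d <- x$deviations
  tibble::tibble(
    length_deviation_pct =
      d$deviation_pct[d$parameter == "length_density_mm_per_mm2"],
    branch_deviation_pct =
      d$deviation_pct[d$parameter == "branch_density_per_mm2"],
    area_fraction_deviation_pct =
      d$deviation_pct[d$parameter == "area_fraction"],
    nnd_deviation_pct = d$deviation_pct[d$parameter == "nnd_mean_um"],
    n_plexuses = nrow(x$per_plexus)
  )
}
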