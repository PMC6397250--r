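#' Read a TIFF image or z-stack
#'
#' Reads single- and multi-page grayscale TIFFs (8/16-bit) into a
#' [calibrated_image()]. Multi-page files become 3D stacks ordered
#' `(z, y, x)`. Calibration is taken from the `pixel_size` argument,
#' overriding any file metadata.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size Micrometres per pixel: one value for 2D, three
#'   `(z, y, x)` for stacks.
#' @param roi Optional logical ROI matrix, or path to a mask TIFF.
#' @param center Optional `(x, y)` centre in pixel coordinates.
#' @return A [calibrated_image()].
#' @export
read_stack <- function(path, pixel_size, roi = NULL, center = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      abort(sprintf("cannot read '%s' as TIFF: %s", path,
                                    conditionMessage(e)))
                    })
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p  # drop extra channels
  })
  px <- if (length(pages) == 1L) {
    pages[[1]]
  } else {
    arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    arr
  }
  if (is.character(roi)) {
    roi <- tiff::readTIFF(roi, as.is = TRUE)
    if (length(dim(roi)) == 3L) roi <- roi[, , 1]
    roi <- roi != 0
  }
  calibrated_image(px, pixel_size, roi = roi, center = center,
                   metadata = list(source = path))
}

#' Write a calibrated image as TIFF
#'
#' 2D images become single-page, stacks multi-page TIFFs. Intensities are
#' stored at the requested bit depth; values are assumed to lie in
#' `[0, 255]` (8-bit convention) and are rescaled accordingly.
#'
#' @param image A [calibrated_image()] or [binary_mask()].
#' @param path Output path.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, bits = 8L) {
  px <- if (inherits(image, "binary_mask")) image$pixels * 255 else image$pixels
  stopifnot(bits %in% c(8L, 16L))
  scale <- function(m) pmin(pmax(m / 255, 0), 1)
  if (length(dim(px)) == 2L) {
    tiff::writeTIFF(scale(px), path, bits.per.sample = bits)
  } else {
    slices <- lapply(seq_len(dim(px)[1]), function(z) scale(px[z, , ]))
    tiff::writeTIFF(slices, path, bits.per.sample = bits)
  }
  invisible(path)
}

#' Write a synthetic network and its ground truth
#'
#' Writes the rasterized image (TIFF) together with a JSON sidecar holding
#' the generator parameters, the node and edge tables (with polylines) and
#' the ground-truth totals, so downstream measurements can be validated
#' without rerunning the generator.
#'
#' @param synth A [synth_image()] result.
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Named character vector of the files written.
#' @export
write_synthetic <- function(synth, dir, name = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  write_tiff(synth$image, tif)
  truth <- list(
    params = unclass(synth$params),
    layers = setNames(lapply(synth$graphs, function(g) {
      list(nodes = g$nodes,
           edges = dplyr::mutate(
             dplyr::select(g$edges, -"polyline"),
             polyline = lapply(g$edges$polyline, function(p) {
               list(x_um = p[, 1], y_um = p[, 2])
             })),
           center_um = g$center,
           total_length_um = network_total_length(g),
           n_junctions = network_junction_count(g),
           outgrowth = network_outgrowth(g))
    }), paste0("layer", seq_along(synth$graphs)))
  )
  js <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  c(image = tif, truth = js)
}

#' Default analysis configuration
#'
#' @return Named list of the tunable pipeline parameters: threshold window
#'   and offset, despeckle toggle, heatmap tile size, plexus separation
#'   mode and smoothing window, and rounding conventions.
#' @export
default_config <- function() {
  list(
    window_px = 51L,
    offset = 10,
    despeckle = TRUE,
    tile_um = 100,
    separation_mode = "auto",
    smooth_window = 3L,
    z_ranges = NULL,
    deviation_digits = 2L,
    percent_change_digits = 1L
  )
}

#' Read a YAML analysis configuration
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A complete configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  extra <- setdiff(names(user), names(cfg))
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  utils::modifyList(cfg, user)
}

#' Write analysis results, heatmaps and provenance to a directory
#'
#' Canonical on-disk form of a run: a tidy CSV of morphometry rows (one
#' per image/plexus, unit-suffixed columns), a JSON mirror of any plexus
#' comparison, the heatmap tile grid (CSV + float TIFF) and histogram CSV,
#' the resolved configuration (YAML), and a plain-text log. Returns a run
#' record listing every file written with its checksum; identical runs
#' produce identical checksums.
#'
#' @param results Tibble of [morphometry()] rows (possibly empty).
#' @param out_dir Output directory (created if needed).
#' @param comparison Optional [analyze_plexuses()] result.
#' @param heatmap Optional [vessel_heatmap()] result.
#' @param config Optional configuration list (see [read_config()]).
#' @param log_lines Optional character vector of log messages.
#' @return A `run_record`: tibble with `file`, `bytes`, `md5`.
#' @export
write_results <- function(results, out_dir, comparison = NULL,
                          heatmap = NULL, config = NULL, log_lines = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  csv <- file.path(out_dir, "morphometry.csv")
  write.csv(as.data.frame(results), csv, row.names = FALSE)
  add(csv)

  if (!is.null(comparison)) {
    js <- file.path(out_dir, "plexus_comparison.json")
    jsonlite::write_json(
      list(per_plexus = comparison$per_plexus,
           aggregated = comparison$aggregated,
           collapsed = comparison$collapsed,
           deviations = comparison$deviations),
      js, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    add(js)
  }
  if (!is.null(heatmap)) {
    hc <- file.path(out_dir, "heatmap_tiles.csv")
    write.csv(as.data.frame(heatmap$tiles), hc, row.names = FALSE)
    add(hc)
    hh <- file.path(out_dir, "heatmap_histogram.csv")
    write.csv(as.data.frame(heatmap$histogram), hh, row.names = FALSE)
    add(hh)
    ht <- file.path(out_dir, "heatmap.tif")
    grid <- heatmap_grid(heatmap)
    grid[is.na(grid)] <- 0
    tiff::writeTIFF(grid, ht, bits.per.sample = 32L, reduce = TRUE)
    add(ht)
  }
  cfg <- config %||% default_config()
  cy <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], cy)
  add(cy)

  lg <- file.path(out_dir, "run.log")
  writeLines(c(sprintf("vesselmetrics %s",
                       as.character(utils::packageVersion("vesselmetrics"))),
               sprintf("results: %d row(s)", nrow(results)),
               log_lines %||% character(0)), lg)
  add(lg)

  structure(tibble::tibble(
    file = files,
    bytes = as.numeric(file.size(files)),
    md5 = as.character(tools::md5sum(files))
  ), class = c("run_record", class(tibble::tibble())))
}

#' Heatmap tile grid as a matrix
#'
#' @param heatmap A [vessel_heatmap()] result.
#' @return Matrix of tile area fractions (`NA` where invalid).
#' @export
heatmap_grid <- function(heatmap) {
  stopifnot(inherits(heatmap, "vessel_heatmap"))
  t_ <- heatmap$tiles
  g <- matrix(NA_real_, max(t_$tile_row), max(t_$tile_col))
  g[cbind(t_$tile_row, t_$tile_col)] <- t_$area_fraction
  g
}

#' Re-read a results CSV written by [write_results()]
#'
#' @param out_dir Directory written by [write_results()].
#' @return Tibble of morphometry rows at full precision.
#' @export
read_results <- function(out_dir) {
  tibble::as_tibble(read.csv(file.path(out_dir, "morphometry.csv")))
}
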