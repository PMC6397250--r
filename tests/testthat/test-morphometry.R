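test_that("area fraction is the foreground/ROI pixel ratio", {
  full <- binary_mask(matrix(TRUE, 10, 10), 1)
  expect_equal(area_fraction(full), 1)
  expect_equal(area_fraction(binary_mask(matrix(FALSE, 10, 10), 1)), 0)

  m <- matrix(FALSE, 100, 100); m[, 1:50] <- TRUE
  expect_equal(area_fraction(binary_mask(m, 1)), 0.5)
})

test_that("length and branch densities normalize by ROI area", {
  # 101-px line at 100 um/px: 10 mm of vessel
  m <- matrix(FALSE, 5, 103); m[3, 2:102] <- TRUE
  g <- build_graph(binary_mask(m, 100))
  expect_equal(length_density(g, roi_area = 10), 1)
  expect_equal(length_density(g, roi_area = 1), 10)
  expect_equal(branch_density(g, roi_area = 1), 0)

  gy <- build_graph(y_mask())
  expect_equal(branch_density(gy, roi_area = 0.01), 100)
  expect_error(length_density(gy, 0), "> 0")
})

test_that("NND arithmetic matches the brute-force pairwise oracle", {
  # two parallel segments, vertical offset 15, aligned midpoints
  m <- matrix(FALSE, 40, 40); m[10, 10:30] <- TRUE; m[25, 10:30] <- TRUE
  v <- nnd(build_graph(binary_mask(m, 1)))
  expect_equal(v$nnd_mean_um, 15)
  expect_equal(v$nnd_sd_um, 0)

  # regular grid of parallel segments, constant spacing
  m <- matrix(FALSE, 64, 40)
  for (r in seq(8, 56, by = 8)) m[r, 8:32] <- TRUE
  v <- nnd(build_graph(binary_mask(m, 1)))
  expect_equal(v$nnd_mean_um, 8)
  expect_equal(v$nnd_sd_um, 0)

  # three centroids on a line: distances {10, 10, 15}
  g <- graph_from_centroids(cbind(c(0, 10, 25), c(0, 0, 0)))
  v <- nnd(g)
  expect_equal(v$d_um, c(10, 10, 15))
  expect_equal(v$nnd_mean_um, 35 / 3)
  expect_equal(v$nnd_sd_um, sd(c(10, 10, 15)))

  expect_error(nnd(graph_from_centroids(cbind(1, 1))), "fewer than 2")
})

test_that("NND is invariant under translation and rotation", {
  set.seed(11)
  xy <- matrix(runif(40, 0, 100), ncol = 2)
  base <- nnd(graph_from_centroids(xy))
  shifted <- nnd(graph_from_centroids(xy + 37.5))
  th <- 0.7
  rot <- xy %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  rotated <- nnd(graph_from_centroids(rot))
  expect_equal(shifted$nnd_mean_um, base$nnd_mean_um)
  expect_equal(shifted$nnd_sd_um, base$nnd_sd_um)
  expect_equal(rotated$nnd_mean_um, base$nnd_mean_um)
  expect_equal(rotated$nnd_sd_um, base$nnd_sd_um)
})

test_that("outgrowth is the vessel-front radius over the ROI radius", {
  roi <- disk_roi(c(201, 201), c(101, 101), 100)
  fg <- disk_roi(c(201, 201), c(101, 101), 50)
  mask <- binary_mask(fg, 1, roi = roi)
  expect_equal(outgrowth(mask, center = c(101, 101)), 0.5, tolerance = 0.02)

  filled <- binary_mask(roi, 1, roi = roi)
  expect_equal(outgrowth(filled, center = c(101, 101)), 1)

  expect_error(outgrowth(mask), "centre|center")
})

test_that("heatmap tiles and histogram count vessel coverage", {
  m <- matrix(FALSE, 200, 200); m[1:100, 1:100] <- TRUE
  hm <- vessel_heatmap(binary_mask(m, 1), tile_um = 100)
  expect_equal(sort(hm$tiles$area_fraction), c(0, 0, 0, 1))
  expect_equal(hm$histogram$count[1], 3L)
  expect_equal(hm$histogram$count[20], 1L)
  expect_equal(sum(hm$histogram$count), sum(hm$tiles$valid))

  # empty mask: all tiles zero
  hm0 <- vessel_heatmap(binary_mask(matrix(FALSE, 120, 120), 1), tile_um = 40)
  expect_true(all(hm0$tiles$area_fraction == 0))

  # uniform half-density checkerboard: every tile at 0.5
  cb <- outer(1:100, 1:100, function(r, c) (r + c) %% 2 == 0)
  hmc <- vessel_heatmap(binary_mask(cb, 1), tile_um = 20)
  expect_true(all(abs(hmc$tiles$area_fraction - 0.5) < 0.01))

  expect_warning(vessel_heatmap(binary_mask(matrix(TRUE, 30, 30), 1), 50),
                 "single tile")
})

test_that("border tiles below 50% ROI coverage are marked missing", {
  roi <- disk_roi(c(100, 100), c(50, 50), 48)
  mask <- binary_mask(matrix(TRUE, 100, 100), 1, roi = roi)
  hm <- vessel_heatmap(apply_roi(mask), tile_um = 24)
  corner <- dplyr::filter(hm$tiles, tile_row == 1, tile_col == 1)
  expect_false(corner$valid)
  centre <- dplyr::filter(hm$tiles, tile_row == 2, tile_col == 2)
  expect_true(centre$valid)
  expect_equal(centre$area_fraction, 1)
})

test_that("morphometry returns the six parameters in one tidy row", {
  p <- synth_params(field_size = 250, seed = 41, branch_rate = 0.015,
                    noise_sd = 0, illumination_gradient = 0)
  g <- generate_network(p)
  mask <- rasterize_mask(g, 1)
  mask$roi <- disk_roi(dim(mask$pixels), mask$center, 120)
  mask <- apply_roi(mask)
  row <- morphometry(mask, label = "demo")
  expect_s3_class(row, "tbl_df")
  expect_equal(nrow(row), 1L)
  expect_named(row, c("label", "area_fraction", "length_density_mm_per_mm2",
                      "branch_density_per_mm2", "nnd_mean_um", "nnd_sd_um",
                      "outgrowth", "roi_area_mm2", "n_segments"))
  expect_gt(row$length_density_mm_per_mm2, 0)
  expect_true(row$area_fraction > 0 && row$area_fraction < 1)
  # deterministic function of its inputs
  expect_identical(row, morphometry(mask, label = "demo"))
})
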