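test_that("straight and diagonal lines measure their calibrated length", {
  g <- build_graph(line_mask())
  expect_equal(nrow(g$segments), 1L)
  expect_equal(total_length(g), 10)
  expect_equal(count_branch_points(g), 0L)
  expect_equal(sum(g$pixels$class == "endpoint"), 2L)

  g <- build_graph(diag_mask(11L))
  expect_equal(nrow(g$segments), 1L)
  expect_equal(total_length(g), 10 * sqrt(2))

  # two disjoint lines sum
  m <- matrix(FALSE, 21, 21); m[5, 3:13] <- TRUE; m[15, 3:13] <- TRUE
  expect_equal(total_length(build_graph(binary_mask(m, 1))), 20)

  # empty skeleton
  expect_equal(total_length(build_graph(binary_mask(matrix(FALSE, 5, 5), 1))), 0)
})

test_that("a symmetric Y yields one junction cluster, three segments", {
  g <- build_graph(y_mask())
  expect_equal(count_branch_points(g), 1L)
  expect_equal(sum(g$segments$kind == "path"), 3L)
  expect_equal(sum(g$pixels$class == "endpoint"), 3L)
})

test_that("an X of crossing lines forms a single junction cluster", {
  g <- build_graph(x_mask())
  expect_equal(count_branch_points(g), 1L)
})

test_that("isolated pixels are zero-length segments, not branches", {
  m <- matrix(FALSE, 9, 9); m[2, 2] <- TRUE; m[7, 3:7] <- TRUE
  g <- build_graph(binary_mask(m, 1))
  iso <- dplyr::filter(g$segments, kind == "isolated")
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$length_um, 0)
  expect_equal(count_branch_points(g), 0L)
})

test_that("thinning reduces thick strokes to single centrelines", {
  m <- matrix(FALSE, 30, 70); m[13:17, 10:59] <- TRUE
  g <- build_graph(skeletonize(binary_mask(m, 1)))
  expect_equal(nrow(g$segments), 1L)
  expect_equal(count_branch_points(g), 0L)
  expect_gte(total_length(g), 44)
  expect_lte(total_length(g), 50)

  disk <- skeletonize(binary_mask(disk_roi(c(41, 41), c(21, 21), 15), 1))
  expect_lte(sum(disk$pixels), 5)

  # thick plus: one central junction region, four arms
  m <- matrix(FALSE, 41, 41); m[19:23, 5:37] <- TRUE; m[5:37, 19:23] <- TRUE
  g <- build_graph(skeletonize(binary_mask(m, 1)))
  expect_equal(count_branch_points(g), 1L)
  expect_equal(sum(g$pixels$class == "endpoint"), 4L)
})

test_that("thinning preserves the 8-connected component count", {
  for (seed in 1:6) {
    mask <- blob_mask(seed)
    sk <- skeletonize(mask)
    expect_equal(n_components8(sk$pixels), n_components8(mask$pixels))
  }
})

test_that("total length equals the brute-force adjacent-pair sum", {
  for (seed in 1:8) {
    sk <- skeletonize(blob_mask(seed, n = 64L))
    g <- build_graph(sk)
    expect_equal(total_length(g), pair_sum_length(sk$pixels))
  }
  # and on hand-built skeletons
  for (mk in list(line_mask(), diag_mask(9L), y_mask(), x_mask())) {
    expect_equal(total_length(build_graph(mk)), pair_sum_length(mk$pixels))
  }
})

test_that("doubling pixel size doubles length and keeps branch count", {
  mk <- y_mask()
  g1 <- build_graph(mk)
  mk2 <- mk; mk2$pixel_size <- 2
  g2 <- build_graph(mk2)
  expect_equal(total_length(g2), 2 * total_length(g1))
  expect_equal(count_branch_points(g2), count_branch_points(g1))
})

test_that("graph extraction is deterministic", {
  mask <- skeletonize(blob_mask(4))
  g1 <- suppressWarnings(build_graph(mask))
  g2 <- suppressWarnings(build_graph(mask))
  expect_identical(g1$segments, g2$segments)
})

test_that("non-thin input triggers a structural warning", {
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  expect_warning(build_graph(binary_mask(m, 1)), "not 1 px")
})

test_that("closed loops are traced as cyclic segments with full length", {
  # diamond ring: every pixel has exactly two (diagonal) neighbours
  m <- matrix(FALSE, 9, 9)
  ring <- rbind(c(3, 5), c(4, 6), c(5, 7), c(6, 6), c(7, 5), c(6, 4),
                c(5, 3), c(4, 4))
  m[ring] <- TRUE
  g <- build_graph(binary_mask(m, 1))
  expect_equal(nrow(g$segments), 1L)
  expect_true(g$segments$closed)
  expect_equal(total_length(g), 8 * sqrt(2))
  expect_equal(total_length(g), pair_sum_length(m))
})
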