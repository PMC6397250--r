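test_that("parameter validation rejects out-of-range settings", {
  expect_error(synth_params(outgrowth_fraction = 1.5), "outgrowth_fraction")
  expect_error(synth_params(anastomosis_probability = -0.1), "anastomosis")
  expect_error(synth_params(branch_rate = -1), "branch_rate")
  expect_error(synth_params(n_layers = 2), "n_layers")
  expect_error(synth_params(layer_z_positions = c(30, 10, 50), n_layers = 3),
               "increasing")
})

test_that("a single tip without branching grows one unbranched vessel", {
  p <- synth_params(field_size = 300, seed = 2, branch_rate = 0,
                    anastomosis_probability = 0, n_initial_tips = 1)
  g <- generate_network(p)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(network_junction_count(g), 0L)
  expect_gt(network_total_length(g), 0)
})

test_that("vessel graphs satisfy their geometric invariants", {
  p <- synth_params(field_size = 400, seed = 13, outgrowth_fraction = 0.5,
                    branch_rate = 0.02)
  g <- generate_network(p)
  # polylines run node to node
  for (i in seq_len(nrow(g$edges))) {
    poly <- g$edges$polyline[[i]]
    a <- g$nodes[g$edges$node_a[i], ]
    b <- g$nodes[g$edges$node_b[i], ]
    expect_equal(unname(poly[1, ]), c(a$x_um, a$y_um))
    expect_equal(unname(poly[nrow(poly), ]), c(b$x_um, b$y_um))
  }
  pts <- do.call(rbind, g$edges$polyline)
  expect_true(all(pts >= 0 & pts <= 400))
  # outgrowth limit: no point beyond half the field radius
  d <- sqrt((pts[, 1] - 200)^2 + (pts[, 2] - 200)^2)
  expect_lte(max(d), 0.5 * 200)
  # total length is the sum of polyline chord lengths
  chord <- sum(vapply(g$edges$polyline, function(p_) {
    sum(sqrt(rowSums(diff(p_)^2)))
  }, numeric(1)))
  expect_equal(network_total_length(g), chord)
  expect_gt(network_total_length(g), 0)
})

test_that("generation is seed-deterministic", {
  p <- synth_params(field_size = 300, seed = 7, branch_rate = 0.02)
  g1 <- generate_network(p)
  g2 <- generate_network(p)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("raising the branch rate does not lose junctions (same seeds)", {
  for (seed in c(4, 9, 14)) {
    lo <- network_junction_count(generate_network(
      synth_params(field_size = 300, seed = seed, branch_rate = 0.004)))
    hi <- network_junction_count(generate_network(
      synth_params(field_size = 300, seed = seed, branch_rate = 0.02)))
    expect_gte(hi, lo)
  }
})

test_that("rasterization matches the analytic stroke oracle exactly", {
  # single horizontal vessel, checked pixel by pixel against the
  # point-to-segment distance computed independently here
  poly <- cbind(c(20, 120), c(60, 60))
  g <- structure(list(
    nodes = tibble::tibble(node_id = 1:2, x_um = poly[, 1], y_um = poly[, 2],
                           degree = c(1L, 1L)),
    edges = tibble::tibble(edge_id = 1L, node_a = 1L, node_b = 2L,
                           radius_um = 2, length_um = 100,
                           polyline = list(poly)),
    center = c(70, 60), field_size = 140), class = "vessel_graph")
  mask <- rasterize_mask(g, pixel_size = 1)
  n <- nrow(mask$pixels)
  oracle <- matrix(FALSE, n, n)
  for (r in seq_len(n)) for (cc in seq_len(n)) {
    x <- cc - 1; y <- r - 1
    t_ <- min(max((x - 20) / 100, 0), 1)
    d2 <- (x - (20 + 100 * t_))^2 + (y - 60)^2
    oracle[r, cc] <- d2 <= 4
  }
  expect_identical(mask$pixels, oracle)
  # 101 columns x 5 rows of stroke plus round caps
  expect_gte(sum(mask$pixels), 505)
  expect_lte(sum(mask$pixels), 525)
})

test_that("an empty network rasterizes to pure background", {
  p <- synth_params(field_size = 100, seed = 1, outgrowth_fraction = 0,
                    n_initial_tips = 1)
  g <- generate_network(p)
  expect_equal(nrow(g$edges), 0L)
  img <- rasterize(g, 1, noise_sd = 5, seed = 3)
  expect_lt(max(img$pixels), 60)  # background plus noise only
})

test_that("binarizing a clean rendering recovers the analytic mask", {
  p <- synth_params(field_size = 250, seed = 21, branch_rate = 0.01,
                    noise_sd = 0, illumination_gradient = 0,
                    vessel_radius_range = c(2, 3))
  g <- generate_network(p)
  truth <- rasterize_mask(g, 1)
  img <- rasterize(g, 1, noise_sd = 0, illumination_gradient = 0)
  rec <- binarize(img, despeckle = FALSE)
  expect_identical(rec$pixels, truth$pixels)
})

test_that("ground-truth totals are invariant under rasterization settings", {
  p <- synth_params(field_size = 250, seed = 8, branch_rate = 0.015)
  g <- generate_network(p)
  before <- network_total_length(g)
  invisible(rasterize(g, pixel_size = 0.8, noise_sd = 4, seed = 1))
  invisible(rasterize(g, pixel_size = 2.5, noise_sd = 0))
  expect_identical(network_total_length(g), before)
})

test_that("sub-pixel strokes are flagged in the image metadata", {
  p <- synth_params(field_size = 150, seed = 3, branch_rate = 0,
                    n_initial_tips = 1, vessel_radius_range = c(0.3, 0.3))
  g <- generate_network(p)
  expect_warning(img <- rasterize(g, pixel_size = 1), "px wide")
  expect_match(img$metadata$warnings, "vanish")
})

test_that("stack rendering puts each layer in its own z-band", {
  p <- synth_params(field_size = 150, seed = 6, branch_rate = 0.01,
                    n_initial_tips = 4)
  graphs <- lapply(0:2, function(i) generate_network(p, seed_offset = i))
  stack <- rasterize_stack(graphs, layer_z = c(10, 30, 50), noise_sd = 0)
  expect_equal(length(dim(stack$pixels)), 3L)
  bright <- apply(stack$pixels > 100, 1, sum)
  # peaks at z = 10, 30, 50 um (slices 11, 31, 51)
  for (zi in c(11, 31, 51)) {
    expect_gt(bright[zi], 0)
    expect_equal(bright[zi], max(bright[max(1, zi - 5):min(61, zi + 5)]))
  }
  # troughs between bands carry no foreground
  expect_equal(bright[21], 0)
  expect_equal(bright[41], 0)

  # an empty layer's band stays background
  empty <- generate_network(synth_params(field_size = 150, seed = 1,
                                         outgrowth_fraction = 0,
                                         n_initial_tips = 1))
  stack2 <- rasterize_stack(list(graphs[[1]], empty, graphs[[3]]),
                            layer_z = c(10, 30, 50), noise_sd = 0)
  expect_equal(sum(stack2$pixels[27:35, , ] > 100), 0)

  expect_warning(rasterize_stack(graphs, layer_z = c(10, 14, 50)), "overlap")
})

test_that("synthetic images are bit-identical for identical parameters", {
  p <- synth_params(field_size = 250, seed = 12, branch_rate = 0.02,
                    noise_sd = 3, illumination_gradient = 0.1)
  s1 <- synth_image(p)
  s2 <- synth_image(p)
  expect_identical(s1$image$pixels, s2$image$pixels)
})
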