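# shared 3-layer fixture: three different networks, well-separated bands
make_stack <- function(seed = 6, field = 200, rate = 0.015, noise = 0) {
  p <- synth_params(field_size = field, seed = seed, branch_rate = rate,
                    n_initial_tips = 6)
  graphs <- lapply(0:2, function(i) generate_network(p, seed_offset = i * 101L))
  stack <- rasterize_stack(graphs, layer_z = c(10, 30, 50), noise_sd = noise,
                           seed = seed + 1)
  list(stack = stack, graphs = graphs)
}

test_that("maximum projection collapses a stack per pixel", {
  fx <- make_stack()
  proj <- collapse_stack(fx$stack)
  expect_equal(dim(proj$pixels), dim(fx$stack$pixels)[2:3])
  expect_equal(proj$pixels, apply(fx$stack$pixels, c(2, 3), max))
  # single-slice stack: identity
  one <- calibrated_image(array(fx$stack$pixels[1, , ],
                                c(1, dim(fx$stack$pixels)[2:3])), c(1, 1, 1))
  expect_equal(collapse_stack(one)$pixels, fx$stack$pixels[1, , ])
})

test_that("the collapsed projection is the union of the layer masks", {
  fx <- make_stack(noise = 0)
  proj <- collapse_stack(fx$stack)
  rec <- binarize(proj, despeckle = FALSE)
  union <- Reduce(`|`, lapply(fx$graphs, function(g) rasterize_mask(g, 1)$pixels))
  expect_identical(rec$pixels, union)
})

test_that("auto plexus separation finds the three layer bands", {
  fx <- make_stack(noise = 2)
  plex <- separate_plexuses(fx$stack, mode = "auto")
  expect_named(plex, c("primary", "intermediate", "deep"))
  ranges <- lapply(plex, function(p_) p_$metadata$z_range)
  # layer depths 10/30/50 um sit in slices 11/31/51
  expect_true(ranges$primary[1] <= 11 && 11 <= ranges$primary[2])
  expect_true(ranges$intermediate[1] <= 31 && 31 <= ranges$intermediate[2])
  expect_true(ranges$deep[1] <= 51 && 51 <= ranges$deep[2])
  # the ranges partition the stack
  expect_equal(ranges$primary[2] + 1L, ranges$intermediate[1])
  expect_equal(ranges$intermediate[2] + 1L, ranges$deep[1])
})

test_that("manual ranges reproduce per-layer masks for separated layers", {
  fx <- make_stack(noise = 0)
  plex <- separate_plexuses(fx$stack, mode = "manual",
                            z_ranges = list(c(1, 21), c(22, 41), c(42, 61)))
  for (i in 1:3) {
    rec <- binarize(plex[[i]], despeckle = FALSE)
    expect_identical(rec$pixels, rasterize_mask(fx$graphs[[i]], 1)$pixels)
  }
  expect_error(separate_plexuses(fx$stack, mode = "manual",
                                 z_ranges = list(c(1, 30), c(20, 40),
                                                 c(41, 61))),
               "overlap")
})

test_that("a two-layer stack is rejected in auto mode", {
  p <- synth_params(field_size = 200, seed = 6, branch_rate = 0.015,
                    n_initial_tips = 6)
  g1 <- generate_network(p)
  g3 <- generate_network(p, seed_offset = 202L)
  empty <- generate_network(synth_params(field_size = 200, seed = 1,
                                         outgrowth_fraction = 0,
                                         n_initial_tips = 1))
  stack <- rasterize_stack(list(g1, empty, g3), layer_z = c(10, 30, 50),
                           noise_sd = 0)
  expect_error(separate_plexuses(stack, mode = "auto"), "manual")
})

test_that("percent deviation reproduces the tabular arithmetic", {
  expect_equal(percent_deviation(0.35, 0.40), 14.29)
  expect_equal(percent_deviation(2155.25, 7206.81), 234.38)
  expect_equal(percent_deviation(3, 3), 0)
  expect_equal(percent_deviation(0.94, 0.85), -9.57)
  expect_error(percent_deviation(0, 1), "undefined")
})

test_that("percent change reports reductions as positive percentages", {
  expect_equal(percent_change(0.35, 0.26), 25.7)
  expect_equal(percent_change(2155.24, 1092.18), 49.3)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("plexus analysis aggregates by sum/mean and computes deviations", {
  fx <- make_stack(seed = 9, noise = 2)
  fx$stack$roi <- disk_roi(dim(fx$stack$pixels)[2:3], fx$stack$center, 95)
  cmp <- analyze_plexuses(fx$stack, mode = "manual",
                          z_ranges = list(c(1, 21), c(22, 41), c(42, 61)))
  pp <- cmp$per_plexus
  expect_equal(cmp$aggregated$length_density_mm_per_mm2,
               sum(pp$length_density_mm_per_mm2))
  expect_equal(cmp$aggregated$branch_density_per_mm2,
               sum(pp$branch_density_per_mm2))
  expect_equal(cmp$aggregated$area_fraction, mean(pp$area_fraction))
  expect_equal(cmp$aggregated$nnd_mean_um, mean(pp$nnd_mean_um))
  expect_equal(cmp$aggregated$outgrowth, mean(pp$outgrowth))
  d <- cmp$deviations
  expect_equal(
    d$deviation_pct,
    percent_deviation(d$whole, d$single)
  )
  # re-running the analysis is bit-identical
  cmp2 <- analyze_plexuses(fx$stack, mode = "manual",
                           z_ranges = list(c(1, 21), c(22, 41), c(42, 61)))
  expect_identical(tidy(cmp), tidy(cmp2))
  expect_identical(cmp$deviations, cmp2$deviations)
})

test_that("three identical overlapping layers triple the summed densities", {
  p <- synth_params(field_size = 200, seed = 15, branch_rate = 0.02,
                    n_initial_tips = 6)
  g <- generate_network(p)
  stack <- rasterize_stack(list(g, g, g), layer_z = c(10, 30, 50),
                           noise_sd = 0)
  cmp <- analyze_plexuses(stack, mode = "manual",
                          z_ranges = list(c(1, 21), c(22, 41), c(42, 61)))
  expect_equal(cmp$aggregated$length_density_mm_per_mm2,
               3 * cmp$collapsed$length_density_mm_per_mm2)
  expect_equal(cmp$aggregated$branch_density_per_mm2,
               3 * cmp$collapsed$branch_density_per_mm2)
})

test_that("an empty plexus still aggregates (means include the zero)", {
  p <- synth_params(field_size = 200, seed = 6, branch_rate = 0.015,
                    n_initial_tips = 6)
  g1 <- generate_network(p)
  g3 <- generate_network(p, seed_offset = 202L)
  empty <- generate_network(synth_params(field_size = 200, seed = 1,
                                         outgrowth_fraction = 0,
                                         n_initial_tips = 1))
  stack <- rasterize_stack(list(g1, empty, g3), layer_z = c(10, 30, 50),
                           noise_sd = 0)
  cmp <- analyze_plexuses(stack, mode = "manual",
                          z_ranges = list(c(1, 21), c(22, 41), c(42, 61)))
  expect_equal(cmp$per_plexus$area_fraction[2], 0)
  expect_equal(cmp$aggregated$area_fraction,
               mean(cmp$per_plexus$area_fraction))
  expect_equal(cmp$aggregated$length_density_mm_per_mm2,
               sum(cmp$per_plexus$length_density_mm_per_mm2))
})
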