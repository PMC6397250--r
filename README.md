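# vesselmetrics

Quantitative morphometry of the developing retinal vasculature from
fluorescence images. The package re-implements, as tested R code, the
flatmount image-analysis workflow used to characterize vascular growth and
remodeling in the postnatal mouse retina: binarization of Cldn5-eGFP-style
flatmount images, skeleton-graph extraction, and six architectural
parameters, for both collapsed whole-retina projections and per-plexus
analysis of confocal z-stacks. A synthetic vascular-network generator with
exact geometric ground truth makes every pipeline stage verifiable without
microscope data.

## Who it is for

Groups quantifying angiogenesis in retinal flatmounts (development,
oxygen-induced retinopathy, pharmacological or genetic perturbations) who
want the classic ImageJ-style measurements as scriptable, reproducible,
unit-tested functions — plus a way to validate the whole measurement chain
against images whose true answer is known.

## The measurements

For a binary vessel mask *V* inside a region of interest *R* with
µm/px calibration:

- **Area fraction** `|V ∩ R| / |R|`
- **Length density** Σ segment lengths of the skeletonized mask (diagonal
  steps √2·px) per ROI area — mm/mm²
- **Branch density** number of junction clusters (8-adjacent skeleton
  pixels with ≥3 neighbours merged) per ROI area — mm⁻²
- **NND mean / SD** for each skeleton segment *i* with centroid *cᵢ*,
  `dᵢ = min_{j≠i} ‖cᵢ − cⱼ‖`; mean = capillary spacing, sample SD =
  spacing regularity — µm
- **Outgrowth** max distance from the optic-nerve-head centre to a vessel
  pixel over the max distance to an ROI pixel — unitless

Whole-retina vs single-plexus comparison: per-plexus length and branch
densities are **summed**, area fraction / NND / outgrowth **averaged**, and
compared with the collapsed projection via
`deviation % = (single − whole)/whole × 100`.

## Worked example

Generate a synthetic retina, run the pipeline, and measure it:

```r
library(vesselmetrics)

params <- synth_params(field_size = 400, seed = 11, branch_rate = 0.012,
                       anastomosis_probability = 0, noise_sd = 3,
                       illumination_gradient = 0.1, outgrowth_fraction = 0.9,
                       vessel_radius_range = c(1.5, 1.5), n_initial_tips = 6)
truth <- generate_network(params)
img   <- rasterize(truth, pixel_size = 1, noise_sd = 3,
                   illumination_gradient = 0.1, seed = 18)
img$roi <- disk_roi(dim(img$pixels), img$center, 200)

mask <- binarize(img)                  # 8-bit -> threshold -> despeckle -> ROI
morphometry(mask, label = "demo")
```

```
#> # A tibble: 1 × 9
#>   label area_fraction length_density_mm_per_mm2 branch_density_per_mm2
#>   <chr>         <dbl>                     <dbl>                  <dbl>
#> 1 demo         0.0345                      11.9                   71.6
#> # nnd_mean_um 24.7, nnd_sd_um 19.5, outgrowth 0.900, roi_area_mm2 0.126,
#> # n_segments 32
```

Reading: vessels cover 3.5% of the ROI; there are 11.9 mm of vessel and
72 branch points per mm²; vessel segments are on average 24.7 µm from
their nearest neighbour (SD 19.5 µm — a sparse, still-irregular network);
the vessel front has reached 90% of the ROI radius. Against the
generator's ground truth (`network_total_length(truth)` = 1432 µm, 9
junctions), the recovered skeleton length is within 5% and the junction
count is exact.

For a z-stack, `analyze_plexuses(stack)` returns the per-plexus table,
the aggregated single-plexus record, the collapsed whole-retina record
and the deviation table; `vessel_heatmap(mask, tile_um = 100)` gives the
tiled area-fraction map and its histogram (`autoplot()` to draw either).

A command-line front end wrapping these functions is installed at
`inst/cli/vesselmetrics.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/vesselmetrics.R", package="vesselmetrics"))')" \
    synth --preset p10 --seed 7 --out synth/
```

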