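---
title: "Quantifying retinal vascular architecture with vesselmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal vascular architecture with vesselmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 5)
library(vesselmetrics)
library(dplyr)
```

## The measurement problem

The mouse retina vascularizes after birth: vessels sprout from the optic
nerve head, spread radially across the inner surface until about postnatal
day 10, and then remodel — the initially dense, irregular capillary mesh is
pruned into a sparser, highly regular adult network. The vasculature is not
one sheet but three stacked plexuses (primary/superficial, intermediate,
deep) that form sequentially and remodel on their own schedules.

`vesselmetrics` measures this architecture from fluorescence images of
flatmounted retinas (and from confocal z-stacks of the three plexuses)
using six parameters:

* **vascular outgrowth** — how far the vessel front has advanced from the
  optic nerve head, as a fraction of the retinal radius (unitless, 0–1);
* **vascular area fraction** — vessel-covered pixels over ROI pixels
  (unitless, 0–1);
* **vessel length density** — summed centreline length per ROI area
  (mm/mm²);
* **branch-point density** — junctions per ROI area (mm⁻²);
* **nearest-neighbour distance (NND)** — mean distance from each vessel
  segment to its closest neighbour (µm), a measure of capillary spacing;
* **NND variability** — the sample standard deviation of those distances
  (µm), a measure of how regular the spacing is.

Length and branch counts are *summed* quantities and normalized by ROI
area; area fraction, NND and outgrowth are *intensive* quantities.
This distinction drives the whole-retina versus single-plexus comparison
below.

## The processing chain

`binarize()` reproduces the standard flatmount workflow:

1. **8-bit conversion** (`to_8bit()`): linear min–max rescale to 0–255,
   rounding half away from zero. A constant image maps to zero.
2. **Adaptive local-mean threshold** (`adaptive_threshold()`): a pixel is
   vessel iff it exceeds the mean of its `window_px` × `window_px`
   neighbourhood by more than `offset`. Defaults: window 51 px, offset 10
   intensity units. The window must be larger than a vessel diameter and
   smaller than the illumination scale; 51 px covers vessels of 3–20 px
   width at typical calibrations (0.3–1.3 µm/px). The offset is the
   brightness above the local background required to call vessel: it is the
   noise gate, and should sit at roughly 3× the background noise SD.
   Local means use replicate padding so image borders are not darkened.
   Because the criterion is *brighter than the local mean plus offset*, a
   flat field (however bright) is all background, and thin bright
   structures re-threshold to themselves — binarization is stable on its
   own output for structures narrower than the window.
3. **Despeckle** (`median_despeckle()`): a median over the 5-pixel
   plus-shaped neighbourhood (the radius-0.5 convention). On binary data
   this is a majority vote: isolated pixels vanish, pinholes fill.
   One-pixel-wide diagonal lines are erased by this kernel — vessels must
   be at least 2 px wide at the chosen calibration, which the rasterizer
   warns about. The filter is a single-pass cleanup; it is idempotent on
   its target defects (speckles, pinholes) but not a morphological fixed
   point on arbitrary masks.
4. **ROI masking** (`apply_roi()`): foreground outside the region of
   interest is cleared, and *all densities downstream are normalized by
   ROI area*, not image area.

## Skeleton graph

`skeletonize()` thins the mask to 8-connected, one-pixel-wide centrelines
with a two-subiteration parallel thinning scheme (Guo–Hall). Deletion
requires a crossing number of 1 (removal cannot split the network or
create a hole) and a local foreground count of 2–3 (interiors of 1-px
lines and endpoints are kept), with alternating direction conditions so
strokes erode from opposite borders towards their medial line. The
component count is preserved exactly — an assertion in the test suite, not
an assumption. We chose this scheme over sequential border peeling because
parallel subiterations keep diagonal strokes at odd widths: a 2-px
diagonal staircase resolves into a clean 1-px diagonal instead of
retracting from its ends.

`build_graph()` classifies skeleton pixels by their 8-neighbour count
(<2 endpoint, =2 slab, ≥3 junction), merges 8-adjacent junction pixels
into **junction clusters**, and traces **segments**. A branch *point* is a
junction cluster, not a junction pixel: a thick crossing thins to several
adjacent ≥3-neighbour pixels that are anatomically one arborization.

Every 8-adjacency step between skeleton pixels belongs to exactly one
segment: maximal slab runs with their terminal attachment steps, direct
terminal–terminal contacts as 2-px bridges, closed slab rings as cyclic
segments, and isolated pixels as zero-length segments. Orthogonal steps
count `pixel_size`, diagonal steps `sqrt(2) * pixel_size` — the √2
convention is a choice, stated here because length totals depend on it; it
makes the summed length equal the brute-force sum over all adjacent
skeleton-pixel pairs, which the test suite verifies exactly. Chain-code
length measured this way overestimates true curve length by up to ~8% at
worst-case orientations (~5% on average over orientations); this, together
with junction geometry, is why pipeline length recovery is validated to a
10% band rather than exactly.

### Nearest-neighbour distances

The NND tool's "single vessels" are taken to be the skeleton segments,
each represented by its pixel centroid; for each segment the distance to
the nearest other centroid is computed, then summarized as mean and
sample SD (n−1). Two alternatives were considered and rejected: pixel-set
distances between adjacent segments are ~0 at shared junctions (which
cannot produce capillary-spacing values of ~15–20 µm), and per-pixel
nearest-foreground distances measure vessel width, not spacing. Bridge
segments that are internal wiring of a single junction cluster are
excluded from the particle set; zero-length (isolated-pixel) segments
likewise. NND is undefined below two particles and the corresponding
functions say so rather than returning a number.

## Heatmaps

`vessel_heatmap()` tiles the ROI bounding box with squares of side
`tile_um` (default 100 µm) and computes the area fraction inside each
tile. Tiles with under half their pixels in the ROI are marked missing —
including them would fabricate low-coverage tiles all along the ROI rim.
The 20-bin histogram of tile values over [0, 1] summarizes coverage: a
young, partially vascularized retina is bimodal (empty periphery, covered
centre), a mature one unimodal. The numeric tile grid is the contract;
colour rendering is cosmetic (`autoplot()`).

## Whole-retina versus single-plexus analysis

A collapsed analysis runs the chain on the maximum projection of the full
stack (`collapse_stack()`). A single-plexus analysis first splits the
stack into three per-plexus projections (`separate_plexuses()`), runs the
chain on each, and combines (`analyze_plexuses()`):

* length density and branch density are **summed** across plexuses —
  vessels in different layers are different vessels;
* area fraction, NND mean, NND SD and outgrowth are **averaged** — they
  are intensive, and summing them would be meaningless. The outgrowth and
  NND-SD aggregation rules are our interpretation (documented, not
  prescribed): the plain mean keeps the aggregate on the scale of a
  single plexus.

The percent deviation `(single − whole)/whole × 100` (rounded
half-away-from-zero to 2 decimals, `percent_deviation()`) quantifies what
a collapsed analysis loses: wherever plexuses overlap in x/y, the
projection merges vessels that are distinct in 3D, so the collapsed
analysis *undercounts* length and branches. For synthetic three-layer
stacks with overlapping layers this undercount is a theorem of the
construction, and the suite asserts `aggregated ≥ collapsed` for both
summed densities. Developmental change between two timepoints uses
`percent_change()`, `(early − late)/early × 100` rounded to 1 decimal,
positive = reduction.

Automatic plexus separation thresholds each slice, counts foreground,
smooths the per-slice counts with a 3-slice moving average, and takes the
three highest local maxima as the plexus depths, cutting at the count
minima between them. A peak must dominate a ±3-slice window and exceed
10% of the maximum count — without the dominance window, ripples inside
one z-band register as spurious peaks. Anything other than three
qualifying peaks is an error instructing the caller to give manual
z-ranges; guessing would silently misassign layers.

## The synthetic generator

Real Cldn5-eGFP retina images are not distributable with a package, and no
real image comes with ground truth. `generate_network()` therefore grows
vascular networks with *exact* geometric truth, and `rasterize()` turns
them into retina-like images, so that every pipeline stage is tested
against known answers.

Growth is iterative tip extension: sprouts leave a small ring around the
centre (trunks exit the optic-nerve-head rim separately, which also keeps
the truth graph free of a single degree-n star node), advance in fixed
4 µm steps with wrapped-normal heading jitter and a configurable outward
drift (`radial_bias`, the front's migration toward the periphery), branch
at `branch_rate` per µm with a refractory arc distance between branch
events (lateral inhibition), and stop at the outgrowth limit
(`outgrowth_fraction` × field radius) or the field border. A tip that
comes within the collision radius of another vessel either **fuses**
(probability `anastomosis_probability`), splitting the target edge at a
new node so the truth graph matches what the image shows, or
**terminates** — tips never cross, because a single plexus is planar. The
collision radius is `max(capture_radius_um, 2·r_max + step/2)`: anything
smaller would let strokes overlap without a recorded junction and the
image would contain junctions absent from the truth. Failed sprouts
shorter than `retract_below_um` (default 10 µm) retract completely, as
abortive sprouts do in vivo; without retraction the truth graph contains
sub-resolution stubs whose junctions no image-based method could see.
Three forms of spatial structure are available: sector heterogeneity
(`branch_rate_dispersion` — every third founder heads a dense sector and
descendants inherit their founder's branch-rate multiplier), an immature
vascular front (`frontier_fraction` / `peripheral_branch_mult` — beyond
the frontier radius only sparse pioneer sprouts grow, which is where the
long right tail of nearest-neighbour distances in a young retina comes
from), and remodeling (`prune_network()` / `prune_below_um` — redundant
capillary loops shorter than a threshold are removed, shortest first,
only when the loop stays connected and both ends remain branch points).

Each tip consumes its own deterministic random substream, so a tip's
decision schedule does not depend on how many other tips exist; raising
`branch_rate` with the same seed can then only add branch events, which
makes the junction-count monotonicity property testable rather than
merely probable. The seed fully determines the network and the image.

Rasterization draws hard (non-anti-aliased) strokes of width 2× the edge
radius by exact point-to-segment distance, so an analytic mask oracle
exists (`rasterize_mask()`); intensity is foreground 200 / background 25
on the 8-bit scale, with a multiplicative linear illumination ramp and
additive Gaussian noise (default SD 3 — a bright, uniformly expressed
vascular reporter; with the default threshold offset of 10 ≈ 3σ the noise
gate is calibrated the way a user would set it on real data). Z-stacks
place each layer's vessels in a Gaussian z-band (σ = 2 µm, truncated at
3σ) centred on its depth.

### What the generator does and does not emulate

It reproduces the features the pipeline is sensitive to: a bright
interconnected curvilinear network radiating from a centre, loops,
layer separation in z, uneven illumination, sensor noise, and calibrated
geometry. It does not attempt biophysical realism: no VEGF or astrocyte
guidance fields, no arteries/veins, no vessel-calibre hierarchy, no
pericytes, no time-lapse. Consequently, passing tests demonstrate that
the *measurement* pipeline recovers known geometry under realistic image
degradations — they do not validate biological conclusions about real
retinas, and absolute parameter values from synthetic data should never
be compared with published biological means.

### Validation conditions

The suite validates parameter recovery on networks of 400 µm fields at
1 µm/px, three seeds × two branching densities, with anastomosis off for
the junction-exactness check (fusion nodes at close range are a separate
regime): recovered junction counts must equal the truth exactly when
ground-truth junctions are separated by at least 5 vessel widths, total
length must be within 10%, and outgrowth within ±0.02. The qualitative
remodeling check compares a dense/irregular preset (`synth_preset("p10")`)
with a pruned/regular one (`synth_preset("p60")`) at 600 µm and asserts
only the *direction* of the differences (area fraction, branch density
and NND variability all lower in the pruned network), never magnitudes.
The two presets realize the two regimes geometrically: the immature
preset is a dense core of dilated vessels (radii 2.8–3.8 µm) with strong
heading jitter, sector heterogeneity and a sparse pioneer front beyond
85% of the outgrowth radius; the remodeled preset is a quasi-lattice —
branching fires essentially at the 25 µm refractory distance, heading
jitter is near zero, an outward drift keeps capillaries parallel, and
vessels are narrowed to 1.8–2.5 µm. A perfectly regular lattice has
*zero* NND variability, which is why lattice-like growth is the right
model for the adult network's regularity.

The undercount comparison needs layers that overlap in x/y the way real
plexuses share their territory; statistically independent layers would
instead *create* junctions wherever projected vessels cross. The
three-layer validation stacks therefore use one mesh plus two
successively pruned versions of it — full overlap, so the projection
merges what depth separates, and both undercount inequalities
(aggregated ≥ collapsed for summed length and branches) hold
deterministically.

## Numerical conventions and degenerate inputs

* Pixel centres sit on the integer grid; physical position of pixel
  `(i, j)` is `((i−1)·pixel_size, (j−1)·pixel_size)` µm. Stacks are
  `(z, y, x)`.
* Rounding of derived percentages is half-away-from-zero (2 decimals for
  deviations, 1 for percent change); all stored results keep full
  precision, rounding is display-side only.
* Segment tracing visits neighbours in the fixed order N, NE, E, SE, S,
  SW, W, NW; together with column-major pixel order this makes every
  result bit-reproducible.
* Empty ROI, zero ROI area, missing centre point, fewer than two NND
  particles, a whole-retina value of zero in a deviation: all are errors
  with instructive messages, not NaNs.
* `to_8bit()` of a constant image is all zeros; an empty skeleton has
  total length 0 and no branches.

## Known limitations

* Skeleton-based length inherits the chain-code bias (≤ ~8%); junction
  clusters closer than about a vessel width merge.
* NND-on-centroids is one defensible reading of "distance between the
  single vessels"; other readings (e.g. labelled-particle distances)
  would give different absolute values.
* The flatmount processing chain is 2D; stacks are analyzed as
  per-plexus projections, not by 3D skeletonization.
* Auto plexus separation assumes three distinguishable bands; stacks
  acquired at coarse z-resolution (> 2 µm) should use manual ranges.
* Test and validation problem sizes (fields of 250–600 µm at 1 µm/px)
  were chosen to exercise all code paths at capillary-realistic geometry;
  they are smaller than a full retina scan, whose tiles should be
  processed ROI by ROI.
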