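---
title: "Methods: assemblage colour lightness and climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assemblage colour lightness and climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(melanoclim)
```

## The model

`melanoclim` tests whether the colour lightness of butterfly assemblages
tracks climate, as predicted by thermal melanism (darker in cold climates),
UV protection (darker under high insolation) and pathogen resistance
(darker in humid climates). The analysis unit is the *assemblage*: the set
of species whose ranges overlap a grid cell of an equal-area tessellation.
The response is the unweighted mean of the member species' colour
lightness; the predictors are per-cell annual means of insolation,
temperature and humidity. Regressions with linear and quadratic predictors
are fitted per continent, family scope and body side, and classified by
sign, significance and curvature.

Assumptions worth stating explicitly:

* **Presence, not abundance.** Atlas- and contour-map-style distribution
  data support only presence/absence, so assemblage means are unweighted.
  Abundance weighting would change cell means wherever common and rare
  species differ in lightness.
* **One trait value per species.** A single (female or monomorphic)
  image per side represents the species; intraspecific and seasonal
  variation is ignored.
* **Cells are exchangeable up to spatial autocorrelation.** The OLS models
  treat cells as independent; the GLS variant absorbs residual spatial
  structure into a Gaussian correlogram rather than modelling its cause.

## Trait extraction

Colour lightness is the grand mean of the R, G and B channels over the
region of interest, 0 (black) to 255 (white). Because the three channels
share one mask, the grand mean equals the mean of the per-channel means;
the computation is done in double precision in one pass.

The ROI is the body plus the proximal third of each wing, the area most
relevant for thermoregulation of the thorax. "Proximal third" is
implemented as a distance criterion along the wing's base-to-tip axis:
a wing pixel belongs to the ROI when its orthogonal projection onto that
axis lies within the first third of the axis length. An area-fraction
criterion would be an alternative reading; the axis rule was chosen
because it is well defined for any wing shape, monotone along the wing,
and directly expresses "closest to the body". Masks are first-class
inputs: `build_roi_mask()` exists for landmarked images, but any
externally produced mask (e.g. manual cropping) is accepted unchanged,
and background pixels are never special-cased — only the mask defines the
considered area.

Species-level assembly: images failing the sex policy (default: keep
`female` and `monomorphic`) are dropped; lightness is averaged within
morph, then unweighted across morphs, per side; species missing either
side become exclusion records, never traits. Morph averaging precedes side
pairing — the order is a package decision, as only one of the two orders
can be implemented. Species complexes are collapsed by unweighted member
means (`complex_average()`), and their presence columns are unions of the
member ranges (`rasterize_ranges(..., complex_map = )`).

## Gridding and aggregation

`make_grid()` anchors the tessellation at integer multiples of the cell
size in the projected CRS, so grids are reproducible without a reference
file. Cells are half-open, making the tessellation a partition; a boundary
point belongs to the lower-left cell. Cell membership of a range uses
*positive-area overlap*: expert contour maps over-cover, so any overlap is
counted, and a polygon touching a cell only along an edge is not present.
A centroid rule would under-count coastal and boundary cells.

The minimum-richness filter (default 5 species) excludes cells whose
assemblage mean would rest on too few species. The filter is applied to
the in-scope richness, i.e. a per-family analysis requires five species of
that family in the cell.

`aggregate_to_grid()` computes area-weighted means of the raster pixels
intersecting each cell, robust to resolution mismatch between climate
pixels and grid cells. Missing pixels are dropped from the weighted mean;
cells with no valid coverage are `NA`, never silently zero. Annual means
weight the twelve months equally; hourly data, where present, are pooled
within month first. Insolation is averaged over all hours including night
zeros — averaging daylight hours only would scale INS by roughly the
day-length fraction; the all-hours choice is the simpler convention and is
configurable upstream of the package by supplying different stacks. CRS
labels must match between rasters and grids; the package performs no
reprojection (the synthetic worlds and any pre-projected data make it
unnecessary).

## Model battery and shape classification

For each design cell of continent × {all + families} × {dorsal, ventral} ×
{INS, TMP, HUM}, `fit_shape_models()` fits `y ~ x` and `y ~ x + x²` and
classifies:

* `n.s.` if neither model's overall F-test is significant at α = 0.001.
  The α applies to the overall F rather than individual coefficients —
  the simplest rule that treats both models symmetrically.
* quadratic (`U` if the x² coefficient is positive, `hump` if negative)
  when Δr² = r²(quad) − r²(linear) is *strictly* greater than 0.1; a Δr²
  of exactly 0.1 is linear.
* otherwise `linear`, signed by the linear slope.

The predictor is z-scored internally before the quadratic fit; r², signs
and p-values are invariant to this, but the normal equations are much
better conditioned. No multiple-testing correction is applied across the
battery — the design reports each model as-is, and readers should treat
marginal significances accordingly. Degenerate inputs (fewer than 10
cells, zero variance) raise errors rather than returning records; the
battery converts such failures into `status = "absent"` rows so the design
stays complete.

## Spatial GLS

`fit_gls_spatial()` refits the mean model with errors correlated as
exp(−(d/ρ)²), d the Manhattan distance between cell centres, ρ estimated
by maximum likelihood (via `nlme::gls`). The mean structure is linear, or
quadratic when the OLS classification was quadratic — the quadratic mean
must be carried over, otherwise curvature masquerades as spatial
correlation. Numerical choices:

* Dense-covariance ML is O(n³), so data beyond `max_n` cells (default
  3000) are fitted on a seeded random subsample, which is recorded in the
  result.
* The profiled range parameter can overflow during optimisation when the
  data carry little spatial correlation; the fitter tries a ladder of
  starting values (span/8, span/20, span/50, span/2 of the Manhattan
  diameter) and reports a diagnostic error — never a silent OLS fallback —
  if all fail.
* Duplicate coordinates would make the correlation matrix singular; they
  are jittered deterministically by about one metre using a multiplicative
  hash of the row index, so results are reproducible.
* The nugget term is off by default and can be enabled.

## Tukey HSD contrasts

Dorsal–ventral and between-family differences in species-level lightness
use a one-way layout with all pairwise comparisons adjusted by the
studentized range distribution (base `aov` + `TukeyHSD`). Groups with
fewer than two species are dropped with a warning. The package's null
simulations (1000 replicates) confirm the family-wise error rate stays at
its nominal 5%.

## The synthetic world

The generator exists to give every stage a ground truth. Defaults were
chosen once, to resemble a continental-scale butterfly study:

| Parameter | Default | Why |
|---|---|---|
| extent | 2000 × 2000 km (continent B: 1500 km) | continental scale at 50 km cells (1600 / 900 cells), large/small pair |
| raster resolution | 25 km | 2 × 2 climate pixels per cell exercises area weighting |
| n_species | 150 (B: 120) | few-hundred-species pools, richness per cell well above the filter |
| families | 0.30/0.40/0.10/0.20 | species-rich Lycaenidae/Nymphalidae vs poorer Papilionidae/Pieridae |
| lightness range | [30, 230] | keeps clipped noise and the ventral offset inside [0, 255] |
| dorsal–ventral offset | +30 | countershading direction and magnitude of real dorsal/ventral contrasts |
| beta | 0.12 °C per lightness unit | optima span the 30 °C gradient over the 200-unit lightness range |
| niche width | 10 °C | bands occupy a plausible fraction of the gradient; richness gradients emerge |
| temperature gradient | 25 °C (south) to −5 °C (north) | temperate-continent span |
| climate noise sd | 1 °C, spatially smoothed | enough autocorrelated texture for the GLS to have something to absorb |
| pixel noise sd | 3 grayscale units | scanner-like noise; SE of the ROI mean ≈ 3/√10⁴ = 0.03 |
| seasonal amplitude | 8 °C | monthly layers differ but average back to the annual field exactly |

Climate fields are a linear north–south gradient plus Gaussian-filtered
white noise — a separable construction, not a full geostatistical model;
it is cheap and produces the spatial autocorrelation the GLS tests need.
Insolation is a positive affine function of temperature, humidity a
negative one, each with independent noise. Monthly layers add a zero-mean
sinusoid so annual averaging is exercised non-trivially but exactly.
Ranges are climate-threshold bands (pixels within half a niche width of
the optimum) — no dispersal or occupancy model; the analysis only needs
presence structure coupled to climate. Rendered specimens are stylised
(body ellipse, four wing quadrilaterals, flat colour plus noise); the
distal two-thirds of each wing deliberately carry a different grayscale
(offset 60) so ROI mistakes are detectable, and the exact mask is emitted
alongside each image.

What the generator does **not** emulate: photorealistic wing patterns,
sexual dichromatism beyond a sex tag, range disjunctions and dispersal
limits, coastlines and irregular continental outlines, elevation, and
observation error in range maps. Passing tests therefore demonstrate the
correctness of the pipeline's computations, not robustness of the
biological conclusions to those real-data complications.

Besides the linear coupling, the generator can produce quadratic
(`response = "hump"` or `"U"`) trait–environment responses by drawing the
thermal optimum uniformly and making lightness a quadratic function of
it. This exists to probe the Δr² shape classifier against a known
generating shape.

Determinism: all randomness flows from one seed through deterministic
per-component sub-seeds (a fixed affine map modulo a Mersenne prime kept
below 2³¹), so identical configurations produce bit-identical rasters,
pools, polygons and images.

## Numerical conventions and degenerate inputs

* Quantile bins use type-7 sample quantiles; ties go to the lower bin and
  the lowest bin is closed on the left. All-equal inputs yield one bin
  with a warning.
* Grid construction kills floating-point sliver cells with a relative
  area tolerance (10⁻¹² of a cell) while preserving genuinely thin
  overlaps.
* Polygon–cell intersection uses Sutherland–Hodgman clipping with the
  shoelace area; pixel-union ranges use exact interval arithmetic.
* Empty ROI masks, degenerate wing axes, mixed-family species, traitless
  present species, zero-variance regressions and mismatched raster
  geometry all raise errors naming the offender rather than degrading
  silently.
* Exact model fits (noiseless synthetic data) legitimately trigger
  `summary.lm`'s "essentially perfect fit" warning; it is suppressed at
  the fit sites.

## Problem sizes in the test suite

The suite validates against brute-force oracles on worlds of 20 × 20 to
80 × 80 climate pixels with 25–150 species, replication studies of 100
worlds (sign recovery) and 20 simulated Gaussian fields of n = 400 (range
recovery), and 1000-replicate null simulations for the Tukey family-wise
error rate — sizes at which the independent oracles (dense sampling,
double loops, eigendecomposition simulation) are themselves fast and
trustworthy.

## Known limitations

* No reprojection: inputs must share a projected equal-area CRS.
* The GLS subsample cap trades statistical efficiency for tractability on
  grids of many thousands of cells; different seeds give slightly
  different ρ̂ on subsampled fits.
* The presence rule and grid origin are conventions; real atlas data
  digitized against a different reference grid will not align cell-for-cell.
* Assemblage means ignore phylogeny; related species contribute as
  independent data points.
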