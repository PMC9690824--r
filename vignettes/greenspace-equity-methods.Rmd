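---
title: "Methods: green-space service coverage, accessibility and equity zoning"
author: "greenserv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: green-space service coverage, accessibility and equity zoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenserv)
```

# The problem

Compact cities ask three related questions of their green space: how far does
each patch's *service* reach (cooling the urban heat island, everyday
recreation, disaster shelter), how *accessible* is park green space to the
people who live in each neighbourhood, and where do service supply and human
activity *mismatch*? `greenserv` implements a complete grid-based workflow
for these questions on projected planar (meter) coordinates, together with a
seeded synthetic-city generator so the entire pipeline is testable and
reproducible without any proprietary GIS layers.

The pipeline has four analytic stages:

1. **Life heat** — kernel density of daily-life points of interest (POIs),
   classified into five ordered density zones.
2. **Service layers** — buffer analysis for three service functions, with
   union, overlap and per-zone coverage statistics and the composite
   three-service space.
3. **Accessibility** — Gaussian two-step floating catchment area (G2SFCA)
   accessibility of park green space, compared against the city-wide
   per-capita park provision.
4. **Integration** — overlay of heat level, accessibility level and service
   enjoyment into six named equity zones.

# Life heat from POI kernel density

The activity intensity ("life heat") surface at a location $s$ is the
finite-support kernel sum over POIs $c_i$ within the search radius $h$:

$$f(s) \;=\; \sum_{\lVert s - c_i\rVert \le h} \frac{1}{\pi h^2}
\left(1 - \frac{\lVert s - c_i\rVert^2}{h^2}\right).$$

Two properties of this kernel are worth stating plainly. First, it is
*unnormalised*: its integral over the support disk is exactly $1/2$ for every
$h$ (the `kernelMass()` diagnostic verifies this by quadrature), so absolute
values are half those of a proper density estimate. We implement it in this
form deliberately — it is the form the GIS point-density workflow computes —
and provide the standard quartic (biweight) kernel, which integrates to 1,
behind `kernel = "quartic"`. Zone classification ranks values, so it is
invariant to this positive scale factor. Second, the kernel is a pure
superposition: the surface of a union of POI sets is the sum of the two
surfaces, which the test suite exploits as an exact identity.

**Bandwidth.** There is no single defensible bandwidth for POI heat mapping;
we default to $h = 1250$ m, the 15-minute walking threshold used everywhere
else in the pipeline, so the analysis carries exactly one distance scale.
It is configurable (`bandwidth` in `pipelineConfig()`).

**Classification.** The five zones (Cold < Sub-Cold < Not-Significant <
Sub-Hot < Hot) are cut with Fisher–Jenks natural breaks by default — the
conventional choice for density zoning — with quantile and equal-interval
options. The Jenks optimiser is an exact $O(kn^2)$ dynamic program; above
3000 cells it runs on a deterministic thinning of the sorted values, which
leaves breaks essentially unchanged while keeping the default 18,200-cell
run instantaneous. Hot is always the highest-density class; zone areas are
reported consistently with that orientation. A constant surface (fewer
distinct values than classes) is an error, not a silent single class.

# Service layers

Every service layer is built the same way: each eligible green patch gets a
buffer measured outward from its polygon *boundary* (not its centroid), the
patch footprint itself counts as served, buffers are dissolved into a union,
and the region covered by at least two individual buffers is the overlap.
All geometry is evaluated on the analysis grid (50 m cells by default,
configurable): a cell belongs to a buffer when its centre lies within the
buffer radius of the polygon, with point-to-polygon distances computed
exactly. Grid counting is also how the published workflow's raster overlay
behaves, and the suite checks the resulting areas against analytic
closed-form and independent counting oracles to within 0.5 % on 5 m grids.

The three rules:

* **Cooling** (parks and protective buffers): radius
  $y = 53.668\ln x - 448.33$ with $x$ the patch area in m² and $y$ in
  meters, clamped at zero. The zero crossing sits at
  $e^{448.33/53.668} \approx 4246$ m²; in these units a 1 km² patch cools
  ~293 m beyond its edge, consistent with the empirical cooling-distance
  literature the rule comes from. The clamped rule is continuous and
  nondecreasing.
* **Recreation** (parks only — protective strips along roads and rivers are
  not recreational destinations): two walking scales at 5 km/h, an inner
  disk of 420 m (&lt; 5 min; 5 min is 416.7 m, kept at the conventional
  planning value of 420 m) and the full 15-minute disk of 1250 m. The
  scales are cumulative (the 1250 m layer contains the 420 m layer), not
  annular.
* **Disaster shelter** (parks and buffers): piecewise-constant radii by
  size class — parks 0.5–1 ha → 500 m, 1–10 ha → 1000 m, 10–50 ha →
  2000 m, ≥ 50 ha → 3000 m; buffers ≥ 0.5 ha → 300 m. Patches below the
  smallest class provide no shelter service at all (the class table is
  silent below 0.5 ha, and a sub-half-hectare patch is no refuge).

Distances are Euclidean throughout. Travel-cost (network) distance is a
deliberate non-goal: the pipeline has no road graph, and the distance
computation is isolated in one place (`distanceToPolygon()`, centroid
distances in the access stage) so a network backend could be substituted
without touching any statistics.

The **composite three-service space** is the geometric intersection of the
cooling, recreation-1250 and disaster unions — the region that "enjoys all
three services". Intersection (rather than a weighted overlay) is the
operational reading of enjoying every service simultaneously; it is
idempotent for identical layers and absorbed by any empty one.

All percentages in every emitted table pass through one reporting function,
`ratioPercent()`: half-up rounding at two decimals (counts of units at zero
decimals), applied only at the reporting layer — internal computation is
never rounded.

# Gaussian two-step floating catchment area

Accessibility uses the truncated, rescaled Gaussian decay

$$G(d) = \frac{e^{-\frac12 (d/d_0)^2} - e^{-\frac12}}{1 - e^{-\frac12}},
\qquad d \le d_0,$$

which equals 1 at distance zero, falls strictly to 0 at the catchment limit
$d_0$ (default 1250 m, the 15-minute walk), and is identically zero beyond.
Step one computes each park's supply–demand ratio
$R_j = S_j / \sum_{k:\,d_{kj}\le d_0} G(d_{kj}) D_k$ (park area in m² over
decay-weighted population in its catchment); step two sums
$A_i = \sum_{j:\,d_{ij}\le d_0} G(d_{ij}) R_j$ over parks reachable from each
demand unit's centroid. Units are m² of park per person throughout.

Three design points:

* **Degenerate parks.** A park with no demand unit inside its catchment has
  an undefined ratio; it is flagged unserved and contributes nothing
  downstream (the alternative — treating it as infinite supply — poisons
  every sum).
* **Conservation.** The defining property of the method is that
  $\sum_i D_i A_i = \sum_{j\,\text{served}} S_j$ exactly: decay-weighted
  redistribution neither creates nor destroys supply. The suite asserts
  this to $10^{-9}$ relative on 100 random instances, and asserts agreement
  with an independent brute-force double loop to $10^{-12}$.
* **Benchmark.** The supply flag compares each $A_i$ with the city-wide
  per-capita park area $\sum S_j / \sum D_k$; $A_i \ge$ benchmark means the
  unit's accessible supply meets the average provision. The threshold is
  configurable.

Accessibility classes (low / medium / mid-high / high) default to quantile
breaks — with many zero-access units the raw quantiles can tie, in which
case breaks are recomputed on the distinct values — and the three-level
collapse used by the overlay merges medium with mid-high.

# Integrated zoning

Each study-area cell gets a partition code: heat group (Cold and Sub-Cold →
low, Not-Significant → medium, Sub-Hot and Hot → high), accessibility level
(the three-level collapse, inherited from the demand unit containing the
cell centre) and service flag (enjoy iff the centre lies in the composite
space) — 3 × 3 × 2 = 18 codes, alongside the unit's binary supply flag.

The merge to six named areas keys on (supply flag, heat group, service
flag). Six of those eight combinations follow the published partition rows:

| supply | heat | service | zone |
|---|---|---|---|
| ≥ demand | medium/high | enjoy | High-quality living area |
| ≥ demand | low | enjoy | Livable area |
| < demand | low | not enjoy | Underdeveloped area |
| ≥ demand | medium/high | not enjoy | Green space service blind area |
| < demand | medium/high | enjoy | Under supply and demand area |
| < demand | medium/high | not enjoy | Comprehensive blind area |

The two remaining combinations are not enumerated in the published table;
we default each to the row differing in exactly one field — (≥ demand, low,
not enjoy) → Green space service blind area, and (< demand, low, enjoy) →
Livable area — and the whole mapping is an ordinary data frame
(`defaultZoneMapping()`) that callers can override. Under the default
mapping, switching a cell's service flag on can never move it into a
"blind" zone, which the suite checks exhaustively.

# The synthetic city

The generator emulates the statistical structure the analysis assumes, under
one seed, so that identical configurations give bit-identical cities:

* a rectangular built-up frame of 7000 × 6500 m (45.5 km², matching the
  tens-of-km² compact-city setting);
* 24 park patches with areas log-uniform between 5 × 10³ and 10⁶ m²,
  stratified so every disaster size class is represented, plus 6 elongated
  protective strips (riverside/roadside green);
* 1294 POIs from a mixture of an old-town cluster (weight 0.45, spread
  600 m), two secondary clusters and a 30 % uniform background — an
  irregularly decaying density from the old centre outward;
* a 100 m population raster proportional to a 300 m Gaussian blur of POI
  intensity plus a 15 % uniform background, normalised to 100,000
  residents (a realistic small prefecture-level built-up population; the
  source setting publishes no total, so this is fixed once here);
* 233 demand units tessellating the frame as near-square row cells (rows of
  equal height, each split into equal-width cells differing by at most one
  per row, so any count — including primes — tessellates exactly); each
  unit's population is the sum of raster cells whose centres it contains.

What the generator does *not* emulate: street networks and network
distances, irregular administrative boundaries, multi-polygon parks,
vertical density (high-rises), and POI category structure beyond labels.
Passing tests on this city therefore demonstrate the correctness and
internal consistency of the computations — conservation, oracle agreement,
determinism, the reporting conventions — not the empirical accuracy of any
particular city's published coverage figures, which depend on unpublished
digitised layers.

# Numerical choices and degenerate inputs

* Grid membership is by cell centre; at 50 m cells the area quantisation is
  below the reporting precision of the tables, and the oracle tests bound
  it at ≤ 0.5 % on 5 m grids.
* Half-up rounding operates on the represented double; a quotient landing
  within ~10⁻⁶ of a .xx5 boundary renders to the nearest representable
  side (documented behaviour of `roundHalfUp()`).
* Problem sizes: the default run uses an 18,200-cell analysis grid, 1294
  POIs and 233 units and completes in a few seconds; oracle tests use 5 m
  grids on ≤ 2.5 km scenes and ≤ 20 polygons.
* Empty green-space sets, POI-free cities and park-free cities all flow
  through: layers report zero coverage, accessibility is identically zero,
  and classification falls back to a single "low" class instead of erroring
  inside the pipeline (direct calls to the classifiers still error on
  degenerate inputs, which is the right behaviour for analysis code).
* Seeds: every generator stage derives its own stream from the config seed
  (kept below 2³¹), so stages are individually reproducible and reordering
  calls cannot change a layer.

# Known limitations

Euclidean distance overstates accessibility wherever the street grid is
sparse; centroid representation of demand units ignores within-unit
population structure; the cooling rule is an empirical log fit from a
different climate and should be recalibrated for serious use elsewhere; and
the five-zone / four-class break methods are conventions, not estimands —
published zone areas are not recoverable without the identical break
algorithm and input layers.
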