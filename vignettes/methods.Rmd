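---
title: "Models and methods behind fenceflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fenceflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fenceflow` chains five models — habitat selection, resistance, circuit
connectivity, restoration scoring, and validation — into one pipeline for
prioritizing fence removal in migratory rangelands. This vignette explains
each model, its assumptions, the tunable parameters and their defaults, the
numerical choices, and what the synthetic test system does and does not
demonstrate.

## Habitat selection model

Use–availability design: each GPS presence is paired with `pseudo_ratio`
(default 50) pseudo-absences placed *area-uniformly* in a disk whose radius
is that animal's maximum observed step length, clipped to the landscape.
"Randomly distributed within a buffer" is read as spatially uniform over the
disk, not uniform in radius. Time-varying covariates (NDVI, and its 16-day
rate of change ΔNDVI) are matched to the presence's timestamp by linear
interpolation between the two nearest composites; an absence inherits its
presence's timestamp.

The default fit is a binomial GLMM with logit link, a per-animal random
intercept, linear terms for every covariate, and a quadratic companion for
every distance covariate (non-linear distance responses are the expected
biology). Design columns (including each squared distance column) are
z-scored before fitting; the moments are stored and re-applied at
prediction, and coefficients are also reported back-transformed to the raw
scale, with distances in kilometres. Estimation is by Laplace approximation
(`lme4::glmer`); if the mixed fit fails, the fit falls back — flagged in
`fit_meta$method` — to a fixed-effects logistic with animal indicator
variables, solved by IRLS with a ridge of 1e-8 on the design so separation
cannot produce infinite estimates. The population-level fixed effects are
the inference target either way, so the fallback changes uncertainty
bookkeeping, not the predicted surface.

**Two-stage estimator.** `fit_rsf(method = "two_stage")` fits an
independent (ridge-stabilised) logistic per animal and averages the
coefficients; its standard error is the between-animal empirical SE,
`sd/√G`. Model-based SEs from the pooled fit treat thousands of serially
dependent fixes as independent and are anticonservative for movement data;
the two-stage SE absorbs within-animal dependence wholesale. Parameter
recovery experiments in the test suite use this estimator.

**Consistency regime.** The movement simulator chooses each step among
kernel-drawn candidates with probability ∝ exp(βᵀx). The marginal
distribution of such a chain is only approximately ∝ exp(βᵀx): at strong
selection the chain lingers on good patches (the excess is governed by the
kernel mass falling within one covariate correlation length), and the
use–availability contrast then *over*-estimates β. Recovery tests therefore
run in the weak-selection regime on a domain much larger than the step
kernel (200 km, correlation length 1.5 km, |β| ≤ 0.05 per standardized
unit), where the estimator is calibrated. This is a property of
use–availability designs generally, not of this implementation.

Prediction sets the random intercept to zero, replaces NDVI by its series
mean and ΔNDVI by a named green-up snapshot, and clamps the inverse-logit
output to the open unit interval at machine epsilon.

## Resistance surface

Suitability is inverted to resistance by the linear map
`r = r_max − (r_max − r_min)·s` with defaults `r_min = 1`, `r_max = 100`.
The linear form makes the fence barrier value 100 the natural maximum of
the scale and keeps resistance bounded; the reciprocal alternative `1/s`
(rescaled into the same interval) sits behind `method = "reciprocal"`. The
mapping used is recorded as an attribute on the output.

Fences are burned in by *supercover* rasterization: every cell whose closed
square a fence segment touches becomes the barrier value — deliberately
conservative for a barrier, with the consequence that a corridor of width
`w` through a fence opens a free passage of only about `w − cell_size`.
Parcels fully enclosed by fencing are filled at the barrier value too.
Enclosure is decided by noding all polylines into a planar arrangement,
trimming dangling edges, and walking half-edge cycles: a bounded face is a
parcel when its boundary uses at least three distinct original fence lines
("two at least parallel or angled toward another" is operationalized as
bounded-face extraction, since a bounded face necessarily satisfies it), and
any face nested inside a detected parcel is a parcel as well. Areas are
reported in m² and acres (1 acre = 4046.8564224 m²).

## Circuit connectivity

Each valid cell is a node joined to its four nearest neighbours; the edge
resistor is the arithmetic mean of the two cell resistances (the
average-resistance convention; average conductance is available behind a
flag). Focal regions are contracted to zero-internal-resistance supernodes.
For each unordered focal pair, one ampere is injected at the source with
the ground fixed at 0 V, and the grounded Laplacian system is solved by
sparse Cholesky factorization (`Matrix`); voltages are deterministic to
solver precision (dense-oracle agreement is tested at 1e-8). Node current
is half the sum of absolute incident edge currents — pass-through counted
once — with the active pair's focal nodes reported at the injected 1.0.
Effective resistance is the source voltage. Disconnected pairs are flagged
(infinite resistance, zero current map), never an exception. Barrier cells
stay in the graph at finite resistance 100 — a worst-case but passable
barrier — rather than being removed.

Cumulative current sums the per-pair maps cellwise (three focal regions →
three solves). Corridors are cells *strictly above* the `1 − top_fraction`
quantile of valid cells (default top 10%); the strict inequality follows
the thresholding rule's wording. The connectivity change map is the
cellwise fenced-minus-pre-fencing difference, so loss is negative.

## Restoration scenarios

A corridor scenario buffers its centerline by half the width with flat
caps, realised as one rectangle per centerline segment. Fence removal is
exact: each fence segment is clipped against each rectangle by half-plane
interval intersection, the inside intervals are unioned, and only the
outside remainder is kept; removed length is the unioned inside length.
Parcel-intersection areas use Sutherland–Hodgman clipping against each
rectangle with pairwise inclusion–exclusion for consecutive-rectangle
overlaps; overlaps of non-adjacent rectangles are assumed empty, which
holds unless a centerline doubles back on itself within one corridor width.

Each of the (corridors × widths) scenarios — default widths 0.5, 1, 2, 3 km
— rebuilds the fenced resistance from the post-removal network (including
re-deciding which parcels are still enclosed), re-solves cumulative
current, and reports:

* `improvement = 100·(S_scenario − S_fenced)/(S_pre − S_fenced)` where `S`
  sums cumulative current over the region of interest (ROI). Values above
  100 (a scenario beating the pre-fencing baseline on the ROI) are reported
  as-is.
* cost = Σ area(parcel ∩ corridor, acres) × `unit_cost_per_acre` (default
  US$75), counting only the land portion inside the corridor;
* fence length removed and the number of fence lines touched.

The default ROI is the union of all corridor buffers at the maximum width
plus a 1-km margin. The ROI definition matters: summed node current over a
region that *every* route must cross is nearly invariant to fencing (unit
current must pass any full transect), and longer forced paths can even
raise it. An informative ROI is one the diverted flow can leave.

**Monotonicity.** Pairwise effective resistance is exactly
Rayleigh-monotone: wider corridors (cellwise-lower resistance) can never
increase it, and the test suite asserts this strictly. The ROI-summed
current is *not* an exactly monotone functional of cellwise resistance —
small path-redistribution effects can move it by a fraction of a percentage
point on plateaus — so the improvement-vs-width check allows a 0.1-point
tolerance.

## Validation design

Modeled surfaces (suitability, pre-fencing current, fenced current, change)
are sampled at an independent validation point set (nearest cell; rows off
the grid dropped with a logged count) and contrasted between presences and
pseudo-absences with a per-animal random intercept. Suitability is
logit-transformed (or fit by a beta-family GLMM via `method = "beta"`),
currents are log-transformed with an offset of half the smallest positive
value when zeros occur (recorded in the output), and the signed change map
is fit untransformed. The local scale restricts points to the restoration
ROI; the regional scale uses all points. A constant metric (e.g. a change
map that is identically zero because there are no fences) makes the
contrast undefined and yields an NA row rather than a misleading zero.

## The synthetic study system

`generate_covariates()` builds autocorrelated fields by separable Gaussian
smoothing of white noise (`correlation_length` is the smoothing sigma;
simpler than variogram simulation and sufficient for recovery testing), an
NDVI series of 16-day composites with a seasonal green-up signal, and true
Euclidean distance transforms (via `EBImage::distmap`) from generated
rivers, roads and woody patches. `simulate_trajectories()` uses
gamma-distributed step lengths moment-matched to the requested mean/SD with
uniform turning angles; the defaults (mean 11 km, SD 9 km at 3-h fixes;
validation at 4-h) emulate the tracked-wildebeest step summaries that also
define the pseudo-absence buffers. The source those numbers summarise is a
distribution of per-animal *maximum* step lengths, so treating them as the
kernel's moments is an emulation choice, not an observation. Fences act as
absolute barriers in simulation — candidate steps whose segment crosses a
fence are discarded, and an animal with no legal candidates stays put (a
counter, never an error) — while the analysis layer independently assigns
fences the finite resistance 100.

`simulate_fenced_world()` is the designed end-to-end test system: 50 × 50 km
at 500-m cells, three focal ranges, three sharp one-cell-row east–west
habitat bands of graded quality planted in the wetness layer, an unfenced
"escape" band along the southern boundary, vertical connector bands near
the focal areas, and a 9-km-deep block of 3 × 3-km fenced parcels severing
all three bands. The geometry is chosen so that fencing *diverts* flow onto
the escape route — outside the ROI — rather than merely lengthening paths
through it, reproducing the qualitative signature of a migratory system
rerouted around a fencing front: a large ROI connectivity loss, corridor
restoration gains that grow with width, and the dominant band's corridor as
the best-value intervention. The 500-m cell size is the coarsest at which
the narrowest 0.5-km corridor scenario spans a full cell row under
supercover burning. Bands one row wide avoid funnel consolidation at
corridor mouths, which would otherwise inflate narrow-corridor ROI sums.

What the synthetic world does **not** emulate: real topography and NDVI
phenology, heterogeneous fence permeability (all fences are equally
resistant — a worst case), behavioural states in movement, landowner and
tenure structure in costs, and the true spatial statistics of fence sprawl.
Passing tests demonstrate the pipeline's internal correctness and the
recoverability of planted structure, not field-data effect sizes.

## Problem sizes and numerical choices

The test suite runs circuit oracles on grids up to 8 × 8 against dense
solves (1e-8), Kirchhoff conservation on a 50 × 50 grid (1e-8), the
12-scenario grid on the 100 × 100-cell fenced world, RSF recovery as 20
replicates of 10 animals × 500 steps on 200 × 200-cell landscapes with a
two-stage fit, and the validation sign pattern over 10 pipeline seeds with
reduced sampling (ratio 20, 5 validation animals). Vertex snapping in the
polygonizer uses a 1e-6-m tolerance; interval unions in fence clipping use
1e-12 parameter tolerance; suitability is clamped at machine epsilon before
inversion; all generators are deterministic under `withr::with_seed`.

## Known limitations

* The improvement metric depends on the ROI; regions that all flow must
  cross are uninformative (see above). The package reports the sums used so
  the sensitivity can be examined.
* Current maps are on the unit-injection scale; no normalization precedes
  the top-quantile corridor threshold, and the quantile rule is taken as
  the operative corridor definition.
* Pseudo-absence likelihood weighting is uniform; the offset and weighting
  conventions of point-process RSF formulations are not implemented.
* The polygonizer handles crossing, touching, and collinear-overlapping
  fence segments by noding and deduplication, but degenerate inputs below
  the snapping tolerance are merged.
* No geographic CRS handling anywhere: one projected planar frame in
  metres, and text formats (ESRI ASCII grid, GeoJSON, CSV) for IO.
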