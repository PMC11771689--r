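# fenceflow

Fencing fragments rangelands shared by people and migratory wildlife. For
landscapes like East African savannas, where white-bearded wildebeest move
between seasonal ranges across a mosaic of private parcels, the practical
conservation question is not *whether* fencing reduces connectivity but
*which* fences to remove first, at what cost, and for how much connectivity
gained. `fenceflow` implements that prioritization pipeline end to end for
ecologists and conservation planners:

1. **Habitat selection.** A resource selection function (RSF) contrasts GPS
   presences against pseudo-absences (50 per presence, placed uniformly in a
   disk of radius equal to the animal's maximum observed step length) with a
   logistic mixed model,
   `logit P(use) = β₀ + βᵀx + b_animal`, with quadratic terms for every
   distance covariate. A two-stage per-animal estimator with between-animal
   standard errors is available for serially dependent fixes.
2. **Resistance surface.** Predicted suitability `s ∈ (0,1)` is inverted
   linearly onto `[1, 100]`; fence lines are burned into the raster at
   resistance 100 ("no movement") by supercover rasterization, and land
   parcels fully enclosed by at least three fence lines — detected by
   polygonizing the fence network into a planar arrangement — are filled at
   the barrier value too.
3. **Circuit-theory connectivity.** The raster becomes a resistor network
   (4-neighbour lattice, edge resistance = mean of the two cell
   resistances); focal seasonal ranges are contracted to supernodes, and
   each unordered focal pair is solved as a grounded graph-Laplacian system
   `Lv = I` with one ampere injected. Cumulative current maps sum the pair
   solves; corridors are the top 10% of pixels.
4. **Restoration scenarios.** Candidate corridors × widths (0.5, 1, 2,
   3 km) are simulated by deleting fence segments inside the buffered
   corridor, re-solving connectivity, and scoring each scenario by
   `improvement = 100·(S_scenario − S_fenced)/(S_pre − S_fenced)` over a
   restoration region of interest, against a cost of US$75 per acre of
   enclosed parcel intersecting the corridor.
5. **Validation.** Independent trajectories are tested for higher
   suitability/connectivity at presences than pseudo-absences (mixed models
   on transformed metrics, beta-family GLMM optional), at regional and
   local scales.

A synthetic-landscape generator (autocorrelated covariate fields, NDVI time
series, fence networks enclosing parcels, gamma-kernel movement simulation
from a known selection model) makes every stage testable without any field
data.

## Worked example

Score all twelve fence-removal scenarios on the built-in synthetic study
system — three focal ranges joined by habitat bands, severed by a block of
fenced parcels:

```r
library(fenceflow)

world <- simulate_fenced_world(seed = 1)
suit  <- true_suitability(world$stack, world$true_beta, world$true_intercept)
res   <- suitability_to_resistance(suit)
sc    <- run_scenarios(res, world$fences, world$corridors, world$focal,
                       parcels = world$parcels)
dplyr::select(sc, corridor_id, width_km, fence_km_removed, cost_usd,
              improvement_pct)
#> # A tibble: 12 × 5
#>    corridor_id width_km fence_km_removed cost_usd improvement_pct
#>    <chr>          <dbl>            <dbl>    <dbl>           <dbl>
#>  1 CI               1                  6  166796.           79.3
#>  2 CI               2                 12  333592.           79.4
#>  3 CI               0.5                3   83398.           18.0
#>  4 CIII             1                 24  166796.           29.3
#>  5 CII              1                  6  166796.           27.7
#>  6 CI               3                 36  500388.           80.0
#>  ...
autoplot(sc)   # improvement (%) versus removal cost, labelled by width
```

Rows are sorted by improvement per dollar. In this world fencing removed
45.4% of the cumulative current crossing the restoration region, and a 1-km
corridor along the dominant historic band (CI) restores 79% of that loss
for US$167k — four times the improvement of an equally priced corridor at
either alternative site, the kind of contrast the ranking is built to
expose. `run_pipeline(pipeline_config(seed = 1), out_dir)` runs the whole
chain (simulation → RSF → resistance → connectivity → change map →
scenarios → validation) and writes rasters (ESRI ASCII), GeoJSON, CSVs and
a manifest with file hashes.

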