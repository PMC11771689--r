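Package: fenceflow
Title: Circuit-Theory Connectivity and Fence-Removal Corridor Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for prioritizing fence removal in
    fragmented rangelands. Fits resource selection functions (logistic
    mixed models on GPS presences versus pseudo-absences), predicts
    habitat suitability, inverts it to a movement resistance surface,
    burns fence barriers and enclosed parcels in at a fixed maximum
    resistance, and solves pairwise circuit-theory (Circuitscape-style)
    connectivity between seasonal-range focal regions on a 4-neighbour
    raster graph. Simulated corridor restoration scenarios are scored by
    the fraction of fencing-induced connectivity loss they restore
    against an area-based removal cost. A synthetic-landscape generator
    (autocorrelated covariates, fence networks enclosing parcels, and
    movement trajectories simulated from a known selection model)
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    glmmTMB,
    igraph,
    jsonlite,
    lme4,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
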