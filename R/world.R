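#' Suitability surface implied by a known selection model
#'
#' Cellwise inverse-logit of `intercept + beta . x` over the stack — the
#' ground-truth counterpart of [predict_suitability()] for simulation
#' experiments where the selection coefficients are known.
#'
#' @param stack A `covariate_stack`.
#' @param beta Named coefficient vector on design columns (see
#'   [rsf_design()]).
#' @param intercept Linear-predictor intercept (default -1, giving
#'   moderate background suitability).
#' @return `fw_raster` of suitability in (0, 1).
#' @export
true_suitability <- function(stack, beta, intercept = -1) {
  tmpl <- stack_template(stack)
  cc <- cell_centers(tmpl)
  cov <- extract_covariates(stack, cc$x, cc$y)
  covariates <- unique(sub("2$", "", names(beta)))
  X <- rsf_design(cov, covariates)
  p <- stats::plogis(intercept + as.vector(X[, names(beta)] %*% beta))
  eps <- .Machine$double.eps
  d <- dim(tmpl$values)
  fw_raster(matrix(pmin(pmax(p, eps), 1 - eps), d[1], d[2]),
            tmpl$cell_size, tmpl$origin, tmpl$nodata)
}

#' Synthetic fenced landscape with a known severed corridor system
#'
#' A designed study system for end-to-end experiments, emulating the
#' migratory geometry the analysis targets: three focal regions (western
#' dry-season range, central stepping-stone, eastern wet-season range)
#' joined by one dominant and two weaker east-west high-quality habitat
#' bands (planted in the `twi` covariate layer), plus an unfenced
#' low-quality-margin "escape" band hugging the southern boundary and two
#' vertical connector bands near the focal areas. A block of rectangular
#' fenced parcels severs all three bands between the central and eastern
#' regions, so circuit flow diverts onto the southern escape route —
#' outside the restoration region of interest — and the ROI loses current.
#' Three candidate restoration corridors cross the block, one per band;
#' the dominant band's corridor is the known best restoration target.
#' Ground truth (`true_beta`, `true_intercept`, band geometry) is returned
#' so recovery can be scored.
#'
#' Band centerlines are offset to run through cell centres so that corridor
#' slits align with whole cell rows (the supercover fence rasterization is
#' conservative: the effective open passage of a corridor is about its
#' width minus one cell).
#'
#' @param seed Integer seed (covariate noise).
#' @param grid_shape Grid (nrow, ncol), default 100 x 100.
#' @param cell_size Cell edge in metres, default 500 (so the narrowest
#'   0.5-km corridor scenario spans a full cell row).
#' @return List: `stack`, `fences`, `parcels`, `focal`, `corridors`
#'   (tibble `corridor_id`, `centerline`), `roi`, `true_beta`,
#'   `true_intercept`, `covariates`, `band_y_m`.
#' @export
simulate_fenced_world <- function(seed = 1, grid_shape = c(100, 100),
                                  cell_size = 500) {
  stack <- generate_covariates(grid_shape, cell_size, seed = seed)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  W <- nc * cell_size; H <- nr * cell_size
  mid_cell <- function(v) floor(v / cell_size) * cell_size + cell_size / 2

  # east-west habitat bands (dominant + two alternates), southern escape
  # band, and vertical connectors linking focal areas to every route
  cc <- cell_centers(stack_template(stack))
  band_y <- c(main = mid_cell(0.50 * H), north = mid_cell(0.70 * H),
              south = mid_cell(0.30 * H))
  band_amp <- c(main = 3.0, north = 2.2, south = 2.0)
  band_sd <- cell_size
  tw <- 0.3 * raster_values(stack$layers$twi)
  # sharp one-row channels: the corridor scenarios act on exactly the rows
  # they open, with no shoulder flow to consolidate at the fence faces
  for (b in seq_along(band_y)) {
    tw <- tw + band_amp[b] * (abs(cc$y - band_y[b]) < cell_size / 2)
  }
  escape_y <- mid_cell(0.04 * H)
  tw <- tw + 3.0 * exp(-(cc$y - escape_y)^2 / (2 * band_sd^2))
  for (xc in mid_cell(c(0.06, 0.94) * W)) {
    tw <- tw + 3.0 * exp(-(cc$x - xc)^2 / (2 * band_sd^2))
  }
  tw <- pmin(tw, 3.0)  # plateau band cores rather than stacking at crossings
  tw <- (tw - mean(tw)) / stats::sd(tw)
  stack$layers$twi <- fw_raster(matrix(tw, nr, nc), cell_size,
                                stack_template(stack)$origin)

  focal <- list(
    focal_rect("west", 0.02 * W, 0.10 * W, 0.35 * H, 0.65 * H),
    focal_rect("central", 0.42 * W, 0.50 * W, 0.42 * H, 0.58 * H),
    focal_rect("east", 0.90 * W, 0.98 * W, 0.35 * H, 0.65 * H))

  # block of touching rectangular fenced parcels severing every band
  # between the central and eastern regions; the escape band stays open
  wall_x0 <- 0.58 * W; wall_x1 <- 0.76 * W
  parcel_w <- 3000; parcel_h <- 3000
  x0s <- seq(wall_x0, wall_x1 - parcel_w, by = parcel_w)
  y0s <- seq(0.12 * H, 0.92 * H - parcel_h, by = parcel_h)
  lines <- list()
  for (x0 in x0s) for (y0 in y0s) {
    corners <- rbind(c(x0, y0), c(x0 + parcel_w, y0),
                     c(x0 + parcel_w, y0 + parcel_h), c(x0, y0 + parcel_h))
    for (k in 1:4) {
      lines[[length(lines) + 1L]] <- rbind(corners[k, ], corners[k %% 4 + 1L, ])
    }
  }
  fences <- fence_network(lines)
  parcels <- detect_parcels(fences)

  # one candidate corridor per band, crossing the fenced block
  cor_x <- c(wall_x0 - 4 * cell_size, wall_x1 + 4 * cell_size)
  corridors <- tibble::tibble(
    corridor_id = c("CI", "CII", "CIII"),
    centerline = list(
      rbind(c(cor_x[1], band_y["main"]), c(cor_x[2], band_y["main"])),
      rbind(c(cor_x[1], band_y["north"]), c(cor_x[2], band_y["north"])),
      rbind(c(cor_x[1], band_y["south"]), c(cor_x[2], band_y["south"]))))

  # restoration region of interest: box around the fenced block and all
  # corridors, excluding the boundary strip that carries the diverted flow
  roi <- rbind(c(cor_x[1] - 2 * cell_size, 0.14 * H),
               c(cor_x[2] + 2 * cell_size, 0.14 * H),
               c(cor_x[2] + 2 * cell_size, 0.86 * H),
               c(cor_x[1] - 2 * cell_size, 0.86 * H))

  covariates <- c("twi", "ndvi", "dist_river")
  true_beta <- c(twi = 2.0, ndvi = 0.3, dist_river = -0.1, dist_river2 = 0.0015)

  list(stack = stack, fences = fences, parcels = parcels, focal = focal,
       corridors = corridors, roi = roi, true_beta = true_beta,
       true_intercept = 0.5, covariates = covariates,
       band_y_m = band_y, escape_y_m = escape_y)
}
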