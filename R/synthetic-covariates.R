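# Synthetic landscape generation: spatially autocorrelated covariate fields
# via separable Gaussian smoothing of white noise, plus true Euclidean
# distance transforms from generated river/road/woody features.

# Separable Gaussian smoothing with reflecting boundaries.
gaussian_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  pad_reflect <- function(x, h) {
    n <- nrow(x)
    rbind(x[pmin(h:1, n), , drop = FALSE], x, x[pmax(n - (1:h) + 1, 1), , drop = FALSE])
  }
  conv_rows <- function(x) {
    xp <- pad_reflect(x, half)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

# Standardized autocorrelated field on the grid.
autocorrelated_field <- function(nr, nc, sigma_px) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma_px)
  (f - mean(f)) / stats::sd(f)
}

# Random polyline roughly crossing the grid (used for rivers/roads).
random_crossing_line <- function(bounds, n_vertices = 8, horizontal = NA) {
  if (is.na(horizontal)) horizontal <- stats::runif(1) < 0.5
  w <- bounds$xmax - bounds$xmin; h <- bounds$ymax - bounds$ymin
  if (horizontal) {
    x <- seq(bounds$xmin, bounds$xmax, length.out = n_vertices)
    y <- bounds$ymin + h * stats::runif(1, 0.15, 0.85) +
      cumsum(stats::rnorm(n_vertices, 0, h / 20))
    y <- pmin(pmax(y, bounds$ymin), bounds$ymax)
  } else {
    y <- seq(bounds$ymin, bounds$ymax, length.out = n_vertices)
    x <- bounds$xmin + w * stats::runif(1, 0.15, 0.85) +
      cumsum(stats::rnorm(n_vertices, 0, w / 20))
    x <- pmin(pmax(x, bounds$xmin), bounds$xmax)
  }
  cbind(x, y)
}

# Cells touched by a polyline (supercover; reused by fence burning).
polyline_cells <- function(r, line) {
  n <- nrow(line)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    out[[i]] <- segment_cells(r, line[i, ], line[i + 1L, ])
  }
  unique(do.call(rbind, out))
}

# All cells whose closed square a segment touches, via per-cell
# Liang-Barsky overlap tests restricted to the segment's bounding box.
segment_cells <- function(r, p1, p2) {
  d <- dim(r$values); cs <- r$cell_size; o <- r$origin
  cmin <- max(1L, floor((min(p1[1], p2[1]) - o[1]) / cs) + 1L - 1L)
  cmax <- min(d[2], floor((max(p1[1], p2[1]) - o[1]) / cs) + 1L + 1L)
  rmin <- max(1L, floor((o[2] - max(p1[2], p2[2])) / cs) + 1L - 1L)
  rmax <- min(d[1], floor((o[2] - min(p1[2], p2[2])) / cs) + 1L + 1L)
  if (cmin > cmax || rmin > rmax) return(matrix(integer(0), 0, 2))
  hits <- list(); k <- 0L
  for (rr in rmin:rmax) {
    ytop <- o[2] - (rr - 1L) * cs; ybot <- ytop - cs
    for (cc in cmin:cmax) {
      xl <- o[1] + (cc - 1L) * cs; xr <- xl + cs
      rect <- rbind(c(xl, ybot), c(xr, ybot), c(xr, ytop), c(xl, ytop))
      if (!is.null(clip_segment_convex(p1, p2, rect))) {
        k <- k + 1L; hits[[k]] <- c(rr, cc)
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, hits)
  colnames(m) <- c("row", "col")
  m
}

#' Generate a synthetic covariate stack
#'
#' Builds spatially autocorrelated environmental fields (Gaussian-smoothed
#' white noise at a chosen correlation scale), an NDVI composite series with
#' a seasonal green-up signal, and true Euclidean distance layers from
#' generated river, road, and woody-patch features. Deterministic for a
#' fixed seed.
#'
#' @param grid_shape Integer (nrow, ncol); both >= 3.
#' @param cell_size Cell edge in metres.
#' @param correlation_length Autocorrelation scale in metres
#'   (>= `cell_size`); the Gaussian smoothing sigma of the noise fields.
#' @param n_ndvi_dates Number of 16-day NDVI composites (>= 2).
#' @param seed Integer seed; same seed, same stack.
#' @return A `covariate_stack` with layers `ndvi`, `dndvi`, `twi`,
#'   `footprint`, `dist_woody`, `dist_river`, `dist_road1`, `dist_road2`.
#' @export
generate_covariates <- function(grid_shape = c(50, 50), cell_size = 1000,
                                correlation_length = 5 * cell_size,
                                n_ndvi_dates = 6, seed = 1) {
  stopifnot(length(grid_shape) == 2L, correlation_length >= cell_size,
            n_ndvi_dates >= 2)
  if (any(grid_shape < 3)) stop("degenerate grid: both dimensions must be >= 3")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  withr::with_seed(seed, {
    sig <- correlation_length / cell_size
    tmpl <- fw_raster(matrix(0, nr, nc), cell_size, c(0, nr * cell_size))
    bounds <- list(xmin = 0, xmax = nc * cell_size, ymin = 0, ymax = nr * cell_size)

    twi <- autocorrelated_field(nr, nc, sig)
    footprint <- autocorrelated_field(nr, nc, sig)

    # NDVI: shared spatial base + smooth seasonal green-up through the series
    base <- autocorrelated_field(nr, nc, sig)
    dates <- as.Date("2011-01-01") + 16 * (seq_len(n_ndvi_dates) - 1L)
    phase <- seq(0, pi, length.out = n_ndvi_dates)
    season_amp <- 0.15
    ndvi_rasters <- lapply(seq_len(n_ndvi_dates), function(i) {
      v <- 0.45 + 0.12 * base + season_amp * sin(phase[i]) +
        0.02 * autocorrelated_field(nr, nc, sig)
      fw_raster(pmin(pmax(v, 0.01), 0.99), cell_size, tmpl$origin)
    })
    ndvi_series <- tibble::tibble(date = dates, raster = ndvi_rasters)

    river <- random_crossing_line(bounds, horizontal = TRUE)
    road1 <- random_crossing_line(bounds, horizontal = FALSE)
    road2 <- random_crossing_line(bounds)
    n_woody <- max(3L, round(nr * nc / 400))
    woody_xy <- cbind(stats::runif(n_woody, bounds$xmin, bounds$xmax),
                      stats::runif(n_woody, bounds$ymin, bounds$ymax))
    woody_cells <- cell_index(tmpl, woody_xy[, 1], woody_xy[, 2])

    dist_layer_line <- function(line) {
      distance_raster(tmpl, polyline_cells(tmpl, line))
    }
    layers <- list(
      ndvi = {
        v <- Reduce(`+`, lapply(ndvi_rasters, function(r) r$values)) / n_ndvi_dates
        fw_raster(v, cell_size, tmpl$origin)
      },
      dndvi = fw_raster(ndvi_rasters[[2]]$values - ndvi_rasters[[1]]$values,
                        cell_size, tmpl$origin),
      twi = fw_raster(twi, cell_size, tmpl$origin),
      footprint = fw_raster(footprint, cell_size, tmpl$origin),
      dist_woody = distance_raster(tmpl, cbind(woody_cells$row, woody_cells$col)),
      dist_river = dist_layer_line(river),
      dist_road1 = dist_layer_line(road1),
      dist_road2 = dist_layer_line(road2)
    )
    covariate_stack(layers, ndvi_series,
                    features = list(river = river, road1 = road1,
                                    road2 = road2, woody = woody_xy))
  })
}
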