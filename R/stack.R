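#' Covariate stack
#'
#' Named environmental layers sharing one grid, plus an NDVI time series from
#' which time-matched NDVI and its rate of change (dNDVI) are interpolated.
#' The layer vocabulary mirrors a migratory-ungulate selection model:
#' `ndvi` (series mean), `dndvi` (green-up snapshot), `twi` (topographic
#' wetness), `footprint` (anthropogenic footprint), and Euclidean distance
#' layers `dist_woody`, `dist_river`, `dist_road1`, `dist_road2` (metres).
#'
#' @param layers Named list of `fw_raster`, all on one grid.
#' @param ndvi_series Tibble with `date` (Date) and `raster` (list of
#'   `fw_raster`) giving the NDVI composite series, or `NULL`.
#' @param features Optional list of generator feature geometries (rivers,
#'   roads, woody patches, settlements) kept for provenance.
#' @return A `covariate_stack`.
#' @export
covariate_stack <- function(layers, ndvi_series = NULL, features = list()) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), all(nzchar(names(layers))))
  tmpl <- layers[[1]]
  for (nm in names(layers)) {
    if (!is_fw_raster(layers[[nm]])) stop("layer '", nm, "' is not an fw_raster")
    stop_if_grid_mismatch(tmpl, layers[[nm]], names(layers)[1], nm)
  }
  if (!is.null(ndvi_series)) {
    stopifnot(all(c("date", "raster") %in% names(ndvi_series)))
    ndvi_series <- ndvi_series[order(ndvi_series$date), ]
    for (rr in ndvi_series$raster) stop_if_grid_mismatch(tmpl, rr, "layers", "ndvi_series")
  }
  structure(list(layers = layers, ndvi_series = ndvi_series,
                 features = features),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  d <- dim(x$layers[[1]]$values)
  cat(sprintf("<covariate_stack> %d layers on a %d x %d grid @ %g m\n",
              length(x$layers), d[1], d[2], x$layers[[1]]$cell_size))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (!is.null(x$ndvi_series)) {
    cat(sprintf("  ndvi series: %d composites (%s .. %s)\n",
                nrow(x$ndvi_series), min(x$ndvi_series$date),
                max(x$ndvi_series$date)))
  }
  invisible(x)
}

stack_template <- function(stack) stack$layers[[1]]

stack_cell_size <- function(stack) stack$layers[[1]]$cell_size

stack_bounds <- function(stack) {
  r <- stack_template(stack)
  d <- dim(r$values)
  list(xmin = r$origin[1], xmax = r$origin[1] + d[2] * r$cell_size,
       ymin = r$origin[2] - d[1] * r$cell_size, ymax = r$origin[2])
}

# NDVI interpolated between the two nearest composite dates for a timestamp;
# dNDVI = difference between those two nearest composites (rate of change).
ndvi_at_time <- function(stack, row, col, time) {
  ser <- stack$ndvi_series
  if (is.null(ser) || nrow(ser) < 2L) {
    stop("covariate stack has no NDVI series with >= 2 dates")
  }
  dates <- as.numeric(ser$date)
  t <- as.numeric(as.Date(time))
  t <- pmin(pmax(t, min(dates)), max(dates))
  i2 <- pmax(2L, findInterval(t, dates, rightmost.closed = TRUE) + 1L)
  i2 <- pmin(i2, length(dates))
  i1 <- i2 - 1L
  w <- (t - dates[i1]) / (dates[i2] - dates[i1])
  idx <- cbind(row, col)
  v1 <- vapply(seq_along(row), function(k) ser$raster[[i1[k]]]$values[row[k], col[k]], numeric(1))
  v2 <- vapply(seq_along(row), function(k) ser$raster[[i2[k]]]$values[row[k], col[k]], numeric(1))
  list(ndvi = (1 - w) * v1 + w * v2, dndvi = v2 - v1)
}

#' Long-term mean NDVI raster of the series
#' @param stack A `covariate_stack`.
#' @export
ndvi_series_mean <- function(stack) {
  ser <- stack$ndvi_series
  stopifnot(!is.null(ser))
  tmpl <- stack_template(stack)
  v <- Reduce(`+`, lapply(ser$raster, function(r) r$values)) / nrow(ser)
  fw_raster(v, tmpl$cell_size, tmpl$origin, tmpl$nodata)
}

#' NDVI rate-of-change raster at a named snapshot date
#' @param stack A `covariate_stack`.
#' @param date Snapshot date; the difference between the composite at or
#'   after `date` and the preceding composite.
#' @export
ndvi_change_snapshot <- function(stack, date) {
  ser <- stack$ndvi_series
  stopifnot(!is.null(ser), nrow(ser) >= 2L)
  dates <- as.numeric(ser$date)
  t <- as.numeric(as.Date(date))
  i2 <- max(2L, min(findInterval(t, dates, rightmost.closed = TRUE) + 1L, nrow(ser)))
  tmpl <- stack_template(stack)
  fw_raster(ser$raster[[i2]]$values - ser$raster[[i2 - 1L]]$values,
            tmpl$cell_size, tmpl$origin, tmpl$nodata)
}
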