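#' Gridded raster surface
#'
#' The lingua franca between pipeline stages: a single-band numeric grid in
#' a projected planar frame (metres). Row 1 is the northernmost row and
#' `origin` is the (x, y) of the grid's *upper-left* corner, so the centre of
#' cell `[r, c]` sits at `origin + ((c - 0.5) * cell_size, -(r - 0.5) *
#' cell_size)`.
#'
#' @param values Numeric matrix of cell values.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Length-2 numeric, (x, y) of the upper-left grid corner.
#' @param nodata Sentinel value marking invalid cells; `NA` cells are always
#'   treated as nodata.
#' @return An object of class `fw_raster`.
#' @export
fw_raster <- function(values, cell_size, origin = c(0, 0), nodata = NA_real_) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L, all(is.finite(origin)))
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("raster must have at least one row and one column")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = nodata),
    class = "fw_raster"
  )
}

#' @export
print.fw_raster <- function(x, ...) {
  v <- raster_values(x)
  cat(sprintf("<fw_raster> %d x %d cells @ %g m\n", nrow(x$values),
              ncol(x$values), x$cell_size))
  cat(sprintf("  origin (UL): (%g, %g)\n", x$origin[1], x$origin[2]))
  if (any(is.finite(v))) {
    cat(sprintf("  values: [%g, %g], %d valid of %d cells\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                sum(is.finite(v)), length(v)))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

is_fw_raster <- function(x) inherits(x, "fw_raster")

#' Cell values with nodata replaced by NA
#' @param r An `fw_raster`.
#' @return Numeric matrix; nodata cells are `NA`.
#' @export
raster_values <- function(r) {
  v <- r$values
  if (!is.na(r$nodata)) v[v == r$nodata] <- NA_real_
  v
}

raster_dim <- function(r) dim(r$values)

#' @export
dim.fw_raster <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_grid_mismatch <- function(a, b, what_a = "first raster",
                                  what_b = "second raster") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch between %s and %s (shape/cell_size/origin)",
                 what_a, what_b), call. = FALSE)
  }
  invisible(TRUE)
}

#' Coordinates of every cell centre
#' @param r An `fw_raster`.
#' @return Tibble with `row`, `col`, `x`, `y` (one row per cell, column-major).
#' @export
cell_centers <- function(r) {
  d <- dim(r$values)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  tibble::tibble(
    row = rc$row, col = rc$col,
    x = r$origin[1] + (rc$col - 0.5) * r$cell_size,
    y = r$origin[2] - (rc$row - 0.5) * r$cell_size
  )
}

#' Map point coordinates to raster row/col indices (nearest cell)
#' @param r An `fw_raster`.
#' @param x,y Point coordinates in metres.
#' @return Tibble with `row`, `col`; `NA` for points outside the grid extent.
#' @export
cell_index <- function(r, x, y) {
  d <- dim(r$values)
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  # points exactly on the outer east/south edge belong to the last cell
  col[x == r$origin[1] + d[2] * r$cell_size] <- d[2]
  row[y == r$origin[2] - d[1] * r$cell_size] <- d[1]
  bad <- row < 1L | row > d[1] | col < 1L | col > d[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Sample raster values at point locations (nearest cell)
#' @inheritParams cell_index
#' @return Numeric vector; `NA` outside the grid or on nodata cells.
#' @export
raster_extract <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  v <- raster_values(r)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- v[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Tidy a raster into a tibble of cell centres and values
#' @param x An `fw_raster`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.fw_raster <- function(x, ...) {
  cc <- cell_centers(x)
  cc$value <- as.vector(raster_values(x))
  cc
}

#' Is a point inside the raster's rectangular extent?
#' @inheritParams cell_index
#' @return Logical vector.
#' @export
in_bounds <- function(r, x, y) {
  d <- dim(r$values)
  x >= r$origin[1] & x <= r$origin[1] + d[2] * r$cell_size &
    y <= r$origin[2] & y >= r$origin[2] - d[1] * r$cell_size
}

#' Exact Euclidean distance raster from feature cells
#'
#' Distance (metres) from each cell centre to the nearest cell belonging to a
#' feature (river, road, woody patch...). Feature cells themselves are 0.
#'
#' @param r Template `fw_raster` (grid geometry reused).
#' @param feature_cells Two-column matrix/data frame of (row, col) indices.
#' @return `fw_raster` of distances in metres.
#' @export
distance_raster <- function(r, feature_cells) {
  d <- dim(r$values)
  feature_cells <- as.matrix(feature_cells)
  if (nrow(feature_cells) == 0L) {
    stop("distance_raster needs at least one feature cell")
  }
  m <- matrix(1, d[1], d[2])
  m[feature_cells] <- 0
  dist_px <- EBImage::distmap(m, metric = "euclidean")
  fw_raster(as.matrix(dist_px) * r$cell_size, r$cell_size, r$origin, r$nodata)
}

#' Arithmetic on rasters sharing one grid
#' @param e1,e2 `fw_raster` or numeric scalar.
#' @export
Ops.fw_raster <- function(e1, e2) {
  if (is_fw_raster(e1) && is_fw_raster(e2)) {
    stop_if_grid_mismatch(e1, e2)
    v <- get(.Generic)(raster_values(e1), raster_values(e2))
    tmpl <- e1
  } else if (is_fw_raster(e1)) {
    v <- get(.Generic)(raster_values(e1), e2)
    tmpl <- e1
  } else {
    v <- get(.Generic)(e1, raster_values(e2))
    tmpl <- e2
  }
  fw_raster(v, tmpl$cell_size, tmpl$origin, NA_real_)
}
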