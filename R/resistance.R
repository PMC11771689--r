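#' Convert suitability to movement resistance
#'
#' Inverts the suitability surface onto a resistance scale whose maximum is
#' the fence barrier value: the default is the linear map
#' `r = r_max - (r_max - r_min) * s`, strictly decreasing in suitability,
#' with `s = 1 -> r_min` and `s = 0 -> r_max`. A reciprocal variant
#' (`r = 1/s` rescaled into `[r_min, r_max]`) is available behind
#' `method = "reciprocal"`.
#'
#' @param s Suitability `fw_raster` with values in (0, 1).
#' @param r_min,r_max Resistance bounds, `0 < r_min < r_max`
#'   (defaults 1 and 100).
#' @param method `"linear"` (default) or `"reciprocal"`.
#' @return Resistance `fw_raster` in `[r_min, r_max]`; metadata attribute
#'   `mapping` records the method used.
#' @export
suitability_to_resistance <- function(s, r_min = 1, r_max = 100,
                                      method = c("linear", "reciprocal")) {
  method <- match.arg(method)
  stopifnot(r_min > 0, r_min < r_max)
  v <- raster_values(s)
  valid <- !is.na(v)
  if (any(v[valid] <= 0 | v[valid] >= 1)) {
    stop("suitability values must lie strictly in (0, 1); clamp before inverting")
  }
  if (!all(is.finite(v[valid]))) stop("non-finite suitability in valid cells")
  r <- v
  if (method == "linear") {
    r[valid] <- r_max - (r_max - r_min) * v[valid]
  } else {
    inv <- 1 / v[valid]
    r[valid] <- r_min + (r_max - r_min) *
      (inv - min(inv)) / max(max(inv) - min(inv), .Machine$double.eps)
  }
  out <- fw_raster(r, s$cell_size, s$origin, s$nodata)
  attr(out, "mapping") <- method
  out
}

#' Burn fences into a resistance surface as near-absolute barriers
#'
#' Every cell whose square is touched by a fence polyline (supercover
#' rasterization — conservative for a barrier), and every cell inside a
#' fully enclosed parcel, is set to `barrier_value`; all other cells are
#' left bit-exactly unchanged. Idempotent; an empty network returns the
#' raster unchanged.
#'
#' @param r Resistance `fw_raster`.
#' @param fences A `fence_network`.
#' @param barrier_value Barrier resistance (default 100, "no movement").
#' @param fill_enclosed Also fill the interiors of enclosed parcels
#'   detected from the network (default TRUE).
#' @param parcels Optional pre-computed parcel list (from
#'   [detect_parcels()]) to avoid re-detection.
#' @return Resistance `fw_raster` with barriers burned in.
#' @export
burn_fences <- function(r, fences, barrier_value = 100, fill_enclosed = TRUE,
                        parcels = NULL) {
  if (nrow(fences) == 0L) return(r)
  v <- r$values
  for (line in fences$geometry) {
    cells <- polyline_cells(r, line)
    if (nrow(cells)) v[cells] <- barrier_value
  }
  if (fill_enclosed) {
    if (is.null(parcels)) parcels <- detect_parcels(fences)
    if (length(parcels)) {
      cc <- cell_centers(r)
      for (p in parcels) {
        inside <- point_in_polygon(cc$x, cc$y, p$polygon)
        if (any(inside)) v[cbind(cc$row[inside], cc$col[inside])] <- barrier_value
      }
    }
  }
  fw_raster(v, r$cell_size, r$origin, r$nodata)
}
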