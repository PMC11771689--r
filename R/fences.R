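#' Fence network
#'
#' A set of fence polylines in projected metres, the barrier layer of the
#' analysis. Stored as a tibble with one row per polyline: an `id` column and
#' a `geometry` list-column of two-column coordinate matrices.
#'
#' @param lines List of two-column matrices (x, y vertices, >= 2 each).
#' @param id Optional character ids (defaults to `"F1"`, `"F2"`, ...).
#' @return A `fence_network` tibble.
#' @export
fence_network <- function(lines = list(), id = NULL) {
  lines <- lapply(lines, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 2L || nrow(m) < 2L) {
      stop("each fence polyline needs a two-column matrix with >= 2 vertices")
    }
    if (!all(is.finite(m))) stop("fence polyline coordinates must be finite")
    unname(m)
  })
  if (is.null(id)) id <- if (length(lines)) paste0("F", seq_along(lines)) else character()
  stopifnot(length(id) == length(lines), !anyDuplicated(id))
  out <- tibble::tibble(id = as.character(id), geometry = lines)
  class(out) <- c("fence_network", class(out))
  out
}

#' @export
print.fence_network <- function(x, ...) {
  cat(sprintf("<fence_network> %d polylines, total length %.2f km\n",
              nrow(x), total_fence_length(x) / 1000))
  invisible(x)
}

polyline_length <- function(m) {
  if (nrow(m) < 2L) return(0)
  sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

#' Total length of all fence polylines (metres)
#' @param fences A `fence_network`.
#' @export
total_fence_length <- function(fences) {
  if (nrow(fences) == 0L) return(0)
  sum(vapply(fences$geometry, polyline_length, numeric(1)))
}

# Flatten a network to a segment table: matrix x1,y1,x2,y2 plus line index.
fence_segments <- function(fences) {
  if (nrow(fences) == 0L) {
    return(list(segs = matrix(numeric(0), 0, 4), line = integer(0)))
  }
  pieces <- lapply(seq_len(nrow(fences)), function(i) {
    m <- fences$geometry[[i]]
    n <- nrow(m)
    cbind(m[-n, 1], m[-n, 2], m[-1, 1], m[-1, 2], i)
  })
  all <- do.call(rbind, pieces)
  list(segs = all[, 1:4, drop = FALSE], line = as.integer(all[, 5]))
}

#' Focal region
#'
#' A named polygon between which circuit connectivity is computed; in the
#' study design these are seasonal ranges or stepping-stone conservancies.
#'
#' @param name Region name.
#' @param polygon Two-column vertex matrix (metres).
#' @return A `focal_region` list.
#' @export
focal_region <- function(name, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(is.character(name), length(name) == 1L, ncol(polygon) == 2L,
            nrow(polygon) >= 3L, all(is.finite(polygon)))
  structure(list(name = name, polygon = unname(polygon)),
            class = "focal_region")
}

#' Axis-aligned rectangular focal region helper
#' @param name Region name.
#' @param xmin,xmax,ymin,ymax Rectangle bounds in metres.
#' @export
focal_rect <- function(name, xmin, xmax, ymin, ymax) {
  focal_region(name, rbind(c(xmin, ymin), c(xmax, ymin),
                           c(xmax, ymax), c(xmin, ymax)))
}
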