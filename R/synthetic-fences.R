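#' Generate a synthetic fence network
#'
#' Places `n_parcels` rectangular fenced parcels (four fence lines each, so
#' every parcel is enclosed by at least three distinct lines) biased towards
#' high-suitability cells — mirroring the tendency of fencing to appear on
#' land that is also good wildebeest habitat — plus open "distractor"
#' polylines that enclose nothing.
#'
#' @param stack A `covariate_stack` (grid and suitability proxy source).
#' @param n_parcels Number of enclosed parcels (>= 0).
#' @param suitability Optional `fw_raster` used for placement bias; defaults
#'   to the stack's mean-NDVI layer.
#' @param n_distractors Number of open polylines (default 3).
#' @param seed Integer seed.
#' @return A `fence_network`; the generated ground-truth parcel rectangles
#'   are attached as `attr(,"truth_parcels")` (list of vertex matrices).
#' @export
generate_fences <- function(stack, n_parcels, suitability = NULL,
                            n_distractors = 3, seed = 1) {
  stopifnot(n_parcels >= 0)
  tmpl <- stack_template(stack)
  d <- dim(tmpl$values); cs <- tmpl$cell_size
  capacity <- floor((d[1] * d[2]) / 64)
  if (n_parcels > capacity) {
    stop(sprintf("n_parcels = %d exceeds grid capacity (%d) for this %d x %d grid",
                 n_parcels, capacity, d[1], d[2]))
  }
  if (is.null(suitability)) suitability <- stack$layers$ndvi
  withr::with_seed(seed, {
    bounds <- stack_bounds(stack)
    cc <- cell_centers(tmpl)
    s <- as.vector(raster_values(suitability))
    ok <- is.finite(s)
    # candidate centres: top 30% suitability, away from the landscape edge
    margin <- 4 * cs
    edge_ok <- cc$x > bounds$xmin + margin & cc$x < bounds$xmax - margin &
      cc$y > bounds$ymin + margin & cc$y < bounds$ymax - margin
    thr <- stats::quantile(s[ok], 0.7)
    cand <- which(ok & edge_ok & s >= thr)
    if (length(cand) == 0L) cand <- which(ok & edge_ok)
    lines <- list(); truth <- list()
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (length(truth) < n_parcels && tries < 2000L) {
      tries <- tries + 1L
      i <- sample(cand, 1L)
      w <- stats::runif(1, 2, 5) * cs; h <- stats::runif(1, 2, 5) * cs
      cx <- cc$x[i]; cy <- cc$y[i]
      if (nrow(centres) > 0 &&
          any(abs(centres[, 1] - cx) < (w + 5 * cs) &
              abs(centres[, 2] - cy) < (h + 5 * cs))) next
      x0 <- cx - w / 2; x1 <- cx + w / 2; y0 <- cy - h / 2; y1 <- cy + h / 2
      if (x0 < bounds$xmin || x1 > bounds$xmax ||
          y0 < bounds$ymin || y1 > bounds$ymax) next
      corners <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
      # one fence line per side: every parcel bounded by 4 distinct lines
      for (k in 1:4) {
        lines[[length(lines) + 1L]] <- rbind(corners[k, ], corners[k %% 4 + 1L, ])
      }
      truth[[length(truth) + 1L]] <- corners
      centres <- rbind(centres, c(cx, cy))
    }
    if (length(truth) < n_parcels) {
      stop("could not place the requested parcels without overlap; lower n_parcels")
    }
    # open zig-zag distractor fences; rejected if they cross anything
    # already placed, so they can never close off an extra face
    existing_segs <- function() {
      if (!length(lines)) return(NULL)
      fence_segments(fence_network(lines))$segs
    }
    placed <- 0L; tries <- 0L
    while (placed < n_distractors && tries < 500L) {
      tries <- tries + 1L
      x <- stats::runif(1, bounds$xmin + margin, bounds$xmax - margin)
      y <- stats::runif(1, bounds$ymin + margin, bounds$ymax - margin)
      nv <- sample(3:5, 1)
      steps <- matrix(stats::rnorm(2 * (nv - 1), 0, 3 * cs), ncol = 2)
      pts <- rbind(c(x, y), c(x, y) + apply(steps, 2, cumsum))
      pts[, 1] <- pmin(pmax(pts[, 1], bounds$xmin), bounds$xmax)
      pts[, 2] <- pmin(pmax(pts[, 2], bounds$ymin), bounds$ymax)
      segs <- existing_segs()
      crosses <- FALSE
      for (k in seq_len(nrow(pts) - 1L)) {
        if (crosses_any_segment(pts[k, 1], pts[k, 2], pts[k + 1L, 1],
                                pts[k + 1L, 2], segs)) {
          crosses <- TRUE
          break
        }
      }
      # a zig-zag can also self-intersect and enclose a face on its own
      self_cross <- FALSE
      if (nrow(pts) >= 4L) {
        for (k in seq_len(nrow(pts) - 3L)) {
          for (k2 in (k + 2L):(nrow(pts) - 1L)) {
            if (segments_cross(pts[k, ], pts[k + 1L, ], pts[k2, ], pts[k2 + 1L, ])) {
              self_cross <- TRUE
            }
          }
        }
      }
      if (crosses || self_cross) next
      lines[[length(lines) + 1L]] <- pts
      placed <- placed + 1L
    }
    net <- fence_network(lines)
    attr(net, "truth_parcels") <- truth
    net
  })
}
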