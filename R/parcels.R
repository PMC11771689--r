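# Enclosed-parcel detection: nodes the fence polylines into a planar
# arrangement, trims dangling edges, and walks half-edge cycles to extract
# bounded faces. A bounded face is a fenced parcel when its boundary uses at
# least `min_bounding_lines` distinct original fence lines, or when it lies
# fully inside another parcel (nested-parcel rule).

ACRE_M2 <- 4046.8564224

# Split all fence segments at mutual intersections and at other segments'
# endpoints lying on them (T-junctions, collinear overlaps), then dedupe.
node_segments <- function(fences, snap = 1e-6) {
  fs <- fence_segments(fences)
  segs <- fs$segs; line <- fs$line
  n <- nrow(segs)
  if (n == 0L) return(list(edges = matrix(numeric(0), 0, 4), lines = list()))
  endpoints <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- segs[i, 1:2]; p2 <- segs[i, 3:4]
    ts <- c(0, 1)
    for (j in seq_len(n)) {
      if (i == j) next
      hit <- seg_intersection(p1, p2, segs[j, 1:2], segs[j, 3:4])
      if (!is.null(hit)) ts <- c(ts, hit$t)
    }
    # endpoints of other segments lying on this one (covers collinear overlap)
    d <- p2 - p1; len2 <- sum(d^2)
    t_pt <- ((endpoints[, 1] - p1[1]) * d[1] + (endpoints[, 2] - p1[2]) * d[2]) / len2
    on_seg <- t_pt > 1e-9 & t_pt < 1 - 1e-9 &
      dist_point_segment(endpoints[, 1], endpoints[, 2],
                         p1[1], p1[2], p2[1], p2[2]) < snap
    ts <- sort(unique(round(c(ts, t_pt[on_seg]), 12)))
    ts <- ts[ts >= 0 & ts <= 1]
    m <- length(ts) - 1L
    sub <- matrix(NA_real_, m, 5)
    for (k in seq_len(m)) {
      a <- p1 + ts[k] * d; b <- p1 + ts[k + 1L] * d
      sub[k, ] <- c(a, b, line[i])
    }
    pieces[[i]] <- sub
  }
  all <- do.call(rbind, pieces)
  # snap vertices and drop zero-length pieces
  key <- function(x, y) paste(round(x / snap), round(y / snap))
  k1 <- key(all[, 1], all[, 2]); k2 <- key(all[, 3], all[, 4])
  keep <- k1 != k2
  all <- all[keep, , drop = FALSE]; k1 <- k1[keep]; k2 <- k2[keep]
  ekey <- ifelse(k1 < k2, paste(k1, "|", k2), paste(k2, "|", k1))
  lines_by_edge <- split(as.integer(all[, 5]), ekey)
  first <- !duplicated(ekey)
  list(edges = all[first, 1:4, drop = FALSE],
       lines = lapply(lines_by_edge[ekey[first]], unique),
       snap = snap)
}

#' Detect enclosed land parcels from a fence network
#'
#' Nodes all polylines into a planar arrangement (crossing lines are noded
#' automatically, never an error), extracts bounded faces by half-edge cycle
#' traversal, and reports each face as a fenced `Parcel` when its boundary
#' uses at least `min_bounding_lines` distinct original fence lines. Faces
#' lying fully inside a larger detected parcel are parcels as well (a
#' nested paddock still has to be de-fenced). Open polylines and dangling
#' spurs enclose nothing and are trimmed before traversal.
#'
#' @param fences A `fence_network`.
#' @param min_bounding_lines Minimum distinct bounding fence lines
#'   (default 3).
#' @return List of parcels, each a list with `id`, `polygon` (CCW vertex
#'   matrix), `area_m2`, `area_acres`, `bounding_lines` (fence ids),
#'   `fully_enclosed`.
#' @export
detect_parcels <- function(fences, min_bounding_lines = 3) {
  if (nrow(fences) == 0L) return(list())
  nd <- node_segments(fences)
  if (nrow(nd$edges) == 0L) return(list())
  snap <- nd$snap
  key <- function(x, y) paste(round(x / snap), round(y / snap))
  vkey <- unique(c(key(nd$edges[, 1], nd$edges[, 2]),
                   key(nd$edges[, 3], nd$edges[, 4])))
  vid <- stats::setNames(seq_along(vkey), vkey)
  v1 <- vid[key(nd$edges[, 1], nd$edges[, 2])]
  v2 <- vid[key(nd$edges[, 3], nd$edges[, 4])]
  # coordinates of each vertex (first occurrence)
  vx <- vy <- numeric(length(vid))
  vx[v1] <- nd$edges[, 1]; vy[v1] <- nd$edges[, 2]
  vx[v2] <- nd$edges[, 3]; vy[v2] <- nd$edges[, 4]

  edges <- cbind(v1, v2)
  lines <- nd$lines
  # trim dangles: iteratively drop edges touching a degree-1 vertex
  repeat {
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(vid))
    drop <- deg[edges[, 1]] < 2 | deg[edges[, 2]] < 2
    if (!any(drop)) break
    edges <- edges[!drop, , drop = FALSE]
    lines <- lines[!drop]
    if (nrow(edges) == 0L) return(list())
  }

  ne <- nrow(edges)
  # half-edges: 1..ne are v1->v2, ne+1..2ne are v2->v1
  he_from <- c(edges[, 1], edges[, 2])
  he_to <- c(edges[, 2], edges[, 1])
  he_edge <- c(seq_len(ne), seq_len(ne))
  twin <- c(ne + seq_len(ne), seq_len(ne))
  ang <- atan2(vy[he_to] - vy[he_from], vx[he_to] - vx[he_from])
  # at each vertex, outgoing half-edges sorted CCW by angle
  out_by_v <- split(seq_len(2L * ne), he_from)
  nxt <- integer(2L * ne)
  for (v in names(out_by_v)) {
    hs <- out_by_v[[v]]
    hs <- hs[order(ang[hs])]
    # incoming half-edge h arrives at v; its twin is outgoing at v.
    # next(h) = outgoing edge immediately clockwise of twin(h).
    for (i in seq_along(hs)) {
      h_out <- hs[i]
      prev_cw <- hs[if (i == 1L) length(hs) else i - 1L]
      # for the half-edge whose twin is h_out, the cycle continues on prev_cw
      nxt[twin[h_out]] <- prev_cw
    }
  }

  used <- logical(2L * ne)
  faces <- list()
  for (h0 in seq_len(2L * ne)) {
    if (used[h0]) next
    cyc <- integer(0); h <- h0
    repeat {
      used[h] <- TRUE
      cyc <- c(cyc, h)
      h <- nxt[h]
      if (h == h0) break
    }
    verts <- cbind(vx[he_from[cyc]], vy[he_from[cyc]])
    a <- polygon_area(verts)
    if (a > snap^2) {
      faces[[length(faces) + 1L]] <- list(
        polygon = verts, area_m2 = a,
        line_idx = sort(unique(unlist(lines[he_edge[cyc]]))))
    }
  }
  if (!length(faces)) return(list())

  n_lines <- vapply(faces, function(f) length(f$line_idx), integer(1))
  is_parcel <- n_lines >= min_bounding_lines
  # nested rule: a face inside an already-accepted parcel is a parcel too
  if (any(is_parcel) && any(!is_parcel)) {
    for (i in which(!is_parcel)) {
      pt <- polygon_interior_point(faces[[i]]$polygon)
      for (j in which(is_parcel)) {
        if (faces[[j]]$area_m2 > faces[[i]]$area_m2 &&
            point_in_polygon(pt[1], pt[2], faces[[j]]$polygon)) {
          is_parcel[i] <- TRUE
          break
        }
      }
    }
  }
  kept <- faces[is_parcel]
  lapply(seq_along(kept), function(i) {
    f <- kept[[i]]
    list(id = sprintf("P%d", i), polygon = f$polygon,
         area_m2 = f$area_m2, area_acres = f$area_m2 / ACRE_M2,
         bounding_lines = fences$id[f$line_idx], fully_enclosed = TRUE)
  })
}

#' Tidy parcel list into a tibble
#' @param parcels Output of [detect_parcels()].
#' @return Tibble with `id`, `area_m2`, `area_acres`, `n_bounding_lines`.
#' @export
parcels_tibble <- function(parcels) {
  tibble::tibble(
    id = vapply(parcels, `[[`, character(1), "id"),
    area_m2 = vapply(parcels, `[[`, numeric(1), "area_m2"),
    area_acres = vapply(parcels, `[[`, numeric(1), "area_acres"),
    n_bounding_lines = vapply(parcels, function(p) length(p$bounding_lines),
                              integer(1)))
}
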