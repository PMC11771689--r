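# Planar computational-geometry primitives shared by the fence, parcel and
# corridor machinery. All coordinates are projected metres. These are the
# operations for which no pre-installed R package provides a vector-geometry
# engine, so they are implemented here directly.

#' Signed area of a polygon (shoelace)
#' @param poly Two-column matrix of vertices (closed or open ring).
#' @return Signed area; positive for counter-clockwise rings.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(0)
  # drop duplicated closing vertex
  if (isTRUE(all.equal(poly[1, ], poly[n, ], check.attributes = FALSE))) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
    if (n < 3L) return(0)
  }
  j <- c(2:n, 1L)
  sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
}

#' Even-odd point-in-polygon test
#' @param px,py Point coordinates (vectorized).
#' @param poly Two-column vertex matrix (open ring).
#' @return Logical vector; points exactly on the boundary may fall either way.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1, ], poly[n, ], check.attributes = FALSE))) {
    poly <- poly[-n, , drop = FALSE]; n <- n - 1L
  }
  inside <- logical(length(px))
  xv <- poly[, 1]; yv <- poly[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yv[i] > py) != (yv[j] > py)) &
      (px < (xv[j] - xv[i]) * (py - yv[i]) / (yv[j] - yv[i]) + xv[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Intersection of segments p1-p2 and p3-p4 including endpoint touches.
# Returns NULL or list(t = param on p1-p2, u = param on p3-p4, pt = point).
# Collinear overlaps return NULL (handled separately by the noding step).
seg_intersection <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  scale <- max(abs(c(d1, d2)), 1)
  if (abs(denom) < eps * scale^2) return(NULL)
  w <- p3 - p1
  t <- (w[1] * d2[2] - w[2] * d2[1]) / denom
  u <- (w[1] * d1[2] - w[2] * d1[1]) / denom
  tol <- 1e-9
  if (t < -tol || t > 1 + tol || u < -tol || u > 1 + tol) return(NULL)
  t <- min(max(t, 0), 1); u <- min(max(u, 0), 1)
  list(t = t, u = u, pt = p1 + t * d1)
}

# Do two segments cross or touch? (used for fence-blocking in movement sim)
segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sc <- max(abs(c(b - a, c - a)), 1)
    if (abs(v) < 1e-12 * sc^2) 0 else sign(v)
  }
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-9 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-9 &&
      min(a[2], b[2]) - 1e-9 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-9
  }
  (o1 == 0 && on_seg(p1, p2, p3)) || (o2 == 0 && on_seg(p1, p2, p4)) ||
    (o3 == 0 && on_seg(p3, p4, p1)) || (o4 == 0 && on_seg(p3, p4, p2))
}

# Vectorized: does segment a-b cross ANY segment of a fence network's
# pre-extracted segment table (matrix with columns x1,y1,x2,y2)?
crosses_any_segment <- function(ax, ay, bx, by, segs) {
  if (is.null(segs) || nrow(segs) == 0L) return(FALSE)
  x1 <- segs[, 1]; y1 <- segs[, 2]; x2 <- segs[, 3]; y2 <- segs[, 4]
  d1x <- bx - ax; d1y <- by - ay
  d2x <- x2 - x1; d2y <- y2 - y1
  wx <- x1 - ax; wy <- y1 - ay
  denom <- d1x * d2y - d1y * d2x
  t <- (wx * d2y - wy * d2x) / denom
  u <- (wx * d1y - wy * d1x) / denom
  hit <- abs(denom) > 1e-12 & t >= 0 & t <= 1 & u >= 0 & u <= 1
  any(hit, na.rm = TRUE)
}

# Parametric interval [t0, t1] of segment p1-p2 lying inside a CONVEX
# counter-clockwise polygon (generalized Liang-Barsky). NULL when disjoint.
clip_segment_convex <- function(p1, p2, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  t0 <- 0; t1 <- 1
  d <- p2 - p1
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    # inward normal of CCW edge a->b
    nx <- -(b[2] - a[2]); ny <- b[1] - a[1]
    denom <- nx * d[1] + ny * d[2]
    num <- nx * (p1[1] - a[1]) + ny * (p1[2] - a[2])
    if (abs(denom) < 1e-14) {
      if (num < -1e-9) return(NULL)   # parallel and outside
    } else {
      t_hit <- -num / denom
      if (denom > 0) t0 <- max(t0, t_hit) else t1 <- min(t1, t_hit)
      if (t0 > t1 + 1e-12) return(NULL)
    }
  }
  if (t0 > t1) return(NULL)
  c(t0, t1)
}

# Sutherland-Hodgman: clip an arbitrary simple polygon against a CONVEX
# counter-clockwise polygon. Returns vertex matrix (possibly degenerate) or
# NULL. The signed area of the result equals the true intersection area.
clip_polygon_convex <- function(subject, clip) {
  subject <- as.matrix(subject); clip <- as.matrix(clip)
  if (polygon_area(subject) < 0) subject <- subject[rev(seq_len(nrow(subject))), , drop = FALSE]
  out <- subject
  nC <- nrow(clip)
  for (i in seq_len(nC)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nC) 1L else i + 1L, ]
    nx <- -(b[2] - a[2]); ny <- b[1] - a[1]   # inward normal (CCW clip)
    side <- (out[, 1] - a[1]) * nx + (out[, 2] - a[2]) * ny
    nS <- nrow(out)
    new_pts <- vector("list", 2L * nS)
    k <- 0L
    for (s in seq_len(nS)) {
      s2 <- if (s == nS) 1L else s + 1L
      cur_in <- side[s] >= -1e-12; nxt_in <- side[s2] >= -1e-12
      if (cur_in) { k <- k + 1L; new_pts[[k]] <- out[s, ] }
      if (cur_in != nxt_in) {
        t <- side[s] / (side[s] - side[s2])
        k <- k + 1L
        new_pts[[k]] <- out[s, ] + t * (out[s2, ] - out[s, ])
      }
    }
    out <- if (k >= 3L) do.call(rbind, new_pts[seq_len(k)]) else NULL
  }
  out
}

# Area of intersection between a simple polygon and a convex polygon.
polygon_clip_area <- function(subject, clip) {
  res <- clip_polygon_convex(subject, clip)
  if (is.null(res)) 0 else abs(polygon_area(res))
}

# Distance from points to a segment a-b (vectorized over points).
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  if (len2 < 1e-20) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# A representative interior point of a simple polygon (scanline midpoint).
polygon_interior_point <- function(poly) {
  poly <- as.matrix(poly)
  ys <- sort(unique(poly[, 2]))
  # horizontal line through the middle of the widest vertical gap of vertices
  if (length(ys) < 2L) return(colMeans(poly))
  gaps <- diff(ys)
  y0 <- ys[which.max(gaps)] + max(gaps) / 2
  n <- nrow(poly)
  xs <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > y0) != (yj > y0)) {
      xs <- c(xs, poly[i, 1] + (y0 - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1]))
    }
    j <- i
  }
  xs <- sort(xs)
  if (length(xs) >= 2L) c(mean(xs[1:2]), y0) else colMeans(poly)
}
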