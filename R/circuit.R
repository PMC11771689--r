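# Pairwise circuit-theory connectivity on a raster resistance surface:
# cells become graph nodes connected to their four nearest neighbours, focal
# regions are contracted to zero-internal-resistance supernodes, and each
# unordered focal pair is solved as a grounded graph-Laplacian linear system
# with one ampere injected at the source. Cumulative current sums the pair
# maps, mirroring Circuitscape's pairwise mode.

#' Build the circuit graph from a resistance raster
#'
#' Each valid (non-nodata) cell is a node; adjacent cells i, j (4-neighbour)
#' are joined by a resistor of `(r_i + r_j) / 2` (average-resistance
#' convention), i.e. conductance `1 / ((r_i + r_j) / 2)`. All cells within a
#' focal region are contracted to a single supernode. Barrier cells keep
#' their finite high resistance and stay in the graph.
#'
#' @param r Resistance `fw_raster` (all valid values > 0).
#' @param focal List of `focal_region`s (>= 2), each intersecting at least
#'   one valid cell.
#' @param convention `"resistance"` (average resistance, default) or
#'   `"conductance"` (average conductance) for the edge weight.
#' @return A `circuit_graph`: sparse edge structure, node-per-cell mapping,
#'   and focal supernode ids.
#' @export
build_graph <- function(r, focal, convention = c("resistance", "conductance")) {
  convention <- match.arg(convention)
  stopifnot(length(focal) >= 2L)
  v <- raster_values(r)
  if (any(v[!is.na(v)] <= 0)) stop("resistance values must be > 0")
  d <- dim(v)
  valid <- !is.na(v)
  node_of_cell <- matrix(NA_integer_, d[1], d[2])
  node_of_cell[valid] <- seq_len(sum(valid))

  # 4-neighbour edges among valid cells
  edge_pairs <- function(r1, c1, r2, c2) {
    ok <- valid[cbind(r1, c1)] & valid[cbind(r2, c2)]
    cbind(node_of_cell[cbind(r1[ok], c1[ok])],
          node_of_cell[cbind(r2[ok], c2[ok])],
          if (convention == "resistance") {
            1 / ((v[cbind(r1[ok], c1[ok])] + v[cbind(r2[ok], c2[ok])]) / 2)
          } else {
            (1 / v[cbind(r1[ok], c1[ok])] + 1 / v[cbind(r2[ok], c2[ok])]) / 2
          })
  }
  rc_h <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2] - 1L))
  rc_v <- expand.grid(row = seq_len(d[1] - 1L), col = seq_len(d[2]))
  E <- rbind(edge_pairs(rc_h$row, rc_h$col, rc_h$row, rc_h$col + 1L),
             edge_pairs(rc_v$row, rc_v$col, rc_v$row + 1L, rc_v$col))

  # contract focal regions to supernodes
  cc <- cell_centers(r)
  group <- seq_len(sum(valid))  # node -> group
  focal_nodes <- integer(length(focal))
  names(focal_nodes) <- vapply(focal, `[[`, character(1), "name")
  for (k in seq_along(focal)) {
    reg <- focal[[k]]
    inside <- point_in_polygon(cc$x, cc$y, reg$polygon) &
      valid[cbind(cc$row, cc$col)]
    if (!any(inside)) {
      stop("focal region '", reg$name, "' touches no valid cell")
    }
    nodes <- node_of_cell[cbind(cc$row[inside], cc$col[inside])]
    group[nodes] <- min(nodes)
    focal_nodes[k] <- min(nodes)
  }
  relabel <- match(group, sort(unique(group)))
  focal_ids <- relabel[focal_nodes]
  names(focal_ids) <- names(focal_nodes)
  i <- relabel[E[, 1]]; j <- relabel[E[, 2]]
  keep <- i != j  # drop intra-supernode edges (zero internal resistance)
  structure(list(
    n_nodes = max(relabel),
    edges = cbind(i = i[keep], j = j[keep], cond = E[keep, 3]),
    node_of_cell = matrix(relabel[node_of_cell], d[1], d[2]),
    focal_ids = focal_ids,
    template = fw_raster(matrix(NA_real_, d[1], d[2]), r$cell_size,
                         r$origin, r$nodata)
  ), class = "circuit_graph")
}

#' @export
print.circuit_graph <- function(x, ...) {
  cat(sprintf("<circuit_graph> %d nodes, %d edges, %d focal supernodes (%s)\n",
              x$n_nodes, nrow(x$edges), length(x$focal_ids),
              paste(names(x$focal_ids), collapse = ", ")))
  invisible(x)
}

graph_laplacian <- function(g) {
  e <- g$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(e[, 3], e[, 3]), dims = c(g$n_nodes, g$n_nodes))
  Matrix::Diagonal(g$n_nodes, Matrix::rowSums(A)) - A
}

graph_connected_between <- function(g, a, b) {
  ig <- igraph::graph_from_edgelist(g$edges[, 1:2, drop = FALSE],
                                    directed = FALSE)
  if (igraph::vcount(ig) < g$n_nodes) {
    ig <- igraph::add_vertices(ig, g$n_nodes - igraph::vcount(ig))
  }
  comp <- igraph::components(ig)$membership
  comp[a] == comp[b]
}

#' Solve one focal pair
#'
#' Injects one unit of current at the source supernode with the ground
#' supernode fixed at 0 V and solves the grounded Laplacian system
#' `L v = I` by sparse Cholesky factorization. Per-node current is half the
#' sum of absolute incident edge currents (pass-through counted once);
#' source and ground are reported at the injected 1.0. A disconnected pair
#' is flagged (`connected = FALSE`, infinite effective resistance) and
#' returns an all-zero current map.
#'
#' @param g A `circuit_graph`.
#' @param source,ground Focal region names (distinct).
#' @return List: `current` (`fw_raster` of per-cell current),
#'   `effective_resistance` (voltage at source), `voltage` (per-node),
#'   `node_current` (per-node), `connected`.
#' @export
solve_pair <- function(g, source, ground) {
  stopifnot(source != ground)
  si <- match(source, names(g$focal_ids)); ti <- match(ground, names(g$focal_ids))
  if (is.na(si) || is.na(ti)) {
    stop("unknown focal region name(s): ", source, " / ", ground)
  }
  s <- g$focal_ids[[si]]; t <- g$focal_ids[[ti]]
  make_map <- function(node_current) {
    vals <- matrix(NA_real_, nrow(g$node_of_cell), ncol(g$node_of_cell))
    ok <- !is.na(g$node_of_cell)
    vals[ok] <- node_current[g$node_of_cell[ok]]
    fw_raster(vals, g$template$cell_size, g$template$origin, g$template$nodata)
  }
  if (!graph_connected_between(g, s, t)) {
    warning(sprintf("focal pair %s-%s is disconnected; effective resistance is infinite",
                    source, ground))
    zero <- rep(0, g$n_nodes)
    return(list(current = make_map(zero), effective_resistance = Inf,
                voltage = zero, node_current = zero, connected = FALSE))
  }
  L <- graph_laplacian(g)
  keep <- setdiff(seq_len(g$n_nodes), t)
  b <- rep(0, g$n_nodes); b[s] <- 1
  Lr <- methods::as(L[keep, keep, drop = FALSE], "symmetricMatrix")
  v <- rep(0, g$n_nodes)
  v[keep] <- as.vector(Matrix::solve(Lr, b[keep]))
  e <- g$edges
  edge_current <- e[, 3] * (v[e[, 1]] - v[e[, 2]])
  node_current <- 0.5 * (
    tabulate_weighted(e[, 1], abs(edge_current), g$n_nodes) +
    tabulate_weighted(e[, 2], abs(edge_current), g$n_nodes))
  node_current[c(s, t)] <- 1.0
  list(current = make_map(node_current),
       effective_resistance = v[s],
       voltage = v, node_current = node_current, connected = TRUE)
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Cumulative current over all focal pairs
#'
#' Solves every unordered pair of focal regions (three regions give three
#' solves) and sums the per-pair current maps cellwise.
#'
#' @param g A `circuit_graph` with >= 2 focal regions.
#' @return A `current_map`: list with `cumulative` (`fw_raster`),
#'   `pair_maps` (named list of `fw_raster`), `pair_resistance` (tibble of
#'   pairwise effective resistances), `connected` (all pairs connected?).
#' @export
cumulative_current <- function(g) {
  nms <- names(g$focal_ids)
  stopifnot(length(nms) >= 2L)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  pair_maps <- list()
  res <- tibble::tibble(from = character(), to = character(),
                        effective_resistance = numeric(), connected = logical())
  cum <- NULL
  for (p in pairs) {
    sol <- solve_pair(g, p[1], p[2])
    key <- paste(p[1], p[2], sep = "-")
    pair_maps[[key]] <- sol$current
    res <- dplyr::bind_rows(res, tibble::tibble(
      from = p[1], to = p[2],
      effective_resistance = sol$effective_resistance,
      connected = sol$connected))
    cum <- if (is.null(cum)) sol$current$values else cum + sol$current$values
  }
  tmpl <- g$template
  structure(list(
    cumulative = fw_raster(cum, tmpl$cell_size, tmpl$origin, tmpl$nodata),
    pair_maps = pair_maps, pair_resistance = res,
    connected = all(res$connected)), class = "current_map")
}

#' @export
print.current_map <- function(x, ...) {
  cat(sprintf("<current_map> %d focal pairs; cumulative current in [%g, %g]\n",
              nrow(x$pair_resistance),
              min(raster_values(x$cumulative), na.rm = TRUE),
              max(raster_values(x$cumulative), na.rm = TRUE)))
  print(x$pair_resistance)
  invisible(x)
}

#' Sum cumulative current over a region of interest
#' @param cm A `current_map` (or `fw_raster`).
#' @param roi Polygon vertex matrix, list of polygons, or `NULL` (whole map).
#' @return Scalar sum of current over cells whose centres fall in the ROI.
#' @export
summed_current <- function(cm, roi = NULL) {
  r <- if (inherits(cm, "current_map")) cm$cumulative else cm
  v <- raster_values(r)
  if (is.null(roi)) return(sum(v, na.rm = TRUE))
  cc <- cell_centers(r)
  polys <- if (is.list(roi) && !is.matrix(roi)) roi else list(roi)
  inside <- rep(FALSE, nrow(cc))
  for (p in polys) inside <- inside | point_in_polygon(cc$x, cc$y, p)
  sum(v[cbind(cc$row[inside], cc$col[inside])], na.rm = TRUE)
}

#' Identify corridors as the top fraction of current
#'
#' The corridor mask keeps cells whose cumulative current is strictly above
#' the `(1 - top_fraction)` quantile of valid cells (the study threshold is
#' the top 10% of pixels).
#'
#' @param cm A `current_map` or cumulative-current `fw_raster`.
#' @param top_fraction Fraction of pixels kept (default 0.10).
#' @return List: `mask` (0/1 `fw_raster`) and `threshold`.
#' @export
identify_corridors <- function(cm, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  r <- if (inherits(cm, "current_map")) cm$cumulative else cm
  v <- raster_values(r)
  vv <- v[!is.na(v)]
  thr <- unname(stats::quantile(vv, 1 - top_fraction))
  if (max(vv) == min(vv)) {
    warning("constant current map: corridor mask is empty")
  }
  mask <- v
  mask[!is.na(v)] <- as.numeric(v[!is.na(v)] > thr)
  list(mask = fw_raster(mask, r$cell_size, r$origin, r$nodata),
       threshold = thr)
}

#' Connectivity change map (fenced minus pre-fencing)
#'
#' Cellwise difference of two cumulative current maps on the same grid;
#' negative values are connectivity loss due to fencing.
#'
#' @param cm_fenced,cm_prefence `current_map`s or `fw_raster`s on one grid.
#' @return `fw_raster` of current change.
#' @export
connectivity_change <- function(cm_fenced, cm_prefence) {
  a <- if (inherits(cm_fenced, "current_map")) cm_fenced$cumulative else cm_fenced
  b <- if (inherits(cm_prefence, "current_map")) cm_prefence$cumulative else cm_prefence
  stop_if_grid_mismatch(a, b, "fenced map", "pre-fencing map")
  fw_raster(raster_values(a) - raster_values(b), a$cell_size, a$origin,
            a$nodata)
}
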