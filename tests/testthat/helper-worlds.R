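# Shared fixtures built in code: tiny rasters, toy fence geometries, and an
# independent dense linear-algebra oracle for the circuit solver.

uniform_raster <- function(value, nr, nc, cell = 1, origin = c(0, nr * cell)) {
  fw_raster(matrix(value, nr, nc), cell, origin)
}

# four fence lines forming an axis-aligned square (one line per side)
square_lines <- function(x0, y0, side) {
  corners <- rbind(c(x0, y0), c(x0 + side, y0),
                   c(x0 + side, y0 + side), c(x0, y0 + side))
  lapply(1:4, function(k) rbind(corners[k, ], corners[k %% 4 + 1L, ]))
}

# focal regions covering single corner cells of a raster
corner_focals <- function(r) {
  d <- dim(r$values); cs <- r$cell_size; o <- r$origin
  list(
    focal_rect("a", o[1], o[1] + cs, o[2] - cs, o[2]),                    # NW
    focal_rect("b", o[1] + (d[2] - 1) * cs, o[1] + d[2] * cs,
               o[2] - d[1] * cs, o[2] - (d[1] - 1) * cs))                 # SE
}

# dense full-matrix solve of the grounded Laplacian: the oracle the sparse
# path is checked against
dense_pair_solve <- function(g, source, ground) {
  L <- matrix(0, g$n_nodes, g$n_nodes)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges[k, 1]; j <- g$edges[k, 2]; c <- g$edges[k, 3]
    L[i, j] <- L[i, j] - c; L[j, i] <- L[j, i] - c
    L[i, i] <- L[i, i] + c; L[j, j] <- L[j, j] + c
  }
  s <- g$focal_ids[[source]]; t <- g$focal_ids[[ground]]
  keep <- setdiff(seq_len(g$n_nodes), t)
  b <- rep(0, g$n_nodes); b[s] <- 1
  v <- rep(0, g$n_nodes)
  v[keep] <- solve(L[keep, keep], b[keep])
  v
}

# small synthetic stack for habitat-model tests
small_stack <- function(seed = 1, shape = c(40, 40), cell = 1000) {
  generate_covariates(shape, cell, correlation_length = 3 * cell, seed = seed)
}
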