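test_that("graph construction follows the 4-neighbour lattice contract", {
  r <- uniform_raster(2, 10, 10)
  g <- build_graph(r, corner_focals(r))
  expect_equal(nrow(g$edges), 2 * 10 * 9)
  expect_true(all(g$edges[, 3] == 0.5))   # conductance 1/((2+2)/2)
  # focal contraction: a k-cell region removes k-1 nodes
  f2 <- list(focal_rect("a", 0, 3, 7, 10), focal_rect("b", 9, 10, 0, 1))
  g2 <- build_graph(r, f2)
  expect_equal(g2$n_nodes, 100 - (9 - 1))
  # interior node degree is 4
  deg <- tabulate(c(g$edges[, 1], g$edges[, 2]), g$n_nodes)
  interior <- setdiff(seq_len(g$n_nodes), g$focal_ids)
  expect_equal(max(deg[interior]), 4)
  expect_error(build_graph(r, list(focal_rect("a", 0, 1, 9, 10),
                                   focal_rect("far", 500, 510, 0, 1))),
               "far")
})

test_that("series and parallel circuits match closed forms", {
  # 1x3 chain, uniform resistance r: R_eff = 2r, middle cell current 1
  chain <- fw_raster(matrix(3, 1, 3), 1, c(0, 1))
  fc <- list(focal_rect("a", 0, 1, 0, 1), focal_rect("b", 2, 3, 0, 1))
  sol <- solve_pair(build_graph(chain, fc), "a", "b")
  expect_equal(sol$effective_resistance, 6, tolerance = 1e-12)
  expect_equal(raster_values(sol$current)[1, 2], 1, tolerance = 1e-12)
  # two equal parallel paths: half the single-path resistance, 50/50 split
  ring <- fw_raster(matrix(5, 3, 3), 1, c(0, 3))
  ring$values[2, 2] <- NA
  fr <- list(focal_rect("a", 0, 1, 2, 3), focal_rect("b", 2, 3, 0, 1))
  g <- build_graph(ring, fr)
  sol2 <- solve_pair(g, "a", "b")
  single_path_R <- 4 * 5  # 4 edges of resistance 5 along one arm
  expect_equal(sol2$effective_resistance, single_path_R / 2, tolerance = 1e-10)
  v <- raster_values(sol2$current)
  expect_equal(v[1, 2], 0.5, tolerance = 1e-10)
  expect_equal(v[2, 1], 0.5, tolerance = 1e-10)
})

test_that("sparse solves match the dense oracle on random small grids", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:8, 1)
    r <- fw_raster(matrix(runif(n * n, 0.5, 30), n, n), 1, c(0, n))
    g <- build_graph(r, corner_focals(r))
    sol <- solve_pair(g, "a", "b")
    v_dense <- dense_pair_solve(g, "a", "b")
    expect_lt(max(abs(sol$voltage - v_dense)), 1e-8)
  }
})

test_that("Kirchhoff current conservation holds at every non-focal node", {
  set.seed(42)
  r <- fw_raster(matrix(runif(2500, 1, 100), 50, 50), 1, c(0, 50))
  g <- build_graph(r, corner_focals(r))
  sol <- solve_pair(g, "a", "b")
  e <- g$edges
  ec <- e[, 3] * (sol$voltage[e[, 1]] - sol$voltage[e[, 2]])
  net <- numeric(g$n_nodes)
  agg_out <- rowsum(ec, e[, 1]); agg_in <- rowsum(ec, e[, 2])
  net[as.integer(rownames(agg_out))] <- net[as.integer(rownames(agg_out))] - agg_out[, 1]
  net[as.integer(rownames(agg_in))] <- net[as.integer(rownames(agg_in))] + agg_in[, 1]
  expect_lt(max(abs(net[-g$focal_ids])), 1e-8)
})

test_that("Rayleigh monotonicity: lowering resistance never isolates a pair", {
  set.seed(7)
  r <- fw_raster(matrix(runif(64, 1, 100), 8, 8), 1, c(0, 8))
  g <- build_graph(r, corner_focals(r))
  base <- solve_pair(g, "a", "b")$effective_resistance
  for (k in 1:5) {
    r2 <- r
    cell <- c(sample(8, 1), sample(8, 1))
    r2$values[cell[1], cell[2]] <- r$values[cell[1], cell[2]] / 10
    low <- solve_pair(build_graph(r2, corner_focals(r2)), "a", "b")
    expect_lte(low$effective_resistance, base + 1e-10)
  }
})

test_that("disconnected pairs are flagged with infinite resistance", {
  r <- uniform_raster(1, 5, 5)
  r$values[, 3] <- NA  # nodata wall
  g <- build_graph(r, corner_focals(r))
  expect_warning(sol <- solve_pair(g, "a", "b"), "disconnected")
  expect_identical(sol$effective_resistance, Inf)
  expect_false(sol$connected)
  expect_true(all(raster_values(sol$current) == 0, na.rm = TRUE))
})

test_that("cumulative current sums pair maps symmetrically", {
  set.seed(9)
  r <- fw_raster(matrix(runif(100, 1, 50), 10, 10), 1, c(0, 10))
  f3 <- list(focal_rect("a", 0, 1, 9, 10), focal_rect("b", 9, 10, 0, 1),
             focal_rect("c", 0, 1, 0, 1))
  cm <- cumulative_current(build_graph(r, f3))
  expect_equal(nrow(cm$pair_resistance), 3)
  expect_equal(raster_values(cm$cumulative),
               Reduce(`+`, lapply(cm$pair_maps, raster_values)))
  # cell current bounded by injected current summed over pairs
  expect_lte(max(raster_values(cm$cumulative)), 3 + 1e-9)
  # permuting focal order leaves the map unchanged
  cm2 <- cumulative_current(build_graph(r, f3[c(3, 1, 2)]))
  expect_equal(raster_values(cm2$cumulative), raster_values(cm$cumulative),
               tolerance = 1e-9)
  # with two regions the cumulative IS the single pair map
  cm3 <- cumulative_current(build_graph(r, f3[1:2]))
  expect_equal(raster_values(cm3$cumulative),
               raster_values(cm3$pair_maps[[1]]))
})

test_that("corridor thresholding keeps exactly the top fraction", {
  vals <- matrix(sample(1:100), 10, 10)
  r <- fw_raster(vals, 1, c(0, 10))
  res <- identify_corridors(r, 0.10)
  expect_equal(sum(raster_values(res$mask)), 10)
  expect_true(all(vals[raster_values(res$mask) == 1] > res$threshold))
  half <- identify_corridors(r, 0.5)
  expect_equal(sum(raster_values(half$mask)), 50)
  # monotone: raising the fraction never deselects a cell
  m10 <- raster_values(identify_corridors(r, 0.10)$mask)
  m25 <- raster_values(identify_corridors(r, 0.25)$mask)
  expect_true(all(m25[m10 == 1] == 1))
  expect_warning(identify_corridors(uniform_raster(1, 4, 4), 0.1), "constant")
})

test_that("connectivity change is an exact cellwise difference", {
  set.seed(4)
  a <- fw_raster(matrix(runif(25), 5, 5), 1, c(0, 5))
  b <- fw_raster(matrix(runif(25), 5, 5), 1, c(0, 5))
  expect_true(all(raster_values(connectivity_change(a, a)) == 0))
  ch <- connectivity_change(a, b)
  expect_equal(sum(raster_values(ch)),
               sum(raster_values(a)) - sum(raster_values(b)))
  shifted <- fw_raster(b$values, 1, c(1, 5))
  expect_error(connectivity_change(a, shifted), "grid mismatch")
})

test_that("a severing barrier only lowers current on the cut route", {
  r <- uniform_raster(5, 9, 9)
  f <- list(focal_rect("a", 0, 1, 4, 5), focal_rect("b", 8, 9, 4, 5))
  cm_pre <- cumulative_current(build_graph(r, f))
  wall <- fence_network(list(rbind(c(4.5, 2), c(4.5, 7))))
  r_fen <- burn_fences(r, wall, 100)
  cm_fen <- cumulative_current(build_graph(r_fen, f))
  ch <- raster_values(connectivity_change(cm_fen, cm_pre))
  # current through the walled cells drops
  expect_true(all(ch[3:7, 5] <= 1e-9))
})
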