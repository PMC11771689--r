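test_that("suitability inverts linearly onto the resistance scale", {
  s <- uniform_raster(0.5, 4, 4)
  r <- suitability_to_resistance(s)
  expect_true(all(raster_values(r) == 50.5))
  # endpoints of the linear map
  near1 <- suitability_to_resistance(uniform_raster(1 - 1e-12, 2, 2))
  near0 <- suitability_to_resistance(uniform_raster(1e-12, 2, 2))
  expect_equal(raster_values(near1)[1, 1], 1, tolerance = 1e-9)
  expect_equal(raster_values(near0)[1, 1], 100, tolerance = 1e-9)
  # rank order exactly reversed
  set.seed(3)
  s2 <- fw_raster(matrix(runif(36, 0.01, 0.99), 6, 6), 1, c(0, 6))
  r2 <- suitability_to_resistance(s2)
  expect_equal(order(as.vector(raster_values(r2))),
               rev(order(as.vector(raster_values(s2)))))
  # reciprocal variant is also strictly decreasing
  r3 <- suitability_to_resistance(s2, method = "reciprocal")
  expect_equal(order(as.vector(raster_values(r3))),
               rev(order(as.vector(raster_values(s2)))))
  expect_error(suitability_to_resistance(uniform_raster(1.2, 2, 2)),
               "strictly in")
})

test_that("fence burning is supercover, enclosure-filling, and idempotent", {
  r <- uniform_raster(7, 10, 10, cell = 1)
  # single horizontal line through the middle of row 5 -> exactly one row
  row_line <- fence_network(list(rbind(c(0, 5.5), c(10, 5.5))))
  b <- burn_fences(r, row_line, 100)
  v <- raster_values(b)
  expect_true(all(v[5, ] == 100))
  expect_true(all(v[-5, ] == 7))
  # closed square parcel: boundary AND interior at the barrier value
  sq <- fence_network(square_lines(2, 2, 5))
  b2 <- burn_fences(r, sq, 100)
  v2 <- raster_values(b2)
  expect_true(all(v2[5, 4:6] == 100))   # interior row
  expect_true(all(v2[1, ] == 7))        # outside untouched, bit-exact
  expect_identical(v2[v2 != 100], rep(7, sum(v2 != 100)))
  # idempotent
  b3 <- burn_fences(b2, sq, 100)
  expect_identical(b3$values, b2$values)
  # empty network is a no-op
  expect_identical(burn_fences(r, fence_network(), 100)$values, r$values)
})

test_that("enclosed-parcel filling can be disabled", {
  r <- uniform_raster(7, 10, 10, cell = 1)
  sq <- fence_network(square_lines(2, 2, 5))
  open <- burn_fences(r, sq, 100, fill_enclosed = FALSE)
  expect_true(raster_values(open)[5, 5] == 7)   # interior untouched
})
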