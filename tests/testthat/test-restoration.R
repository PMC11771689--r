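test_that("corridor fence removal clips at the buffer boundary exactly", {
  fences <- fence_network(list(
    rbind(c(0, 0), c(10, 0)),        # along the future corridor
    rbind(c(50, 50), c(60, 60))))    # far away
  # corridor: 4 km wide around a centerline through the first fence
  scen <- corridor_scenario("C", rbind(c(2, 0), c(8, 0)), width_km = 0.004)
  res <- apply_scenario(fences, scen)
  expect_equal(res$removed_length_m, 6)   # clipped inside length [2, 8]
  expect_equal(sort(res$lines_touched), "F1")
  expect_equal(total_fence_length(res$fences),
               total_fence_length(fences) - 6)
  # disjoint corridor is the identity
  far <- corridor_scenario("C", rbind(c(100, 100), c(110, 100)), 0.001)
  res2 <- apply_scenario(fences, far)
  expect_equal(res2$removed_length_m, 0)
  expect_equal(total_fence_length(res2$fences), total_fence_length(fences))
  # corridor covering everything removes everything
  all_scen <- corridor_scenario("C", rbind(c(-100, 0), c(200, 0)), 0.5)
  res3 <- apply_scenario(fences, all_scen)
  expect_equal(res3$removed_length_m, total_fence_length(fences),
               tolerance = 1e-9)
  expect_equal(nrow(res3$fences), 0)
})

test_that("a segment half inside the buffer loses exactly its inside part", {
  # vertical segment crossing a horizontal corridor of half-width 1000
  fences <- fence_network(list(rbind(c(5000, -3000), c(5000, 3000))))
  scen <- corridor_scenario("C", rbind(c(0, 0), c(10000, 0)), width_km = 2)
  res <- apply_scenario(fences, scen)
  expect_equal(res$removed_length_m, 2000, tolerance = 1e-9)
  # the retained pieces end exactly at the buffer edges
  ys <- sort(unlist(lapply(res$fences$geometry, function(m) m[, 2])))
  expect_equal(ys, c(-3000, -1000, 1000, 3000), tolerance = 1e-9)
})

test_that("improvement metric is the restored share of the loss", {
  expect_equal(improvement_metric(20, 10, 15), 50)
  expect_equal(improvement_metric(20, 10, 20), 100)
  expect_equal(improvement_metric(20, 10, 10), 0)
  expect_gt(improvement_metric(20, 10, 22), 100)  # over-restoration reported
  expect_error(improvement_metric(10, 12, 11), "undefined|no connectivity loss")
})

test_that("scenario cost is proportional to intersected parcel acreage", {
  acre_side <- sqrt(4046.8564224)
  parcel <- list(list(id = "P1",
                      polygon = rbind(c(0, 0), c(acre_side, 0),
                                      c(acre_side, acre_side), c(0, acre_side)),
                      area_m2 = 4046.8564224, area_acres = 1,
                      bounding_lines = c("F1", "F2", "F3"),
                      fully_enclosed = TRUE))
  # corridor covering the whole parcel: exactly one acre at $75
  big <- corridor_scenario("C", rbind(c(-100, 30), c(200, 30)), width_km = 1)
  cost <- scenario_cost(parcel, big, 75)
  expect_equal(cost$cost_usd, 75, tolerance = 1e-9)
  expect_equal(cost$n_parcels_intersected, 1L)
  # half inside by area -> half the cost; a 10-acre parcel costs $375
  ten <- parcel
  side <- sqrt(10 * 4046.8564224)
  ten[[1]]$polygon <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  half <- corridor_scenario("C", rbind(c(-10, side / 2), c(side + 10, side / 2)),
                            width_km = side / 1000)
  ch <- scenario_cost(ten, half, 75)
  expect_equal(ch$area_acres, 10, tolerance = 1e-9)
  # now shift the corridor so only the lower half is covered
  lower <- corridor_scenario("C", rbind(c(-10, 0), c(side + 10, 0)),
                             width_km = side / 1000)
  cl <- scenario_cost(ten, lower, 75)
  expect_equal(cl$area_acres, 5, tolerance = 1e-9)
  expect_equal(cl$cost_usd, 375, tolerance = 1e-9)
  # no intersection, no cost
  none <- corridor_scenario("C", rbind(c(1e6, 0), c(1e6 + 10, 0)), 0.1)
  expect_equal(scenario_cost(parcel, none, 75)$cost_usd, 0)
})

test_that("bent-corridor buffer areas correct for rectangle overlap", {
  # right-angle centerline whose two 2000m-wide rectangles overlap in a
  # 1000x1000 square at the joint; a parcel covering everything must count
  # the union area, not the sum
  center <- rbind(c(0, 0), c(5000, 0), c(5000, 5000))
  scen <- corridor_scenario("C", center, width_km = 1)
  parcel <- list(list(id = "P", area_m2 = 4e8, area_acres = 4e8 / 4046.8564224,
                      polygon = rbind(c(-10000, -10000), c(10000, -10000),
                                      c(10000, 10000), c(-10000, 10000)),
                      bounding_lines = "F1", fully_enclosed = TRUE))
  got <- scenario_cost(parcel, scen, 75)$area_acres * 4046.8564224
  # rect1: x[0,5000] x y[-500,500]; rect2: x[4500,5500] x y[0,5000];
  # they overlap on x[4500,5000] x y[0,500]
  expect_equal(got, 5000 * 1000 + 1000 * 5000 - 500 * 500, tolerance = 1e-6)
})
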