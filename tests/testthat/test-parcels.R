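test_that("closed faces become parcels; open shapes do not", {
  one <- detect_parcels(fence_network(square_lines(0, 0, 10)))
  expect_length(one, 1)
  expect_equal(one[[1]]$area_m2, 100)
  expect_equal(one[[1]]$area_acres, 100 / 4046.8564224)
  expect_length(one[[1]]$bounding_lines, 4)
  expect_true(one[[1]]$fully_enclosed)
  # U-shape of three lines leaves only the unbounded face
  u <- fence_network(list(rbind(c(0, 0), c(0, 10)), rbind(c(0, 0), c(10, 0)),
                          rbind(c(10, 0), c(10, 10))))
  expect_length(detect_parcels(u), 0)
  expect_length(detect_parcels(fence_network()), 0)
})

test_that("shared-edge squares and nested parcels follow the enclosure rules", {
  seven <- fence_network(list(
    rbind(c(0, 0), c(10, 0)), rbind(c(10, 0), c(10, 10)),
    rbind(c(10, 10), c(0, 10)), rbind(c(0, 10), c(0, 0)),
    rbind(c(10, 0), c(20, 0)), rbind(c(20, 0), c(20, 10)),
    rbind(c(20, 10), c(10, 10))))
  p <- detect_parcels(seven)
  expect_length(p, 2)
  expect_equal(sort(vapply(p, `[[`, numeric(1), "area_m2")), c(100, 100))
  # a ring inside a parcel is itself a parcel (rule 2), even with < 3 lines
  nested <- fence_network(c(
    square_lines(0, 0, 10),
    list(rbind(c(3, 3), c(6, 3), c(6, 6), c(3, 6), c(3, 3)))))
  pn <- detect_parcels(nested)
  expect_length(pn, 2)
  expect_equal(sort(vapply(pn, `[[`, numeric(1), "area_m2")), c(9, 100))
})

test_that("crossing lines are noded automatically", {
  # a square cut in half by one crossing line -> two parcels
  cut <- fence_network(c(square_lines(0, 0, 10),
                         list(rbind(c(-1, 5), c(11, 5)))))
  p <- detect_parcels(cut)
  expect_length(p, 2)
  expect_equal(sort(vapply(p, `[[`, numeric(1), "area_m2")), c(50, 50))
  # two lines crossing in an X enclose nothing
  x <- fence_network(list(rbind(c(0, 0), c(10, 10)), rbind(c(0, 10), c(10, 0))))
  expect_length(detect_parcels(x), 0)
})

test_that("the minimum-bounding-lines rule filters faces", {
  # a closed triangle drawn as ONE self-closing polyline: 1 distinct line
  tri <- fence_network(list(rbind(c(0, 0), c(10, 0), c(5, 8), c(0, 0))))
  expect_length(detect_parcels(tri, min_bounding_lines = 3), 0)
  expect_length(detect_parcels(tri, min_bounding_lines = 1), 1)
  # total parcel area never exceeds the hull of the network
  st <- small_stack(seed = 12)
  f <- generate_fences(st, 4, seed = 3)
  p <- detect_parcels(f)
  expect_lte(sum(vapply(p, `[[`, numeric(1), "area_m2")),
             40000 * 40000)
  expect_s3_class(parcels_tibble(p), "tbl_df")
})
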