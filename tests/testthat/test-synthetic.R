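test_that("covariate generation is deterministic and validates its grid", {
  a <- generate_covariates(c(20, 20), 500, 2500, seed = 11)
  b <- generate_covariates(c(20, 20), 500, 2500, seed = 11)
  for (nm in names(a$layers)) {
    expect_identical(a$layers[[nm]]$values, b$layers[[nm]]$values)
  }
  expect_error(generate_covariates(c(2, 20), 500, seed = 1), "degenerate")
  expect_error(generate_covariates(c(20, 20), 500, 100, seed = 1))
})

test_that("distance layers vanish exactly on their source features", {
  st <- generate_covariates(c(50, 50), 1000, 5000, seed = 1)
  for (nm in c("dist_river", "dist_road1", "dist_woody")) {
    v <- raster_values(st$layers[[nm]])
    expect_true(any(v == 0), info = nm)
    expect_true(all(v >= 0), info = nm)
  }
  expect_gte(nrow(st$ndvi_series), 2)
})

test_that("longer correlation lengths raise spatial autocorrelation (Moran's I)", {
  skip_if_not_installed("ape")
  moran_rook <- function(r) {
    v <- raster_values(r)[1:25, 1:25]
    n <- length(v)
    cc <- expand.grid(row = 1:25, col = 1:25)
    w <- matrix(0, n, n)
    d <- as.matrix(stats::dist(cc))
    w[d == 1] <- 1
    ape::Moran.I(as.vector(v), w)$observed
  }
  smooth <- generate_covariates(c(25, 25), 1000, 10000, seed = 5)
  rough <- generate_covariates(c(25, 25), 1000, 1000, seed = 5)
  expect_gt(moran_rook(smooth$layers$twi), moran_rook(rough$layers$twi))
})

test_that("fence generator encloses exactly the requested parcels", {
  st <- small_stack(seed = 3)
  f0 <- generate_fences(st, 0, seed = 2)
  expect_length(detect_parcels(f0), 0)
  f5 <- generate_fences(st, 5, seed = 2)
  expect_length(detect_parcels(f5), 5)
  f5b <- generate_fences(st, 5, seed = 2)
  expect_identical(f5$geometry, f5b$geometry)
  expect_error(generate_fences(st, 1e6, seed = 1), "capacity")
})

test_that("simulated step lengths match the requested kernel", {
  st <- generate_covariates(c(200, 200), 1000, 3000, seed = 2)
  beta <- c(twi = 0)
  tr <- simulate_trajectories(st, beta, n_animals = 2, n_steps = 600,
                              step_mean = 5, step_sd = 3,
                              start_xy = matrix(1e5, 2, 2), seed = 9)
  steps <- tr |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(s = list(sqrt(diff(x)^2 + diff(y)^2))) |>
    dplyr::pull(s) |>
    unlist() / 1000
  expect_lt(abs(mean(steps) - 5) / 5, 0.10)
  expect_lt(abs(stats::sd(steps) - 3) / 3, 0.10)
})

test_that("null selection walks are unbiased; strong selection shifts use", {
  st <- small_stack(seed = 4)
  null_tr <- simulate_trajectories(st, c(twi = 0), n_animals = 3,
                                   n_steps = 300, step_mean = 3, step_sd = 2,
                                   seed = 5)
  disp <- null_tr |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(dx = mean(diff(x)), dy = mean(diff(y)))
  # mean per-step displacement ~ 0 within Monte-Carlo error (SE ~ L/sqrt(n))
  expect_lt(max(abs(c(disp$dx, disp$dy))), 3 * 3000 / sqrt(300))

  sel_tr <- simulate_trajectories(st, c(twi = 2), n_animals = 3,
                                  n_steps = 400, step_mean = 5, step_sd = 3,
                                  seed = 6)
  used <- extract_covariates(st, sel_tr$x, sel_tr$y)
  bounds <- fenceflow:::stack_bounds(st)
  withr::with_seed(1, {
    ax <- stats::runif(2000, bounds$xmin, bounds$xmax)
    ay <- stats::runif(2000, bounds$ymin, bounds$ymax)
  })
  avail <- extract_covariates(st, ax, ay)
  expect_gt(mean(used$twi, na.rm = TRUE), mean(avail$twi, na.rm = TRUE))
})

test_that("fences are absolute barriers to simulated movement", {
  st <- small_stack(seed = 8)
  fences <- fence_network(list(rbind(c(20000, 0), c(20000, 40000))))
  tr <- simulate_trajectories(st, c(twi = 1), n_animals = 4, n_steps = 150,
                              step_mean = 6, step_sd = 4, fences = fences,
                              seed = 7)
  segs <- fenceflow:::fence_segments(fences)$segs
  crossings <- 0L
  for (a in unique(tr$animal_id)) {
    p <- tr[tr$animal_id == a, ]
    for (i in seq_len(nrow(p) - 1L)) {
      if (fenceflow:::crosses_any_segment(p$x[i], p$y[i], p$x[i + 1],
                                          p$y[i + 1], segs)) {
        crossings <- crossings + 1L
      }
    }
  }
  expect_identical(crossings, 0L)
})
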