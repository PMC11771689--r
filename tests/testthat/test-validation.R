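fake_points <- function(n_per_animal = 200, n_animals = 4, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      animal_id = rep(sprintf("A%02d", seq_len(n_animals)),
                      each = 2 * n_per_animal),
      is_presence = rep(rep(c(1L, 0L), each = n_per_animal), n_animals),
      x = stats::runif(2 * n_per_animal * n_animals, 0, 1000),
      y = stats::runif(2 * n_per_animal * n_animals, 0, 1000))
  })
}

test_that("metric extraction samples the nearest cell and drops outsiders", {
  r <- fw_raster(matrix(1:100, 10, 10), 100, c(0, 1000))
  tab <- tibble::tibble(animal_id = "A", is_presence = 1L,
                        x = c(150, 950, 5000), y = c(950, 50, 50))
  expect_message(out <- extract_metric_at_points(r, tab), "1 points outside")
  expect_equal(nrow(out), 2)
  expect_equal(out$metric[1], r$values[1, 2])    # exact cell value
  # constant raster gives identical values everywhere
  rc <- uniform_raster(3.5, 10, 10, cell = 100)
  tabc <- fake_points(50, 2)
  expect_equal(unique(extract_metric_at_points(rc, tabc)$metric), 3.5)
  # 1000 random points reproduce the raster mean within Monte-Carlo error
  set.seed(2)
  rr <- fw_raster(matrix(rnorm(100), 10, 10), 100, c(0, 1000))
  tabr <- fake_points(250, 2, seed = 3)
  got <- extract_metric_at_points(rr, tabr)$metric
  expect_lt(abs(mean(got) - mean(rr$values)), 3 * stats::sd(rr$values) / sqrt(1000))
})

test_that("a null metric yields a null presence coefficient", {
  zs <- vapply(1:3, function(s) {
    tab <- fake_points(seed = s)
    withr::with_seed(s, tab$metric <- stats::rnorm(nrow(tab), 5, 1))
    res <- compare_presence_absence(tab, "metric", transform = "none")
    res$statistic
  }, numeric(1))
  expect_lt(stats::median(abs(zs)), 2)
})

test_that("a planted presence signal is recovered with the right sign", {
  hits <- vapply(1:5, function(s) {
    tab <- fake_points(250, 4, seed = s)
    withr::with_seed(s + 50,
      tab$metric <- 0.3 * tab$is_presence + stats::rnorm(nrow(tab)))
    res <- compare_presence_absence(tab, "metric", transform = "none")
    res$coefficient > 0 && res$statistic > 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("transforms respect their domains and record themselves", {
  tab <- fake_points(100, 3, seed = 9)
  withr::with_seed(1, tab$suit <- stats::runif(nrow(tab), 0.05, 0.95))
  res <- compare_presence_absence(tab, "suit", transform = "logit")
  expect_identical(res$transform, "logit")
  withr::with_seed(2, tab$cur <- c(0, stats::rexp(nrow(tab) - 1)))
  expect_message(
    res2 <- compare_presence_absence(tab, "cur", transform = "log"),
    "offset")
  expect_identical(res2$transform, "log_offset")
  tab$bad <- tab$suit + 1
  expect_error(compare_presence_absence(tab, "bad", transform = "logit"),
               "strictly in")
  # beta-family route reports its own transform
  resb <- compare_presence_absence(tab, "suit", method = "beta")
  expect_identical(resb$transform, "beta_logit")
  expect_equal(sign(resb$coefficient), sign(res$coefficient))
})

test_that("results are invariant to row shuffling", {
  tab <- fake_points(150, 3, seed = 4)
  withr::with_seed(5, tab$metric <- stats::rnorm(nrow(tab)))
  r1 <- compare_presence_absence(tab, "metric", transform = "none")
  withr::with_seed(6, tab2 <- tab[sample(nrow(tab)), ])
  r2 <- compare_presence_absence(tab2, "metric", transform = "none")
  expect_equal(r1$coefficient, r2$coefficient, tolerance = 1e-8)
  expect_equal(r1$se, r2$se, tolerance = 1e-8)
})
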