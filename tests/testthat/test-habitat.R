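make_pa <- function(seed = 1, ratio = 5, n_steps = 120, n_animals = 4,
                    beta = c(twi = 0.8, dist_woody = -0.05, dist_woody2 = 0.005)) {
  st <- small_stack(seed = seed)
  tr <- simulate_trajectories(st, beta, n_animals = n_animals,
                              n_steps = n_steps, step_mean = 5, step_sd = 3,
                              seed = seed + 1)
  list(stack = st,
       table = sample_pseudo_absences(tr, st, pseudo_ratio = ratio,
                                      seed = seed + 2),
       traj = tr, beta = beta)
}

test_that("pseudo-absence tables honour the ratio and buffer radius", {
  st <- small_stack(seed = 2)
  tr <- simulate_trajectories(st, c(twi = 0.5), n_animals = 1, n_steps = 9,
                              step_mean = 4, step_sd = 2, seed = 3)
  pa <- sample_pseudo_absences(tr, st, pseudo_ratio = 50, seed = 4)
  expect_equal(sum(pa$is_presence == 1), 10)
  expect_equal(sum(pa$is_presence == 0), 500)
  # every absence within the animal's maximum observed step length
  p <- tr[tr$animal_id == tr$animal_id[1], ]
  rmax <- max(sqrt(diff(p$x)^2 + diff(p$y)^2))
  ab <- pa[pa$is_presence == 0, ]
  pres_xy <- pa[pa$is_presence == 1, c("x", "y")]
  d <- sqrt((ab$x - rep(pres_xy$x, each = 50))^2 +
              (ab$y - rep(pres_xy$y, each = 50))^2)
  expect_true(all(d <= rmax + 1e-9))
  pa2 <- sample_pseudo_absences(tr, st, pseudo_ratio = 50, seed = 4)
  expect_identical(pa$x, pa2$x)
  # single-fix trajectory has no defined buffer
  one <- tr[1, ]
  expect_error(sample_pseudo_absences(one, st, 5, seed = 1), "fewer than 2")
})

test_that("rsf fit preconditions are enforced", {
  w <- make_pa()
  tab1 <- w$table[w$table$animal_id == "A01", ]
  expect_error(fit_rsf(tab1), ">= 2 animals")
  tab_pres <- w$table[w$table$is_presence == 1, ]
  expect_error(fit_rsf(tab_pres), "presences and absences")
})

test_that("a randomly permuted covariate earns a null coefficient", {
  w <- make_pa(seed = 5, ratio = 8, n_steps = 200, n_animals = 5)
  tab <- w$table
  withr::with_seed(9, tab$footprint <- sample(tab$footprint))
  fit <- suppressMessages(fit_rsf(tab, covariates = c("twi", "footprint")))
  td <- tidy(fit)
  z <- td$statistic[td$term == "footprint"]
  expect_lt(abs(z), 2.5)
})

test_that("duplicating the data leaves estimates fixed and shrinks SEs", {
  w <- make_pa(seed = 6, ratio = 4, n_steps = 80, n_animals = 3)
  fit1 <- suppressMessages(fit_rsf(w$table, covariates = c("twi", "dist_woody")))
  dup <- dplyr::bind_rows(w$table, w$table)
  fit2 <- suppressMessages(fit_rsf(dup, covariates = c("twi", "dist_woody")))
  expect_lt(max(abs(fit2$beta - fit1$beta)), 0.05)
  expect_true(all(fit2$se[-1] < fit1$se[-1]))
})

test_that("fit is invariant to row order and reports its method", {
  w <- make_pa(seed = 7, ratio = 4, n_steps = 80, n_animals = 3)
  fit1 <- suppressMessages(fit_rsf(w$table, covariates = c("twi", "dist_woody")))
  withr::with_seed(2, shuffled <- w$table[sample(nrow(w$table)), ])
  fit2 <- suppressMessages(fit_rsf(shuffled, covariates = c("twi", "dist_woody")))
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
  expect_true(fit1$fit_meta$method %in% c("glmer_laplace", "fixed_fallback"))
  ts <- fit_rsf(w$table, covariates = c("twi", "dist_woody"),
                method = "two_stage")
  expect_identical(ts$fit_meta$method, "two_stage")
  # the two estimators agree on the population-level signal
  expect_equal(unname(sign(ts$beta[-1])), unname(sign(fit1$beta[-1])))
  expect_s3_class(glance(ts), "tbl_df")
})

test_that("suitability prediction follows the logit identities", {
  w <- make_pa(seed = 8, ratio = 3, n_steps = 60, n_animals = 3)
  fit <- suppressMessages(fit_rsf(w$table, covariates = c("twi", "dist_woody")))
  # all-zero coefficients -> uniform 0.5
  fit0 <- fit
  fit0$beta[] <- 0
  s0 <- predict_suitability(fit0, w$stack)
  expect_true(all(abs(raster_values(s0) - 0.5) < 1e-12))
  # single positive coefficient -> suitability ranks equal the layer ranks
  fit1 <- fit
  fit1$beta[] <- 0
  fit1$beta["twi"] <- 1.3
  s1 <- predict_suitability(fit1, w$stack)
  expect_equal(order(as.vector(raster_values(s1))),
               order(as.vector(raster_values(w$stack$layers$twi))))
  # suitability bounded away from {0, 1}
  expect_true(all(raster_values(s1) > 0 & raster_values(s1) < 1))
  # missing covariate layer is named in the error
  st2 <- w$stack
  st2$layers$twi <- NULL
  expect_error(predict_suitability(fit, st2), "twi")
})

test_that("fitted suitability correlates strongly with the generating truth", {
  st <- small_stack(seed = 10)
  beta <- c(twi = 0.6, footprint = -0.5, dist_woody = -0.04, dist_woody2 = 0.004)
  tr <- simulate_trajectories(st, beta, n_animals = 6, n_steps = 300,
                              step_mean = 6, step_sd = 4, seed = 11)
  pa <- sample_pseudo_absences(tr, st, pseudo_ratio = 10, seed = 12)
  fit <- suppressMessages(fit_rsf(pa, covariates = c("twi", "footprint",
                                                     "dist_woody")))
  pred <- predict_suitability(fit, st)
  truth <- true_suitability(st, beta, intercept = fit$beta_raw[1])
  r <- stats::cor(as.vector(raster_values(pred)),
                  as.vector(raster_values(truth)))
  expect_gte(r, 0.9)
})
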