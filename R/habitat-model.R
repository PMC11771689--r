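#' Sample pseudo-absences around each GPS presence
#'
#' For every presence fix, `pseudo_ratio` available points are placed
#' area-uniformly within a disk whose radius is that animal's maximum
#' observed step length (the study design uses 50 per presence), clipped to
#' the landscape bounds. Time-varying covariates of an absence are matched
#' to its presence's timestamp.
#'
#' @param traj Trajectory tibble (`animal_id`, `timestamp`, `x`, `y`).
#' @param stack A `covariate_stack` supplying the covariates and bounds.
#' @param pseudo_ratio Absences per presence (default 50).
#' @param covariates Covariate columns to extract (default: all).
#' @param seed Integer seed.
#' @return Presence/absence tibble: `animal_id`, `is_presence` (1/0),
#'   `timestamp`, `x`, `y`, plus one column per covariate.
#' @export
sample_pseudo_absences <- function(traj, stack, pseudo_ratio = 50,
                                   covariates = NULL, seed = 1) {
  stopifnot(pseudo_ratio >= 1)
  bounds <- stack_bounds(stack)
  split_by_animal <- split(seq_len(nrow(traj)), traj$animal_id)
  bad <- names(split_by_animal)[vapply(split_by_animal, length, 1L) < 2]
  if (length(bad)) {
    stop("trajectory for animal(s) ", paste(bad, collapse = ", "),
         " has fewer than 2 fixes; maximum step length is undefined")
  }
  withr::with_seed(seed, {
    rows <- lapply(names(split_by_animal), function(id) {
      i <- split_by_animal[[id]]
      x <- traj$x[i]; y <- traj$y[i]; ts <- traj$timestamp[i]
      steps <- sqrt(diff(x)^2 + diff(y)^2)
      rmax <- max(steps)
      if (rmax <= 0) rmax <- stack_cell_size(stack)  # stationary animal
      n <- length(x)
      pres <- tibble::tibble(animal_id = id, is_presence = 1L,
                             timestamp = ts, x = x, y = y)
      # area-uniform in the disk, resampled into bounds
      m <- n * pseudo_ratio
      px <- rep(x, each = pseudo_ratio); py <- rep(y, each = pseudo_ratio)
      pt <- rep(ts, each = pseudo_ratio)
      ax <- numeric(m); ay <- numeric(m)
      todo <- seq_len(m)
      while (length(todo)) {
        r <- rmax * sqrt(stats::runif(length(todo)))
        th <- stats::runif(length(todo), 0, 2 * pi)
        ax[todo] <- px[todo] + r * cos(th)
        ay[todo] <- py[todo] + r * sin(th)
        inside <- ax[todo] >= bounds$xmin & ax[todo] <= bounds$xmax &
          ay[todo] >= bounds$ymin & ay[todo] <= bounds$ymax
        todo <- todo[!inside]
      }
      abs_ <- tibble::tibble(animal_id = id, is_presence = 0L,
                             timestamp = pt, x = ax, y = ay)
      dplyr::bind_rows(pres, abs_)
    })
    tab <- dplyr::bind_rows(rows)
    cov <- extract_covariates(stack, tab$x, tab$y, time = tab$timestamp)
    if (!is.null(covariates)) cov <- cov[, covariates, drop = FALSE]
    dplyr::bind_cols(tab, cov)
  })
}

#' Fit the resource selection function
#'
#' Logistic mixed model of presence vs pseudo-absence with a per-animal
#' random intercept, linear terms for every covariate and quadratic terms
#' for every distance covariate. Design columns are z-scored before fitting;
#' the standardization parameters are stored and reapplied at prediction,
#' and coefficients are also reported back-transformed to the raw covariate
#' scale. If the mixed fit fails (separation, non-convergence), the fit
#' falls back — flagged in `fit_meta$method` — to a fixed-effects logistic
#' model with animal indicator variables; the population-level coefficients
#' are the inference target either way.
#'
#' An alternative estimator, `method = "two_stage"`, fits an independent
#' logistic regression per animal and averages the coefficients, reporting
#' the between-animal empirical standard error (`sd / sqrt(n_animals)`).
#' Its point estimates are close to the mixed model's, but its standard
#' errors remain honest under the serial autocorrelation of GPS fixes,
#' which model-based standard errors from the pooled fit understate; it is
#' the estimator used for parameter-recovery experiments.
#'
#' @param table Presence/absence tibble from [sample_pseudo_absences()].
#' @param covariates Covariate names entering the model (default: all stack
#'   covariates present in `table`).
#' @param method `"glmm"` (default; Laplace-approximation logistic mixed
#'   model) or `"two_stage"` (per-animal fits, between-animal SEs).
#' @param ridge Small ridge penalty used by the non-mixed fitters to break
#'   ties under separation (default 1e-8).
#' @return An `rsf_fit` with elements `beta`, `se` (standardized scale),
#'   `beta_raw`, `se_raw`, `scaling`, `random_intercept_sd`, `fit_meta`.
#' @export
fit_rsf <- function(table, covariates = NULL, method = c("glmm", "two_stage"),
                    ridge = 1e-8) {
  method <- match.arg(method)
  if (length(unique(table$animal_id)) < 2L) {
    stop("fit_rsf needs >= 2 animals for the random intercept")
  }
  if (length(unique(table$is_presence)) < 2L) {
    stop("fit_rsf needs both presences and absences")
  }
  X <- rsf_design(table, covariates)
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " rows with non-finite covariates dropped")
    X <- X[keep, , drop = FALSE]; table <- table[keep, , drop = FALSE]
  }
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("constant design column(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  dat <- data.frame(is_presence = table$is_presence,
                    animal_id = factor(table$animal_id), Z, check.names = FALSE)
  terms <- colnames(Z)
  if (method == "two_stage") {
    return(fit_rsf_two_stage(dat, terms, mu, sdv, ridge))
  }
  fml <- stats::as.formula(paste(
    "is_presence ~", paste(sprintf("`%s`", terms), collapse = " + "),
    "+ (1 | animal_id)"))
  fit <- NULL; method <- "glmer_laplace"; diag_msg <- character()
  fit <- tryCatch(
    withCallingHandlers(
      lme4::glmer(fml, data = dat, family = stats::binomial("logit"),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) {
        diag_msg <<- c(diag_msg, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) { diag_msg <<- c(diag_msg, conditionMessage(e)); NULL })
  if (!is.null(fit)) {
    beta_all <- lme4::fixef(fit)
    se_all <- sqrt(Matrix::diag(stats::vcov(fit)))
    ri_sd <- sqrt(unlist(lme4::VarCorr(fit))[["animal_id"]])
    ll <- as.numeric(stats::logLik(fit))
  } else {
    method <- "fixed_fallback"
    message("mixed model failed (", paste(diag_msg, collapse = "; "),
            "); falling back to fixed-effects logistic with animal indicators")
    A <- stats::model.matrix(~ animal_id, dat)[, -1, drop = FALSE]
    Xf <- cbind(`(Intercept)` = 1, Z, A)
    fit <- ridge_logistic(Xf, dat$is_presence, ridge)
    beta_all <- fit$coef
    se_all <- fit$se
    ri_sd <- stats::sd(c(0, beta_all[grep("^animal_id", names(beta_all))]))
    if (!is.finite(ri_sd)) ri_sd <- 0
    ll <- fit$logLik
  }
  nm <- c("(Intercept)", terms)
  pick <- match(c("(Intercept)", sprintf("`%s`", terms)), names(beta_all))
  if (anyNA(pick)) pick <- match(nm, names(beta_all))
  beta <- stats::setNames(beta_all[pick], nm)
  se <- stats::setNames(se_all[pick], nm)
  beta_raw <- c(beta[1] - sum(beta[-1] * mu / sdv), beta[-1] / sdv)
  se_raw <- c(se[1], se[-1] / sdv)
  names(beta_raw) <- names(se_raw) <- nm
  structure(list(
    beta = beta, se = se, beta_raw = beta_raw, se_raw = se_raw,
    scaling = tibble::tibble(term = terms, mean = mu, sd = sdv),
    random_intercept_sd = ri_sd,
    covariates = unique(sub("2$", "", terms)),
    fit_meta = list(method = method, logLik = ll, n = nrow(dat),
                    n_animals = nlevels(dat$animal_id),
                    messages = diag_msg),
    model = fit), class = "rsf_fit")
}

# Two-stage estimator: logistic fit per animal, coefficients averaged,
# SE = between-animal SD / sqrt(n_animals).
fit_rsf_two_stage <- function(dat, terms, mu, sdv, ridge) {
  animals <- levels(dat$animal_id)
  Zm <- as.matrix(dat[, terms, drop = FALSE])
  ests <- matrix(NA_real_, length(animals), length(terms) + 1L,
                 dimnames = list(animals, c("(Intercept)", terms)))
  lls <- numeric(length(animals))
  for (k in seq_along(animals)) {
    i <- dat$animal_id == animals[k]
    f <- ridge_logistic(cbind(`(Intercept)` = 1, Zm[i, , drop = FALSE]),
                        dat$is_presence[i], ridge)
    ests[k, ] <- f$coef
    lls[k] <- f$logLik
  }
  nm <- colnames(ests)
  beta <- colMeans(ests)
  se <- apply(ests, 2, stats::sd) / sqrt(nrow(ests))
  beta_raw <- c(beta[1] - sum(beta[-1] * mu / sdv), beta[-1] / sdv)
  se_raw <- c(se[1], se[-1] / sdv)
  names(beta_raw) <- names(se_raw) <- nm
  structure(list(
    beta = beta, se = se, beta_raw = beta_raw, se_raw = se_raw,
    scaling = tibble::tibble(term = terms, mean = mu, sd = sdv),
    random_intercept_sd = stats::sd(ests[, 1]),
    covariates = unique(sub("2$", "", terms)),
    fit_meta = list(method = "two_stage", logLik = sum(lls), n = nrow(dat),
                    n_animals = length(animals), messages = character()),
    model = NULL, animal_estimates = ests), class = "rsf_fit")
}

# IRLS logistic with a small ridge on the design: breaks separation ties
# while leaving a well-posed fit numerically unchanged.
ridge_logistic <- function(X, y, ridge = 1e-8, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  P <- diag(ridge, p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  H <- crossprod(X, X * pmax(mu * (1 - mu), 1e-12)) + P
  list(coef = stats::setNames(as.vector(beta), colnames(X)),
       se = stats::setNames(sqrt(diag(solve(H))), colnames(X)),
       logLik = sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300))))
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %s | n = %d (%d animals) | logLik = %.1f\n",
              x$fit_meta$method, x$fit_meta$n, x$fit_meta$n_animals,
              x$fit_meta$logLik))
  cat(sprintf("  random intercept SD: %.3f\n", x$random_intercept_sd))
  print(tidy.rsf_fit(x), n = length(x$beta))
  invisible(x)
}

#' Tidy RSF coefficients
#' @param x An `rsf_fit`.
#' @param scale `"standardized"` (fitting scale) or `"raw"` (original
#'   covariate units, distances in km).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`.
#' @export
tidy.rsf_fit <- function(x, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  b <- if (scale == "raw") x$beta_raw else x$beta
  s <- if (scale == "raw") x$se_raw else x$se
  tibble::tibble(term = names(b), estimate = unname(b),
                 std.error = unname(s), statistic = unname(b / s))
}

#' One-row RSF fit summary
#' @param x An `rsf_fit`.
#' @param ... Unused.
#' @export
glance.rsf_fit <- function(x, ...) {
  tibble::tibble(logLik = x$fit_meta$logLik, nobs = x$fit_meta$n,
                 n_animals = x$fit_meta$n_animals,
                 random_intercept_sd = x$random_intercept_sd,
                 method = x$fit_meta$method)
}

#' Predict a habitat-suitability surface
#'
#' Cellwise inverse-logit of the fitted linear predictor (random intercept
#' at zero: a population-level prediction). For the migratory-phase map the
#' NDVI covariate is replaced by its long-term series mean, and dNDVI by a
#' named green-up snapshot.
#'
#' @param fit An `rsf_fit`.
#' @param stack A `covariate_stack` containing every model covariate.
#' @param ndvi_mode `"long_term_mean"` (default) or `"layer"` (use the
#'   stack's static `ndvi` layer unchanged).
#' @param dndvi_snapshot Date of the dNDVI snapshot; default the stack's
#'   static `dndvi` layer.
#' @return `fw_raster` of suitability clamped to (eps, 1 - eps).
#' @export
predict_suitability <- function(fit, stack, ndvi_mode = "long_term_mean",
                                dndvi_snapshot = NULL) {
  tmpl <- stack_template(stack)
  missing <- setdiff(fit$covariates, names(stack$layers))
  if (length(missing)) {
    stop("covariate layer(s) missing from stack: ",
         paste(missing, collapse = ", "))
  }
  cc <- cell_centers(tmpl)
  cov <- extract_covariates(stack, cc$x, cc$y, time = NULL)
  if ("ndvi" %in% fit$covariates && ndvi_mode == "long_term_mean" &&
      !is.null(stack$ndvi_series)) {
    cov$ndvi <- as.vector(raster_values(ndvi_series_mean(stack)))
  }
  if ("dndvi" %in% fit$covariates && !is.null(dndvi_snapshot)) {
    cov$dndvi <- as.vector(raster_values(ndvi_change_snapshot(stack, dndvi_snapshot)))
  }
  X <- rsf_design(cov, fit$covariates)
  sc <- fit$scaling
  Z <- sweep(sweep(X[, sc$term, drop = FALSE], 2, sc$mean), 2, sc$sd, "/")
  eta <- fit$beta[1] + as.vector(Z %*% fit$beta[-1])
  p <- stats::plogis(eta)
  eps <- .Machine$double.eps
  p <- pmin(pmax(p, eps), 1 - eps)
  d <- dim(tmpl$values)
  fw_raster(matrix(p, d[1], d[2]), tmpl$cell_size, tmpl$origin, tmpl$nodata)
}
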