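# Independent validation of modeled surfaces: do suitability, connectivity,
# and connectivity change differ between occurrence locations and matched
# pseudo-absences, at the regional and the local (restoration ROI) scale?

#' Sample a modeled metric at presence/pseudo-absence points
#'
#' Nearest-cell sampling of a raster at every row of a presence/absence
#' table; rows falling outside the grid or on nodata cells are dropped with
#' a logged count.
#'
#' @param raster An `fw_raster` (suitability, current, or change surface).
#' @param table Presence/absence tibble with `x`, `y` columns.
#' @param name Column name for the sampled metric (default `"metric"`).
#' @return `table` augmented with the sampled column, invalid rows dropped.
#' @export
extract_metric_at_points <- function(raster, table, name = "metric") {
  v <- raster_extract(raster, table$x, table$y)
  bad <- is.na(v)
  if (all(bad)) stop("all points fall outside valid raster cells")
  if (any(bad)) {
    message(sum(bad), " points outside valid cells dropped")
  }
  out <- table[!bad, , drop = FALSE]
  out[[name]] <- v[!bad]
  out
}

#' Compare a modeled metric between presences and pseudo-absences
#'
#' Mixed model of the (transformed) metric against presence status with a
#' per-animal random intercept; returns the presence coefficient and its
#' SE — the Table-1-style validation contrast. Transforms: `"logit"` for
#' suitability-like metrics in (0,1), `"log"` for current (zeros handled by
#' an offset of half the smallest positive value, reported), `"none"` for
#' signed metrics like connectivity change. With `method = "beta"` the
#' untransformed (0,1) metric is fit by a beta-family GLMM (glmmTMB) instead
#' of a Gaussian mixed model.
#'
#' @param table Tibble with `animal_id`, `is_presence`, and the metric column.
#' @param metric Name of the metric column.
#' @param transform `"logit"`, `"log"`, or `"none"`.
#' @param scale_label `"regional"` or `"local"` (recorded in the result).
#' @param method `"lmm"` (Gaussian mixed model on the transformed metric,
#'   default) or `"beta"` (beta-family GLMM, logit link, ignores `transform`).
#' @return One-row tibble: `metric`, `scale`, `coefficient`, `se`,
#'   `statistic`, `transform`, `n`.
#' @export
compare_presence_absence <- function(table, metric,
                                     transform = c("logit", "log", "none"),
                                     scale_label = "regional",
                                     method = c("lmm", "beta")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  if (length(unique(table$is_presence)) < 2L) {
    stop("both presences and pseudo-absences are required")
  }
  y <- table[[metric]]
  if (is.null(y)) stop("no column '", metric, "' in table")
  if (stats::sd(y[is.finite(y)]) == 0) {
    stop("metric '", metric, "' is constant; the contrast is undefined")
  }
  dat <- data.frame(y = y, is_presence = table$is_presence,
                    animal_id = factor(table$animal_id))
  dat <- dat[is.finite(dat$y) | method == "beta", , drop = FALSE]
  used_transform <- transform
  if (method == "beta") {
    if (any(dat$y <= 0 | dat$y >= 1)) {
      eps <- 1e-6
      dat$y <- pmin(pmax(dat$y, eps), 1 - eps)
    }
    fit <- glmmTMB::glmmTMB(y ~ is_presence + (1 | animal_id), data = dat,
                            family = glmmTMB::beta_family())
    sm <- summary(fit)$coefficients$cond
    used_transform <- "beta_logit"
  } else {
    if (transform == "logit") {
      if (any(dat$y <= 0 | dat$y >= 1)) {
        stop("logit transform needs values strictly in (0,1)")
      }
      dat$y <- stats::qlogis(dat$y)
    } else if (transform == "log") {
      if (any(dat$y < 0)) stop("log transform needs non-negative values")
      if (any(dat$y == 0)) {
        off <- min(dat$y[dat$y > 0]) / 2
        message("zeros under log transform: offset ", signif(off, 3), " added")
        dat$y <- dat$y + off
        used_transform <- "log_offset"
      }
      dat$y <- log(dat$y)
    }
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ is_presence + (1 | animal_id), data = dat, REML = TRUE)))
    sm <- stats::coef(summary(fit))
  }
  est <- sm["is_presence", "Estimate"]
  se <- sm["is_presence", "Std. Error"]
  tibble::tibble(metric = metric, scale = scale_label,
                 coefficient = unname(est), se = unname(se),
                 statistic = unname(est / se), transform = used_transform,
                 n = nrow(dat))
}

#' Table-1-style validation of all modeled metrics
#'
#' Runs the presence-vs-pseudo-absence contrast for suitability,
#' pre-fencing connectivity, fenced connectivity, and connectivity change
#' at the regional scale (all points) and the local scale (points inside
#' the restoration ROI).
#'
#' @param table Validation presence/absence tibble (from
#'   [sample_pseudo_absences()] on the validation trajectories).
#' @param surfaces Named list of `fw_raster`s:
#'   `suitability`, `prefence_current`, `fenced_current`, `change`.
#' @param roi Polygon(s) defining the local scale.
#' @return Tibble with one row per metric x scale.
#' @export
validate_surfaces <- function(table, surfaces, roi) {
  specs <- tibble::tribble(
    ~metric, ~transform,
    "suitability", "logit",
    "prefence_current", "log",
    "fenced_current", "log",
    "change", "none")
  specs <- specs[specs$metric %in% names(surfaces), ]
  polys <- if (is.list(roi) && !is.matrix(roi)) roi else list(roi)
  na_row <- function(metric, scale, transform, n) {
    tibble::tibble(metric = metric, scale = scale, coefficient = NA_real_,
                   se = NA_real_, statistic = NA_real_,
                   transform = transform, n = n)
  }
  out <- purrr::pmap(specs, function(metric, transform) {
    tab <- extract_metric_at_points(surfaces[[metric]], table, name = metric)
    reg <- tryCatch(
      compare_presence_absence(tab, metric, transform, "regional"),
      error = function(e) na_row(metric, "regional", transform, nrow(tab)))
    loc_tab <- tab[point_in_roi_rows(tab, polys), , drop = FALSE]
    loc <- tryCatch(
      compare_presence_absence(loc_tab, metric, transform, "local"),
      error = function(e) na_row(metric, "local", transform, nrow(loc_tab)))
    dplyr::bind_rows(reg, loc)
  })
  dplyr::bind_rows(out)
}

point_in_roi_rows <- function(tab, polys) {
  inside <- rep(FALSE, nrow(tab))
  for (p in polys) inside <- inside | point_in_polygon(tab$x, tab$y, p)
  inside
}
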