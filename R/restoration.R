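# Fence-removal scenario evaluation: corridor geometry, fence clipping,
# connectivity improvement, and area-based removal cost.

#' Corridor scenario geometry
#'
#' A candidate restoration corridor: a centerline buffered by half the
#' corridor width on each side with flat caps (per-segment rectangles; at
#' bends the rectangles overlap, which the area accounting corrects for).
#'
#' @param corridor_id Corridor label (e.g. `"CI"`).
#' @param centerline Two-column vertex matrix (metres).
#' @param width_km Corridor width in km (> 0).
#' @return A `corridor_scenario` with precomputed buffer rectangles.
#' @export
corridor_scenario <- function(corridor_id, centerline, width_km) {
  centerline <- as.matrix(centerline)
  stopifnot(width_km > 0, ncol(centerline) == 2L, nrow(centerline) >= 2L)
  structure(list(corridor_id = corridor_id, centerline = centerline,
                 width_km = width_km,
                 rects = buffer_rectangles(centerline, width_km * 1000 / 2)),
            class = "corridor_scenario")
}

# Flat-capped rectangle (CCW) around each centerline segment.
buffer_rectangles <- function(centerline, half_width) {
  n <- nrow(centerline)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- centerline[i, ]; b <- centerline[i + 1L, ]
    d <- b - a; len <- sqrt(sum(d^2))
    if (len < 1e-12) next
    u <- d / len
    nv <- c(-u[2], u[1]) * half_width
    out[[i]] <- rbind(a - nv, b - nv, b + nv, a + nv)
  }
  out[!vapply(out, is.null, logical(1))]
}

# Is each point inside the corridor buffer (any rectangle)?
in_corridor <- function(scenario, px, py) {
  inside <- rep(FALSE, length(px))
  for (rect in scenario$rects) {
    todo <- which(!inside)
    if (!length(todo)) break
    ok <- rep(TRUE, length(todo))
    for (i in 1:4) {
      a <- rect[i, ]; b <- rect[i %% 4 + 1L, ]
      nx <- -(b[2] - a[2]); ny <- b[1] - a[1]
      ok <- ok & ((px[todo] - a[1]) * nx + (py[todo] - a[2]) * ny >= 0)
    }
    inside[todo] <- ok
  }
  inside
}

#' Remove fences inside a corridor
#'
#' Deletes every portion of every fence polyline that falls inside the
#' buffered corridor; portions outside are retained (segments are clipped
#' exactly at the buffer boundary, by half-plane interval clipping against
#' the per-segment buffer rectangles). Returns the modified network with the
#' removed length and the set of fence lines touched.
#'
#' @param fences A `fence_network`.
#' @param scenario A `corridor_scenario`.
#' @return List: `fences` (clipped `fence_network`), `removed_length_m`,
#'   `lines_touched` (ids of fence lines partially or wholly removed).
#' @export
apply_scenario <- function(fences, scenario) {
  if (nrow(fences) == 0L) {
    return(list(fences = fences, removed_length_m = 0,
                lines_touched = character()))
  }
  removed <- 0
  touched <- character()
  new_lines <- list(); new_ids <- character()
  for (li in seq_len(nrow(fences))) {
    m <- fences$geometry[[li]]
    kept_pieces <- list()
    line_removed <- 0
    for (si in seq_len(nrow(m) - 1L)) {
      p1 <- m[si, ]; p2 <- m[si + 1L, ]
      seg_len <- sqrt(sum((p2 - p1)^2))
      if (seg_len < 1e-12) next
      ivals <- list()
      for (rect in scenario$rects) {
        iv <- clip_segment_convex(p1, p2, rect)
        if (!is.null(iv) && iv[2] > iv[1] + 1e-12) ivals[[length(ivals) + 1L]] <- iv
      }
      inside <- merge_intervals(ivals)
      line_removed <- line_removed +
        seg_len * sum(vapply(inside, function(iv) iv[2] - iv[1], numeric(1)))
      outside <- complement_intervals(inside)
      for (iv in outside) {
        a <- p1 + iv[1] * (p2 - p1); b <- p1 + iv[2] * (p2 - p1)
        kept_pieces[[length(kept_pieces) + 1L]] <- rbind(a, b)
      }
    }
    if (line_removed > 1e-9) touched <- c(touched, fences$id[li])
    removed <- removed + line_removed
    # re-join contiguous kept pieces into polylines
    pieces <- join_pieces(kept_pieces)
    for (k in seq_along(pieces)) {
      new_lines[[length(new_lines) + 1L]] <- pieces[[k]]
      new_ids <- c(new_ids,
                   if (length(pieces) == 1L) fences$id[li]
                   else sprintf("%s.%d", fences$id[li], k))
    }
  }
  list(fences = fence_network(new_lines, new_ids),
       removed_length_m = removed, lines_touched = touched)
}

# Union of parametric intervals within [0, 1].
merge_intervals <- function(ivals) {
  if (!length(ivals)) return(list())
  m <- do.call(rbind, ivals)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2] + 1e-12) {
      out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      out[[length(out) + 1L]] <- m[i, ]
    }
  }
  out
}

complement_intervals <- function(inside) {
  if (!length(inside)) return(list(c(0, 1)))
  out <- list()
  lo <- 0
  for (iv in inside) {
    if (iv[1] > lo + 1e-12) out[[length(out) + 1L]] <- c(lo, iv[1])
    lo <- max(lo, iv[2])
  }
  if (lo < 1 - 1e-12) out[[length(out) + 1L]] <- c(lo, 1)
  out
}

# Chain kept 2-point pieces back into polylines where endpoints coincide.
join_pieces <- function(pieces) {
  if (!length(pieces)) return(list())
  out <- list(pieces[[1]])
  for (p in pieces[-1]) {
    last <- out[[length(out)]]
    if (sqrt(sum((last[nrow(last), ] - p[1, ])^2)) < 1e-9) {
      out[[length(out)]] <- rbind(last, p[2, , drop = FALSE])
    } else {
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Connectivity improvement restored by a scenario
#'
#' The percentage of the connectivity lost between the pre-fencing and
#' fenced states that a removal scenario restores over the region of
#' interest: `100 * (scenario - fenced) / (pre - fenced)`. May exceed 100
#' if a scenario outperforms the pre-fencing baseline over the ROI.
#'
#' @param sum_pre,sum_fenced,sum_scenario Summed ROI current in the
#'   pre-fencing, fenced, and scenario states; requires
#'   `sum_pre > sum_fenced` (a loss to restore).
#' @return Improvement percentage.
#' @export
improvement_metric <- function(sum_pre, sum_fenced, sum_scenario) {
  if (sum_pre <= sum_fenced) {
    stop("no connectivity loss to restore (sum_pre <= sum_fenced); ",
         "improvement is undefined")
  }
  100 * (sum_scenario - sum_fenced) / (sum_pre - sum_fenced)
}

#' Fence-removal cost of a scenario
#'
#' Cost is proportional to the fenced-parcel area intersecting the buffered
#' corridor (only the land portion inside the corridor counts), at the
#' per-acre compensation rate paid for voluntary de-fencing (default
#' US$75/acre).
#'
#' @param parcels Parcel list from [detect_parcels()].
#' @param scenario A `corridor_scenario`.
#' @param unit_cost_per_acre USD per acre (default 75).
#' @return List: `cost_usd`, `area_acres`, `n_parcels_intersected`.
#' @export
scenario_cost <- function(parcels, scenario, unit_cost_per_acre = 75) {
  stopifnot(unit_cost_per_acre > 0)
  total_m2 <- 0; n_hit <- 0L
  rects <- scenario$rects
  for (p in parcels) {
    a <- sum(vapply(rects, function(rc) polygon_clip_area(p$polygon, rc),
                    numeric(1)))
    # subtract double-counted overlap of consecutive buffer rectangles
    if (length(rects) > 1L) {
      for (i in seq_len(length(rects) - 1L)) {
        piece <- clip_polygon_convex(p$polygon, rects[[i]])
        if (!is.null(piece)) a <- a - polygon_clip_area(piece, rects[[i + 1L]])
      }
    }
    if (a > 1e-9) {
      total_m2 <- total_m2 + a
      n_hit <- n_hit + 1L
    }
  }
  area_acres <- total_m2 / ACRE_M2
  list(cost_usd = area_acres * unit_cost_per_acre, area_acres = area_acres,
       n_parcels_intersected = n_hit)
}

#' Evaluate the full corridor-by-width scenario grid
#'
#' For every combination of candidate corridor and width (the study design
#' is 3 corridors x widths 0.5, 1, 2, 3 km = 12 scenarios): remove the
#' fences inside the buffered corridor, rebuild the fenced resistance
#' surface from the reduced network, re-solve cumulative current, and score
#' the scenario by the share of fencing-induced connectivity loss restored
#' over the ROI, the fence length removed, and the parcel-area removal
#' cost. Results are sorted by improvement per dollar.
#'
#' @param resistance_prefence Pre-fencing resistance `fw_raster` (no fences
#'   burned in).
#' @param fences Full `fence_network` (the fenced state).
#' @param corridors Tibble with `corridor_id` and `centerline` (list of
#'   vertex matrices).
#' @param focal List of `focal_region`s.
#' @param widths_km Corridor widths in km (default `c(0.5, 1, 2, 3)`).
#' @param roi Region of interest: polygon(s) summed over; default the union
#'   of all corridor buffers at the maximum width plus `roi_margin_km`.
#' @param roi_margin_km Margin added to the default ROI width (default 1).
#' @param unit_cost_per_acre USD per acre (default 75).
#' @param barrier_value Fence resistance (default 100).
#' @param parcels Optional pre-computed parcels of `fences`.
#' @return A `scenario_results` tibble: `corridor_id`, `width_km`,
#'   `fence_km_removed`, `n_fences_removed`, `area_acres`, `n_parcels`,
#'   `cost_usd`, `improvement_pct`, `sum_pre`, `sum_fenced`,
#'   `sum_scenario`, sorted by improvement per dollar. Baseline maps are in
#'   `attr(,"baselines")`.
#' @export
run_scenarios <- function(resistance_prefence, fences, corridors, focal,
                          widths_km = c(0.5, 1, 2, 3), roi = NULL,
                          roi_margin_km = 1, unit_cost_per_acre = 75,
                          barrier_value = 100, parcels = NULL) {
  if (is.null(parcels)) parcels <- detect_parcels(fences)
  r_fenced <- burn_fences(resistance_prefence, fences, barrier_value,
                          parcels = parcels)
  g_pre <- build_graph(resistance_prefence, focal)
  g_fen <- build_graph(r_fenced, focal)
  cm_pre <- cumulative_current(g_pre)
  cm_fen <- cumulative_current(g_fen)
  if (is.null(roi)) {
    w_roi <- max(widths_km) + 2 * roi_margin_km
    roi <- unlist(lapply(seq_len(nrow(corridors)), function(i) {
      buffer_rectangles(corridors$centerline[[i]], w_roi * 1000 / 2)
    }), recursive = FALSE)
  }
  sum_pre <- summed_current(cm_pre, roi)
  sum_fen <- summed_current(cm_fen, roi)
  grid <- tidyr::expand_grid(ci = seq_len(nrow(corridors)), width = widths_km)
  rows <- purrr::pmap(grid, function(ci, width) {
    scen <- corridor_scenario(corridors$corridor_id[[ci]],
                              corridors$centerline[[ci]], width)
    res <- tryCatch({
      rem <- apply_scenario(fences, scen)
      r_scen <- burn_fences(resistance_prefence, rem$fences, barrier_value)
      cm_scen <- cumulative_current(build_graph(r_scen, focal))
      sum_scen <- summed_current(cm_scen, roi)
      cost <- scenario_cost(parcels, scen, unit_cost_per_acre)
      tibble::tibble(
        corridor_id = scen$corridor_id, width_km = width,
        fence_km_removed = rem$removed_length_m / 1000,
        n_fences_removed = length(rem$lines_touched),
        area_acres = cost$area_acres, n_parcels = cost$n_parcels_intersected,
        cost_usd = cost$cost_usd,
        improvement_pct = improvement_metric(sum_pre, sum_fen, sum_scen),
        sum_pre = sum_pre, sum_fenced = sum_fen, sum_scenario = sum_scen,
        failed = FALSE)
    }, error = function(e) {
      warning(sprintf("scenario %s @ %g km failed: %s",
                      corridors$corridor_id[[ci]], width, conditionMessage(e)))
      tibble::tibble(corridor_id = corridors$corridor_id[[ci]],
                     width_km = width, fence_km_removed = NA_real_,
                     n_fences_removed = NA_integer_, area_acres = NA_real_,
                     n_parcels = NA_integer_, cost_usd = NA_real_,
                     improvement_pct = NA_real_, sum_pre = sum_pre,
                     sum_fenced = sum_fen, sum_scenario = NA_real_,
                     failed = TRUE)
    })
    res
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(improvement_pct / pmax(cost_usd, 1e-9)))
  class(out) <- c("scenario_results", class(out))
  attr(out, "baselines") <- list(cm_pre = cm_pre, cm_fenced = cm_fen, roi = roi)
  out
}
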