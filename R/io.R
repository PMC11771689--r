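# Plain-text geospatial IO: rasters as ESRI ASCII grids, vector data as
# GeoJSON, trajectories as CSV. All coordinates are projected metres in one
# planar frame; no CRS handling.

#' Write a raster as an ESRI ASCII grid
#' @param r An `fw_raster`.
#' @param path Output `.asc` path.
#' @export
write_raster_ascii <- function(r, path) {
  d <- dim(r$values)
  nodata <- if (is.na(r$nodata)) -9999 else r$nodata
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - d[1] * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(row) paste(format(row, digits = 9, trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#' @param path Path to a `.asc` file.
#' @return An `fw_raster` (nodata cells as `NA`).
#' @export
read_raster_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  v <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) v[v == nodata] <- NA_real_
  fw_raster(v, hdr$cellsize,
            c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize))
}

geojson_feature <- function(geom_type, coords, props = list()) {
  list(type = "Feature",
       properties = props,
       geometry = list(type = geom_type, coordinates = coords))
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Write a fence network as GeoJSON LineStrings
#' @param fences A `fence_network`.
#' @param path Output `.geojson` path.
#' @export
write_fences_geojson <- function(fences, path) {
  feats <- lapply(seq_len(nrow(fences)), function(i) {
    m <- fences$geometry[[i]]
    geojson_feature("LineString",
                    lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2])),
                    props = list(id = fences$id[i]))
  })
  write_geojson(feats, path)
}

#' Read a GeoJSON LineString collection as a fence network
#' @param path Path to a `.geojson` file.
#' @export
read_fences_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lines <- list(); ids <- character()
  for (f in fc$features) {
    if (f$geometry$type != "LineString") next
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) c(p[[1]], p[[2]])))
    lines[[length(lines) + 1L]] <- m
    ids <- c(ids, if (!is.null(f$properties$id)) as.character(f$properties$id)
             else sprintf("F%d", length(lines)))
  }
  fence_network(lines, ids)
}

#' Write focal regions (or any named polygons) as GeoJSON Polygons
#' @param regions List of `focal_region`s.
#' @param path Output path.
#' @export
write_regions_geojson <- function(regions, path) {
  feats <- lapply(regions, function(rg) {
    m <- rbind(rg$polygon, rg$polygon[1, , drop = FALSE])
    geojson_feature(
      "Polygon",
      list(lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))),
      props = list(name = rg$name))
  })
  write_geojson(feats, path)
}

#' Read GeoJSON Polygons as focal regions
#' @param path Path to a `.geojson` file.
#' @export
read_regions_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- list()
  for (f in fc$features) {
    if (f$geometry$type != "Polygon") next
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 3L &&
        isTRUE(all.equal(m[1, ], m[nrow(m), ], check.attributes = FALSE))) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    nm <- if (!is.null(f$properties$name)) as.character(f$properties$name)
          else sprintf("R%d", length(out) + 1L)
    out[[length(out) + 1L]] <- focal_region(nm, m)
  }
  out
}

#' Write trajectories as CSV
#' @param traj Trajectory tibble (`animal_id`, `timestamp`, `x`, `y`).
#' @param path Output `.csv` path.
#' @export
write_trajectories_csv <- function(traj, path) {
  out <- dplyr::mutate(traj, timestamp = format(.data$timestamp,
                                                "%Y-%m-%dT%H:%M:%SZ",
                                                tz = "UTC"))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read trajectories from CSV
#' @param path Path to a trajectory CSV.
#' @param fix_interval Hours between fixes (stored as an attribute).
#' @export
read_trajectories_csv <- function(path, fix_interval = NA_real_) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           animal_id = readr::col_character(),
                           timestamp = readr::col_datetime(),
                           x = readr::col_double(),
                           y = readr::col_double()))
  attr(out, "fix_interval") <- fix_interval
  out
}

#' Write a parcel list as GeoJSON Polygons with area attributes
#' @param parcels Output of [detect_parcels()].
#' @param path Output path.
#' @export
write_parcels_geojson <- function(parcels, path) {
  feats <- lapply(parcels, function(p) {
    m <- rbind(p$polygon, p$polygon[1, , drop = FALSE])
    geojson_feature(
      "Polygon",
      list(lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))),
      props = list(id = p$id, area_m2 = p$area_m2, area_acres = p$area_acres,
                   fully_enclosed = p$fully_enclosed))
  })
  write_geojson(feats, path)
}
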