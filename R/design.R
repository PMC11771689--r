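# Shared covariate extraction and design-matrix construction used by the
# movement simulator (true selection weights), the presence/absence builder,
# and suitability prediction — one code path, so truth and fit agree on what
# a "covariate" is.

#' Extract covariate values at points
#'
#' Samples every stack layer at the nearest cell. Time-varying layers are
#' matched to `time`: NDVI is interpolated between the two nearest 16-day
#' composites and dNDVI is their difference. Distance layers are returned in
#' kilometres so selection coefficients are on an interpretable scale.
#'
#' @param stack A `covariate_stack`.
#' @param x,y Point coordinates (metres).
#' @param time Optional timestamps (`POSIXct`/`Date`), recycled; when `NULL`
#'   the stack's static `ndvi`/`dndvi` layers are used.
#' @return Tibble with one column per covariate; `NA` rows for points
#'   outside the grid.
#' @export
extract_covariates <- function(stack, x, y, time = NULL) {
  out <- lapply(names(stack$layers), function(nm) {
    v <- raster_extract(stack$layers[[nm]], x, y)
    if (startsWith(nm, "dist_")) v <- v / 1000
    v
  })
  names(out) <- names(stack$layers)
  out <- tibble::as_tibble(out)
  if (!is.null(time) && !is.null(stack$ndvi_series)) {
    idx <- cell_index(stack_template(stack), x, y)
    ok <- which(!is.na(idx$row))
    if (length(ok)) {
      time <- rep(time, length.out = length(x))
      tv <- ndvi_at_time(stack, idx$row[ok], idx$col[ok], time[ok])
      out$ndvi[ok] <- tv$ndvi
      out$dndvi[ok] <- tv$dndvi
    }
  }
  out
}

# Names of the design columns for a covariate set: distance covariates get a
# quadratic companion column "<name>2".
design_terms <- function(covariates) {
  unlist(lapply(covariates, function(nm) {
    if (startsWith(nm, "dist_")) c(nm, paste0(nm, "2")) else nm
  }), use.names = FALSE)
}

#' Build the selection design matrix from extracted covariates
#'
#' Linear columns for every covariate plus a quadratic column for each
#' distance covariate (non-linear responses to distance are expected
#' biologically). Columns are raw-scale; standardization happens inside
#' [fit_rsf()].
#'
#' @param tbl Tibble of extracted covariates (see [extract_covariates()]).
#' @param covariates Character vector of covariate names to use; defaults to
#'   all columns of `tbl` that are stack covariates.
#' @return Numeric matrix with named columns.
#' @export
rsf_design <- function(tbl, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(
      c("ndvi", "dndvi", "twi", "footprint",
        grep("^dist_", names(tbl), value = TRUE)),
      names(tbl))
  }
  missing <- setdiff(covariates, names(tbl))
  if (length(missing)) {
    stop("missing covariate column(s): ", paste(missing, collapse = ", "))
  }
  cols <- lapply(covariates, function(nm) {
    v <- tbl[[nm]]
    if (startsWith(nm, "dist_")) cbind(v, v^2) else cbind(v)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- design_terms(covariates)
  m
}
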