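#' Georeferenced multi-band raster
#'
#' Lightweight in-memory raster used throughout the pipeline. Values are held
#' as a `[row, col, band]` array with `NA` as the in-memory missing-value
#' marker (the `nodata` sentinel is only used on disk). Grids are north-up
#' with cell-center registration: the map origin `(x, y)` is the outer corner
#' of pixel `(1, 1)` (top-left), x increases with column, y decreases with
#' row.
#'
#' @param values numeric array `[row, col, band]`, or a matrix for one band.
#' @param bands character vector of band labels (one per band).
#' @param res ground sampling distance in m (single positive number).
#' @param origin numeric `c(x, y)` of the top-left outer corner.
#' @param date optional acquisition `Date`.
#' @param kind one of `"reflectance"`, `"lai"`, `"other"`; drives validation.
#' @param nodata sentinel written to file in place of `NA` (default -9999).
#' @return An object of class `sat_raster`.
#' @export
sat_raster <- function(values, bands, res, origin = c(0, 0), date = NULL,
                       kind = c("other", "reflectance", "lai"), nodata = -9999) {
  kind <- match.arg(kind)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("`values` must be a [row, col, band] array or a matrix")
  if (missing(bands)) bands <- dimnames(values)[[3]]
  bands <- as.character(bands)
  if (length(bands) != dim(values)[3L])
    stopf("%d band labels for %d bands", length(bands), dim(values)[3L])
  if (anyDuplicated(bands)) stopf("duplicated band labels")
  if (!is_scalar_num(res) || res <= 0) stopf("`res` must be a positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stopf("`origin` must be finite c(x, y)")
  storage.mode(values) <- "double"
  dimnames(values) <- list(NULL, NULL, bands)
  r <- structure(list(values = values, bands = bands, res = as.numeric(res),
                      origin = as.numeric(origin),
                      date = if (is.null(date)) NULL else as.Date(date),
                      kind = kind, nodata = as.numeric(nodata)),
                 class = "sat_raster")
  r
}

#' @export
print.sat_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sat_raster> %d x %d pixels, %d band(s) @ %g m [%s]\n",
              d[1], d[2], d[3], x$res, x$kind))
  cat("  bands:", paste(x$bands, collapse = ", "), "\n")
  cat(sprintf("  origin: (%g, %g)%s\n", x$origin[1], x$origin[2],
              if (is.null(x$date)) "" else paste0("  date: ", format(x$date))))
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat(sprintf("  range: [%.4g, %.4g], NA: %d\n",
                             min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.sat_raster <- function(x) dim(x$values)

raster_nrow <- function(r) dim(r$values)[1L]
raster_ncol <- function(r) dim(r$values)[2L]
raster_nband <- function(r) dim(r$values)[3L]

#' Validate raster invariants
#'
#' Reflectance rasters must lie in \[0, 1\] and LAI rasters must be
#' non-negative wherever not missing.
#'
#' @param r a [sat_raster].
#' @param kind validation class; defaults to the raster's own `kind`.
#' @return `r`, invisibly; errors on violation.
#' @export
validate_raster <- function(r, kind = r$kind) {
  if (!inherits(r, "sat_raster")) stopf("not a sat_raster")
  v <- r$values
  if (identical(kind, "reflectance")) {
    bad <- v[!is.na(v)]
    if (length(bad) && (min(bad) < 0 || max(bad) > 1))
      stopf("reflectance values outside [0, 1] (range %.4g..%.4g)",
            min(bad), max(bad))
  } else if (identical(kind, "lai")) {
    bad <- v[!is.na(v)]
    if (length(bad) && min(bad) < 0)
      stopf("LAI values below 0 (min %.4g)", min(bad))
  }
  invisible(r)
}

#' Extract one band as a matrix
#' @param r a [sat_raster].
#' @param band band label or index.
#' @return numeric matrix `[row, col]`.
#' @export
raster_band <- function(r, band) {
  if (is.character(band)) {
    i <- match(band, r$bands)
    if (is.na(i)) stopf("band '%s' not present (have: %s)", band,
                        paste(r$bands, collapse = ", "))
    band <- i
  }
  r$values[, , band, drop = TRUE]
}

# Map coordinates -> 1-based (row, col) of the containing pixel; floor rule,
# so points on a boundary belong to the lower-index pixel.
map_to_cell <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$res) + 1
  row <- floor((r$origin[2] - y) / r$res) + 1
  cbind(row = row, col = col)
}

# Map coordinates of a cell center.
cell_center <- function(r, row, col) {
  cbind(x = r$origin[1] + (col - 0.5) * r$res,
        y = r$origin[2] - (row - 0.5) * r$res)
}

#' Aggregate a raster by block mean
#'
#' Each output pixel is the arithmetic mean of the `factor` x `factor` block
#' of non-missing input pixels; a block that is entirely missing yields `NA`.
#' Trailing rows/columns not filling a whole block are dropped (with a
#' message). Used to carry the 3 m predictors onto the 30 m training grid.
#'
#' @param r a [sat_raster].
#' @param factor integer aggregation factor (>= 1).
#' @return A [sat_raster] at `res * factor`.
#' @export
aggregate_block_mean <- function(r, factor) {
  if (!is_scalar_num(factor) || factor < 1 || factor != round(factor))
    stopf("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(r)
  d <- dim(r$values)
  nr2 <- d[1L] %/% factor; nc2 <- d[2L] %/% factor
  if (nr2 < 1L || nc2 < 1L) stopf("raster smaller than one %d x %d block", factor, factor)
  if (nr2 * factor != d[1L] || nc2 * factor != d[2L])
    message(sprintf("aggregate_block_mean: dropping trailing partial blocks (%d row(s), %d col(s))",
                    d[1L] - nr2 * factor, d[2L] - nc2 * factor))
  out <- array(NA_real_, c(nr2, nc2, d[3L]))
  for (b in seq_len(d[3L])) {
    m <- r$values[seq_len(nr2 * factor), seq_len(nc2 * factor), b]
    a <- aperm(array(m, c(factor, nr2, factor, nc2)), c(1L, 3L, 2L, 4L))
    dim(a) <- c(factor * factor, nr2 * nc2)
    s <- colSums(a, na.rm = TRUE)
    n <- colSums(!is.na(a))
    v <- s / n
    v[n == 0L] <- NA_real_
    out[, , b] <- v
  }
  sat_raster(out, r$bands, r$res * factor, r$origin, r$date, r$kind, r$nodata)
}

#' Mean over a square pixel window around a map location
#'
#' Averages the `window` x `window` block of pixels centered on the pixel
#' containing `center`, skipping missing values. This is the plot-evaluation
#' extractor (7 x 7 fine-sensor pixels around a measurement-zone center).
#'
#' @param r a [sat_raster].
#' @param center map coordinates `c(x, y)`.
#' @param window odd window size in pixels.
#' @param band band label or index (default first band).
#' @return single numeric value (`NA` if the whole window is missing).
#' @export
extract_window_mean <- function(r, center, window = 7L, band = 1L) {
  if (!is_scalar_num(window) || window < 1 || window %% 2 != 1)
    stopf("`window` must be a positive odd integer")
  rc <- map_to_cell(r, center[1], center[2])
  h <- (window - 1) / 2
  rows <- (rc[1, "row"] - h):(rc[1, "row"] + h)
  cols <- (rc[1, "col"] - h):(rc[1, "col"] + h)
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > raster_nrow(r) || max(cols) > raster_ncol(r))
    stopf("window footprint crosses the raster edge at (%.1f, %.1f)",
          center[1], center[2])
  m <- raster_band(r, band)[rows, cols]
  if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
}

#' Read / write the field-observation table
#'
#' CSV with header `field_id,imz_id,x,y,date,lai,stage`, ISO-8601 dates.
#' `stage` may be empty; codes are restricted to the maize vegetative /
#' reproductive set V2, V6, V11, VT, R1..R6.
#'
#' @param path file path.
#' @return data frame with typed columns.
#' @export
read_field_observations <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "imz_id", "x", "y", "date", "lai", "stage")
  if (!all(need %in% names(df)))
    stopf("field-observation CSV must have columns %s", paste(need, collapse = ","))
  df$date <- as.Date(df$date)
  df$stage[!nzchar(trimws(as.character(df$stage)))] <- NA_character_
  check_observations(df)
  df
}

#' @rdname read_field_observations
#' @param obs observation data frame.
#' @export
write_field_observations <- function(obs, path) {
  check_observations(obs)
  out <- obs[, c("field_id", "imz_id", "x", "y", "date", "lai", "stage")]
  out$date <- format(as.Date(out$date))
  out$stage[is.na(out$stage)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stage_codes <- function() c("V2", "V6", "V11", "VT", "R1", "R2", "R3", "R4", "R5", "R6")

check_observations <- function(obs) {
  if (any(obs$lai < 0, na.rm = TRUE)) stopf("in-situ LAI must be >= 0")
  st <- obs$stage[!is.na(obs$stage)]
  bad <- setdiff(unique(st), stage_codes())
  if (length(bad)) stopf("unknown stage code(s): %s", paste(bad, collapse = ", "))
  invisible(obs)
}
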