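# The 19 vegetation indices used as LAI predictors. The 7 visible/NIR
# indices are computable from both sensors; the red-edge and SWIR indices
# need the coarse sensor. Formulas are evaluated on band-center reflectances
# looked up by label (b490 = 490 nm, ...), never by band position.

#' Vegetation-index definitions
#'
#' Returns the catalogue of the 19 supported indices: abbreviation, required
#' band labels, spectral category and sensor availability (`"both"` for the
#' visible/NIR set computable from the 4-band fine sensor, `"coarse"` for
#' indices needing red-edge or SWIR bands).
#'
#' @return data frame with columns `abbr`, `formula`, `bands` (list),
#'   `category`, `availability`.
#' @export
vi_definitions <- function() {
  def <- function(abbr, formula, bands, category, availability)
    list(abbr = abbr, formula = formula, bands = list(bands),
         category = category, availability = availability)
  rows <- list(
    def("SR",      "b865/b665", c("b865", "b665"), "V,NIR", "both"),
    def("NDVI",    "(b865-b665)/(b865+b665)", c("b865", "b665"), "V,NIR", "both"),
    def("OSAVI",   "1.16*(b865-b665)/(b865+b665+0.16)", c("b865", "b665"), "V,NIR", "both"),
    def("GSR",     "b865/b560", c("b865", "b560"), "V,NIR", "both"),
    def("GNDVI",   "(b865-b560)/(b865+b560)", c("b865", "b560"), "V,NIR", "both"),
    def("MTVI2",   "1.5*(1.2*(b865-b665)-2.5*(b665+b560))/sqrt((2*b865+1)^2-(b865-5*sqrt(b865))-0.5)",
        c("b865", "b665", "b560"), "V,NIR", "both"),
    def("EVI2",    "2.5*(b865-b665)/(b865+2.4*b665+1)", c("b865", "b665"), "V,NIR", "both"),
    def("MCARI",   "((b704-b665)-0.2*(b704-b560))*(b704/b665)", c("b704", "b665", "b560"), "V,RE", "coarse"),
    def("MTCI",    "(b740-b704)/(b704-b665)", c("b740", "b704", "b665"), "V,RE", "coarse"),
    def("VREI1",   "b740/b704", c("b740", "b704"), "RE", "coarse"),
    def("RENDVI",  "(b865-b704)/(b865+b704)", c("b865", "b704"), "RE,NIR", "coarse"),
    def("RENDVI2", "(b865-b740)/(b865+b740)", c("b865", "b740"), "RE,NIR", "coarse"),
    def("RSR",     "b865/b704", c("b865", "b704"), "RE,NIR", "coarse"),
    def("RSR2",    "b865/b740", c("b865", "b740"), "RE,NIR", "coarse"),
    def("NDWI",    "(b865-b1614)/(b865+b1614)", c("b865", "b1614"), "NIR,SWIR", "coarse"),
    def("NDWI2",   "(b865-b2202)/(b865+b2202)", c("b865", "b2202"), "NIR,SWIR", "coarse"),
    def("MSR",     "b865/b1614", c("b865", "b1614"), "NIR,SWIR", "coarse"),
    def("MSR2",    "b865/b2202", c("b865", "b2202"), "NIR,SWIR", "coarse"),
    def("PSRI",    "(b665-b560)/b704", c("b665", "b560", "b704"), "V,RE", "coarse"))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(abbr = r$abbr, formula = r$formula, category = r$category,
               availability = r$availability, bands = I(r$bands))
  }))
}

#' @rdname vi_definitions
#' @param availability `"both"`, `"coarse"` or `"all"`.
#' @return For `vi_abbreviations()`: character vector of index abbreviations.
#' @export
vi_abbreviations <- function(availability = c("all", "both", "coarse")) {
  availability <- match.arg(availability)
  d <- vi_definitions()
  if (availability == "all") d$abbr else d$abbr[d$availability == availability]
}

#' Export index definitions as JSON
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vi_definitions_json <- function(path) {
  d <- vi_definitions()
  out <- lapply(seq_len(nrow(d)), function(i) list(
    abbreviation = d$abbr[i], formula = d$formula[i],
    bands = d$bands[[i]], category = d$category[i],
    availability = d$availability[i]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Vectorized index evaluation on a named list/data.frame of band vectors.
# Zero denominators and negative square-root arguments yield NA (counted by
# the caller); no exceptions are thrown for numeric degeneracies.
vi_eval <- function(abbr, B, mtvi2_variant = c("pipeline", "literature")) {
  mtvi2_variant <- match.arg(mtvi2_variant)
  g <- function(label) {
    v <- B[[label]]
    if (is.null(v)) stopf("index %s requires band %s, which is missing", abbr, label)
    v
  }
  safe_div <- function(num, den) {
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  switch(abbr,
    SR      = safe_div(g("b865"), g("b665")),
    NDVI    = safe_div(g("b865") - g("b665"), g("b865") + g("b665")),
    OSAVI   = safe_div(1.16 * (g("b865") - g("b665")), g("b865") + g("b665") + 0.16),
    GSR     = safe_div(g("b865"), g("b560")),
    GNDVI   = safe_div(g("b865") - g("b560"), g("b865") + g("b560")),
    MTVI2   = {
      n <- g("b865"); r <- g("b665"); gr <- g("b560")
      num <- 1.5 * (1.2 * (n - r) - 2.5 * (r + gr))
      arg <- if (mtvi2_variant == "pipeline")
        (2 * n + 1)^2 - (n - 5 * sqrt(n)) - 0.5
      else
        (2 * n + 1)^2 - (6 * n - 5 * sqrt(r)) - 0.5
      arg[arg < 0] <- NA_real_
      safe_div(num, sqrt(arg))
    },
    EVI2    = safe_div(2.5 * (g("b865") - g("b665")), g("b865") + 2.4 * g("b665") + 1),
    MCARI   = ((g("b704") - g("b665")) - 0.2 * (g("b704") - g("b560"))) * safe_div(g("b704"), g("b665")),
    MTCI    = safe_div(g("b740") - g("b704"), g("b704") - g("b665")),
    VREI1   = safe_div(g("b740"), g("b704")),
    RENDVI  = safe_div(g("b865") - g("b704"), g("b865") + g("b704")),
    RENDVI2 = safe_div(g("b865") - g("b740"), g("b865") + g("b740")),
    RSR     = safe_div(g("b865"), g("b704")),
    RSR2    = safe_div(g("b865"), g("b740")),
    NDWI    = safe_div(g("b865") - g("b1614"), g("b865") + g("b1614")),
    NDWI2   = safe_div(g("b865") - g("b2202"), g("b865") + g("b2202")),
    MSR     = safe_div(g("b865"), g("b1614")),
    MSR2    = safe_div(g("b865"), g("b2202")),
    PSRI    = safe_div(g("b665") - g("b560"), g("b704")),
    stopf("unknown vegetation index '%s'", abbr))
}

#' Compute one vegetation index from band reflectances
#'
#' @param reflectances named numeric vector (or list) of band reflectances,
#'   labelled by band-center (`b865 = 0.4`, ...). Values may be vectors.
#' @param abbr index abbreviation (see [vi_definitions()]).
#' @param mtvi2_variant MTVI2 formula variant; the default follows the form
#'   used throughout this pipeline, `"literature"` selects the common
#'   published alternative.
#' @return numeric value(s); `NA` with a warning where the formula is
#'   undefined (zero denominator, negative square-root argument).
#' @export
compute_index <- function(reflectances, abbr, mtvi2_variant = c("pipeline", "literature")) {
  B <- as.list(reflectances)
  out <- vi_eval(abbr, B, match.arg(mtvi2_variant))
  n_bad <- sum(is.na(out) & !Reduce(`|`, lapply(B, is.na), FALSE))
  if (n_bad > 0)
    warnf("%s: %d value(s) undefined (zero denominator or negative sqrt argument); set to NA",
          abbr, n_bad)
  out
}

#' Compute a vegetation-index stack from a reflectance raster
#'
#' Applies [compute_index()] pixel-wise; the output raster has one band per
#' requested index, named by abbreviation. Missing input pixels propagate.
#'
#' @param r reflectance [sat_raster] with wavelength band labels.
#' @param profile the [sensor_profile] the raster comes from (availability
#'   check: red-edge/SWIR indices cannot be requested from the 4-band fine
#'   sensor).
#' @param indices character vector of abbreviations; default all indices
#'   available to the sensor.
#' @param mtvi2_variant see [compute_index()].
#' @return A [sat_raster] of class-kind `"other"` with index bands.
#' @export
compute_vi_stack <- function(r, profile, indices = NULL,
                             mtvi2_variant = c("pipeline", "literature")) {
  mtvi2_variant <- match.arg(mtvi2_variant)
  defs <- vi_definitions()
  if (is.null(indices)) {
    have <- function(b) all(b %in% profile$bands)
    indices <- defs$abbr[vapply(defs$bands, have, TRUE)]
  }
  bad <- setdiff(indices, defs$abbr)
  if (length(bad)) stopf("unknown index abbreviation(s): %s", paste(bad, collapse = ", "))
  for (abbr in indices) {
    need <- defs$bands[[match(abbr, defs$abbr)]]
    miss <- setdiff(need, profile$bands)
    if (length(miss))
      stopf("index %s needs band(s) %s not offered by sensor '%s'",
            abbr, paste(miss, collapse = ", "), profile$name)
    miss <- setdiff(need, r$bands)
    if (length(miss))
      stopf("index %s needs band(s) %s missing from the raster", abbr,
            paste(miss, collapse = ", "))
  }
  d <- dim(r$values)
  B <- stats::setNames(lapply(r$bands, function(b) as.vector(raster_band(r, b))), r$bands)
  out <- array(NA_real_, c(d[1L], d[2L], length(indices)))
  for (i in seq_along(indices))
    out[, , i] <- vi_eval(indices[i], B, mtvi2_variant)
  sat_raster(out, indices, r$res, r$origin, r$date, kind = "other", nodata = r$nodata)
}
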