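# Independent oracles and small constructors used across the suite.

# Hand-written index formulas, kept deliberately separate from the package's
# evaluator so the two can disagree.
oracle_vi <- list(
  SR      = function(b) b$b865 / b$b665,
  NDVI    = function(b) (b$b865 - b$b665) / (b$b865 + b$b665),
  OSAVI   = function(b) 1.16 * (b$b865 - b$b665) / (b$b865 + b$b665 + 0.16),
  GSR     = function(b) b$b865 / b$b560,
  GNDVI   = function(b) (b$b865 - b$b560) / (b$b865 + b$b560),
  MTVI2   = function(b) 1.5 * (1.2 * (b$b865 - b$b665) - 2.5 * (b$b665 + b$b560)) /
    sqrt((2 * b$b865 + 1)^2 - (b$b865 - 5 * sqrt(b$b865)) - 0.5),
  EVI2    = function(b) 2.5 * (b$b865 - b$b665) / (b$b865 + 2.4 * b$b665 + 1),
  MCARI   = function(b) ((b$b704 - b$b665) - 0.2 * (b$b704 - b$b560)) * (b$b704 / b$b665),
  MTCI    = function(b) (b$b740 - b$b704) / (b$b704 - b$b665),
  VREI1   = function(b) b$b740 / b$b704,
  RENDVI  = function(b) (b$b865 - b$b704) / (b$b865 + b$b704),
  RENDVI2 = function(b) (b$b865 - b$b740) / (b$b865 + b$b740),
  RSR     = function(b) b$b865 / b$b704,
  RSR2    = function(b) b$b865 / b$b740,
  NDWI    = function(b) (b$b865 - b$b1614) / (b$b865 + b$b1614),
  NDWI2   = function(b) (b$b865 - b$b2202) / (b$b865 + b$b2202),
  MSR     = function(b) b$b865 / b$b1614,
  MSR2    = function(b) b$b865 / b$b2202,
  PSRI    = function(b) (b$b665 - b$b560) / b$b704)

# Random 9-band reflectance draws as a named list of vectors.
random_bands <- function(n, seed = 1) {
  set.seed(seed)
  labs <- coarse_sensor()$bands
  setNames(lapply(labs, function(x) runif(n, 0.01, 0.95)), labs)
}

# Single-band raster from a matrix.
mk_raster <- function(m, res = 30, origin = c(0, nrow(m) * res), date = NULL,
                      band = "lai", kind = "lai") {
  sat_raster(array(m, c(nrow(m), ncol(m), 1L)), band, res, origin, date, kind)
}

# Multi-band raster from a named list of matrices.
mk_stack <- function(mats, res = 30, origin = NULL, date = NULL, kind = "other") {
  d <- dim(mats[[1]])
  origin <- origin %||% c(0, d[1] * res)
  v <- array(unlist(mats), c(d[1], d[2], length(mats)))
  sat_raster(v, names(mats), res, origin, date, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
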