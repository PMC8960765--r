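# Synthetic (vegetation index, LAI) training data from forward runs of a
# canopy reflectance model. The pipeline's forward-model contract is: a data
# frame of canopy/leaf/soil/geometry parameters in -> reflectance at the
# coarse sensor's nine band centers out, deterministic given the parameters.
# A full PROSPECT+SAIL backend can be plugged in behind the same contract;
# the packaged `toy_forward` is a transparent two-stream caricature
# (Beer-Lambert extinction between a soil and a dense-canopy spectrum) that
# preserves the features the retrieval relies on: per-band monotonicity in
# LAI, NIR saturation, soil-brightness and pigment sensitivity.

#' Default canopy-parameter distributions
#'
#' All parameters are drawn independently and uniformly within the listed
#' bounds; LAI is a mixture enriched for bare-soil conditions. Units: LAI
#' m2/m2; cab ug/cm2; cw cm; cm g/cm2; ala, sza, vza, raa degrees; psoil,
#' n_struct, hotspot unitless.
#'
#' @return named list of `c(lower, upper)` bounds plus mixture settings.
#' @export
rt_param_defaults <- function() {
  list(
    lai = c(0, 7), lai_bare_frac = 0.15, lai_bare_max = 0.5,
    cab = c(20, 80), cw = c(0.005, 0.03), cm = c(0.003, 0.011),
    n_struct = c(1.2, 1.8), ala = c(30, 70), hotspot = c(0.05, 0.5),
    psoil = c(0, 1), sza = c(20, 50), vza = c(0, 10), raa = c(0, 180))
}

#' Sample canopy parameter vectors
#'
#' @param n number of draws (>= 1).
#' @param seed integer seed; draws are reproducible.
#' @param config bounds list as returned by [rt_param_defaults()]; entries
#'   may be overridden individually.
#' @return data frame with one row per draw and the columns of
#'   [rt_param_defaults()].
#' @export
sample_canopy_params <- function(n, seed, config = rt_param_defaults()) {
  if (!is_scalar_num(n) || n < 1) stopf("`n` must be >= 1")
  config <- utils::modifyList(rt_param_defaults(), config)
  vars <- c("lai", "cab", "cw", "cm", "n_struct", "ala", "hotspot",
            "psoil", "sza", "vza", "raa")
  for (v in vars) {
    b <- config[[v]]
    if (length(b) != 2L || b[1] > b[2])
      stopf("invalid bounds for %s: [%g, %g]", v, b[1], b[2])
  }
  with_seed(seed, {
    draws <- lapply(vars, function(v) stats::runif(n, config[[v]][1], config[[v]][2]))
    names(draws) <- vars
    df <- as.data.frame(draws)
    # bare-soil enrichment: a fraction of rows redrawn from a low-LAI slab
    bare <- stats::runif(n) < config$lai_bare_frac
    if (any(bare))
      df$lai[bare] <- stats::runif(sum(bare), config$lai[1],
                                   min(config$lai_bare_max, config$lai[2]))
    df
  })
}

# Tabulated endmember spectra at the coarse sensor's nine band centers
# (490, 560, 665, 704, 740, 783, 865, 1614, 2202 nm).
.toy_soil_base <- c(0.06, 0.08, 0.11, 0.13, 0.15, 0.17, 0.19, 0.26, 0.23)
.toy_leaf_base <- c(0.04, 0.10, 0.05, 0.16, 0.32, 0.50, 0.52, 0.28, 0.16)
.toy_k0       <- c(0.85, 0.75, 0.90, 0.70, 0.60, 0.55, 0.50, 0.55, 0.60)

toy_geo_factor <- function(params) {
  1 + 0.03 * (cos(params$sza * pi / 180) - 0.8) + 0.01 * params$hotspot
}

#' Soil spectrum of the toy forward model
#'
#' The zero-LAI limit of [toy_forward()] for the given parameters: the base
#' soil spectrum scaled by soil brightness (`psoil`) and the (small)
#' geometric brightness factor.
#'
#' @param params one-or-more-row data frame of canopy parameters.
#' @return matrix `[n, 9]` of reflectances with coarse-sensor band labels.
#' @export
toy_soil_spectrum <- function(params) {
  bright <- 0.5 + params$psoil          # psoil in [0,1] -> 0.5x..1.5x
  geo <- toy_geo_factor(params)
  out <- outer(bright * geo, .toy_soil_base)
  colnames(out) <- names(coarse_sensor()$wavelengths)
  out
}

toy_leaf_spectrum <- function(params) {
  f_cab <- pmin(2, pmax(0.5, (50 / params$cab)^0.6))     # pigment absorption
  f_cw  <- pmin(1.5, pmax(0.6, (0.015 / params$cw)^0.5)) # leaf water (SWIR)
  f_nir <- 0.9 + 0.1 * params$n_struct                   # mesophyll scattering
  f_cm  <- 1 + 8 * (params$cm - 0.007)                   # dry matter
  n <- length(params$cab)
  L <- matrix(rep(.toy_leaf_base, each = n), n, 9)
  vis <- 1:4
  L[, vis] <- L[, vis] * f_cab
  L[, 5] <- L[, 5] * f_cab^0.3                           # red-edge shoulder
  L[, 6:7] <- L[, 6:7] * f_nir
  L[, 8:9] <- L[, 8:9] * f_cw * f_cm
  L
}

#' Toy canopy forward model
#'
#' Two-stream exponential mixing between a soil and an asymptotic canopy
#' spectrum: per band b, `R_b = S_b exp(-k_b LAI) + C_b (1 - exp(-k_b LAI))`
#' with extinction `k_b` scaled by leaf angle. Strictly monotone in LAI per
#' band and saturating in the NIR; deterministic given the parameters.
#'
#' @param params data frame of canopy parameters (see
#'   [sample_canopy_params()]).
#' @return matrix `[n, 9]` of reflectances in (0, 1), columns labelled by the
#'   coarse sensor's bands.
#' @export
toy_forward <- function(params) {
  params <- as.data.frame(params)
  if (any(params$lai < 0)) stopf("LAI must be >= 0")
  if (any(params$sza >= 90 | params$vza >= 90)) stopf("angles must be < 90 degrees")
  if (any(params$psoil < 0 | params$psoil > 1)) stopf("psoil must lie in [0, 1]")
  S <- toy_soil_spectrum(params)
  L <- toy_leaf_spectrum(params) * toy_geo_factor(params)
  g_ala <- 0.3 + 0.8 * cos(params$ala * pi / 180)        # erect leaves -> less extinction
  K <- outer(g_ala, .toy_k0)
  E <- exp(-K * params$lai)
  R <- S * E + L * (1 - E)
  R <- pmin(pmax(R, 1e-4), 0.999)
  colnames(R) <- names(coarse_sensor()$wavelengths)
  R
}

# All-19-index predictor matrix from a [n, 9] reflectance matrix.
vi_matrix <- function(refl, indices = vi_abbreviations("all")) {
  B <- stats::setNames(lapply(seq_len(ncol(refl)), function(j) refl[, j]),
                       colnames(refl))
  out <- vapply(indices, function(a) vi_eval(a, B), numeric(nrow(refl)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, indices))
  out
}

#' Build the synthetic (VI, LAI) training set
#'
#' Draws canopy parameters, simulates coarse-sensor reflectance with the
#' forward model, computes all 19 vegetation indices and returns the
#' predictor matrix with its LAI targets. Rows with any non-finite index are
#' dropped and counted.
#'
#' @param n number of forward runs (default 50000).
#' @param seed integer seed.
#' @param forward_model function: parameter data frame -> `[n, 9]`
#'   reflectance matrix (default [toy_forward()]).
#' @param config parameter-distribution overrides for
#'   [sample_canopy_params()].
#' @param noise_sigma Gaussian noise (1 sigma, reflectance units) added to
#'   the simulated reflectances before index computation, emulating sensor
#'   and harmonization noise so the regressor learns the noise-blurred
#'   mapping it will face at prediction time (standard regularization in
#'   hybrid inversion). Default 0.01; set 0 for a noise-free set.
#' @return object of class `canopy_training_set` with elements `predictors`
#'   (matrix, 19 columns), `targets` (LAI vector), `params`, `n_dropped`,
#'   `seed`.
#' @export
build_training_set <- function(n = 50000, seed = 1, forward_model = toy_forward,
                               config = rt_param_defaults(), noise_sigma = 0.01) {
  params <- sample_canopy_params(n, seed, config)
  refl <- forward_model(params)
  if (!is.matrix(refl) || nrow(refl) != nrow(params) || ncol(refl) != 9L)
    stopf("forward model must return an [n, 9] reflectance matrix")
  if (noise_sigma > 0) {
    refl <- with_seed(seed + 104729L,
      refl + matrix(stats::rnorm(length(refl), 0, noise_sigma), nrow(refl)))
    refl <- pmin(pmax(refl, 1e-4), 0.999)
  }
  if (any(!is.finite(refl)) || any(refl <= 0) || any(refl >= 1)) {
    bad <- which(!is.finite(refl) | refl <= 0 | refl >= 1, arr.ind = TRUE)
    stopf("forward model returned reflectance outside (0, 1) at sample %d",
          bad[1, 1])
  }
  X <- vi_matrix(refl)
  keep <- stats::complete.cases(X) & apply(is.finite(X), 1L, all)
  structure(list(predictors = X[keep, , drop = FALSE],
                 targets = params$lai[keep],
                 params = params[keep, , drop = FALSE],
                 n_dropped = sum(!keep), seed = seed),
            class = "canopy_training_set")
}

#' @export
print.canopy_training_set <- function(x, ...) {
  cat(sprintf("<canopy_training_set> %d samples x %d indices (%d dropped), LAI %.2f..%.2f\n",
              nrow(x$predictors), ncol(x$predictors), x$n_dropped,
              min(x$targets), max(x$targets)))
  invisible(x)
}

#' Persist / load a training set
#'
#' Tabular CSV (indices + `lai` target) with a JSON sidecar holding the seed
#' and drop count.
#'
#' @param ts a `canopy_training_set`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
write_training_set <- function(ts, path) {
  df <- as.data.frame(ts$predictors)
  df$lai <- ts$targets
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(seed = ts$seed, n_dropped = ts$n_dropped,
                            n = nrow(df)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
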