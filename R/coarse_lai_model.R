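# 30 m LAI from the coarse sensor: three random-forest regressors trained on
# the radiative-transfer training set with different spectral feature sets
# (VNIR+RE, VNIR+SWIR, VNIR+RE+SWIR); combining them regularizes the
# ill-posed inversion. Forests are fitted with ranger; the ensemble surface
# (feature sets, combiner, clipping, serialization) is defined here.

#' Spectral feature sets of the LAI ensemble
#'
#' VNIR block: the 7 visible/NIR indices shared by both sensors; RE block:
#' the 8 red-edge indices; SWIR block: the 4 shortwave-infrared indices.
#'
#' @return named list of index-abbreviation vectors: `VNIR_RE` (15 members),
#'   `VNIR_SWIR` (11), `VNIR_RE_SWIR` (19).
#' @export
feature_sets <- function() {
  vnir <- c("SR", "NDVI", "OSAVI", "GSR", "GNDVI", "MTVI2", "EVI2")
  re   <- c("MCARI", "MTCI", "VREI1", "RENDVI", "RENDVI2", "RSR", "RSR2", "PSRI")
  swir <- c("NDWI", "NDWI2", "MSR", "MSR2")
  list(VNIR_RE = c(vnir, re), VNIR_SWIR = c(vnir, swir),
       VNIR_RE_SWIR = c(vnir, re, swir))
}

#' Default forest hyperparameters
#' @return list: `num_trees`, `min_node_size`, `mtry` (`NULL` = sqrt(p)).
#' @export
forest_defaults <- function() list(num_trees = 200, min_node_size = 5, mtry = NULL)

#' Train one ensemble member
#'
#' @param ts a `canopy_training_set`.
#' @param feature_set name from [feature_sets()] or a character vector of
#'   predictor columns.
#' @param hyperparams see [forest_defaults()].
#' @param seed integer seed for the forest.
#' @return list with the fitted `ranger` forest, `features`, `oob_r2`.
#' @export
train_lai_member <- function(ts, feature_set, hyperparams = forest_defaults(), seed = 1) {
  feats <- if (is.character(feature_set) && length(feature_set) == 1L &&
               feature_set %in% names(feature_sets()))
    feature_sets()[[feature_set]] else feature_set
  miss <- setdiff(feats, colnames(ts$predictors))
  if (length(miss)) stopf("training set lacks predictor column(s): %s",
                          paste(miss, collapse = ", "))
  hp <- utils::modifyList(forest_defaults(), hyperparams)
  df <- as.data.frame(ts$predictors[, feats, drop = FALSE])
  df$.lai <- ts$targets
  fit <- ranger::ranger(
    dependent.variable.name = ".lai", data = df,
    num.trees = hp$num_trees, min.node.size = hp$min_node_size,
    mtry = hp$mtry %||% floor(sqrt(length(feats))),
    seed = as.integer(seed), num.threads = 1, verbose = FALSE)
  list(forest = fit, features = feats, oob_r2 = fit$r.squared)
}

#' Train the three-member LAI ensemble
#'
#' @param ts a `canopy_training_set`.
#' @param hyperparams forest hyperparameters, shared across members.
#' @param seed base seed; members use `seed + 1..3`.
#' @param lai_clip prediction clip range (default `c(0, 8)`).
#' @param combiner `"mean"` (default) or `"median"` across members.
#' @return object of class `lai_ensemble`.
#' @export
train_lai_ensemble <- function(ts, hyperparams = forest_defaults(), seed = 1,
                               lai_clip = c(0, 8), combiner = c("mean", "median")) {
  combiner <- match.arg(combiner)
  sets <- names(feature_sets())
  members <- lapply(seq_along(sets), function(i)
    train_lai_member(ts, sets[i], hyperparams, seed + i))
  names(members) <- sets
  structure(list(members = members, lai_clip = lai_clip, combiner = combiner,
                 n_train = nrow(ts$predictors), seed = seed,
                 hyperparams = utils::modifyList(forest_defaults(), hyperparams)),
            class = "lai_ensemble")
}

#' @export
print.lai_ensemble <- function(x, ...) {
  cat(sprintf("<lai_ensemble> %d members, %d training samples, clip [%g, %g], %s combiner\n",
              length(x$members), x$n_train, x$lai_clip[1], x$lai_clip[2], x$combiner))
  for (nm in names(x$members))
    cat(sprintf("  %-13s %2d indices, OOB R2 = %.4f\n", nm,
                length(x$members[[nm]]$features), x$members[[nm]]$oob_r2))
  invisible(x)
}

# Member predictions for a predictor matrix with named columns.
ensemble_member_matrix <- function(ensemble, X) {
  vapply(ensemble$members, function(m) {
    miss <- setdiff(m$features, colnames(X))
    if (length(miss)) stopf("VI stack lacks band(s): %s", paste(miss, collapse = ", "))
    stats::predict(m$forest, data = as.data.frame(X[, m$features, drop = FALSE]),
                   num.threads = 1)$predictions
  }, numeric(nrow(X)))
}

#' Predict 30 m LAI from a coarse-sensor VI stack
#'
#' Per-pixel LAI is the combination (mean by default) of the three members'
#' predictions, clipped to the ensemble's LAI range; the member spread
#' (max - min) is returned as an uncertainty proxy. Missing pixels propagate.
#'
#' @param object a [train_lai_ensemble()] fit.
#' @param vi_stack [sat_raster] containing all 19 index bands, or a numeric
#'   matrix with index columns.
#' @param ... unused.
#' @return for a raster input, list of two [sat_raster]s (`lai`, `spread`);
#'   for a matrix input, a list of two vectors.
#' @export
predict.lai_ensemble <- function(object, vi_stack, ...) {
  as_matrix <- is.matrix(vi_stack)
  if (!as_matrix) {
    d <- dim(vi_stack$values)
    X <- matrix(vi_stack$values, d[1L] * d[2L], d[3L],
                dimnames = list(NULL, vi_stack$bands))
  } else X <- vi_stack
  ok <- stats::complete.cases(X)
  lai <- spread <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    P <- ensemble_member_matrix(object, X[ok, , drop = FALSE])
    comb <- if (object$combiner == "mean") rowMeans(P)
            else apply(P, 1L, stats::median)
    lai[ok] <- pmin(pmax(comb, object$lai_clip[1]), object$lai_clip[2])
    spread[ok] <- apply(P, 1L, max) - apply(P, 1L, min)
  }
  if (as_matrix) return(list(lai = lai, spread = spread))
  mk <- function(v, kind) sat_raster(array(v, c(d[1L], d[2L], 1L)),
                                     if (kind == "lai") "lai" else "spread",
                                     vi_stack$res, vi_stack$origin, vi_stack$date,
                                     kind = if (kind == "lai") "lai" else "other",
                                     nodata = vi_stack$nodata)
  list(lai = mk(lai, "lai"), spread = mk(spread, "spread"))
}

.lai_ensemble_schema <- 1L

#' Serialize / load a fitted ensemble
#'
#' Versioned binary file embedding the training config and seed; loading
#' refuses files written under an incompatible schema version.
#'
#' @param ensemble a `lai_ensemble`.
#' @param path file path.
#' @export
save_lai_ensemble <- function(ensemble, path) {
  saveRDS(list(schema = .lai_ensemble_schema, ensemble = ensemble), path)
  invisible(path)
}

#' @rdname save_lai_ensemble
#' @export
load_lai_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, .lai_ensemble_schema))
    stopf("ensemble file %s has schema version %s; this build reads version %d",
          path, format(obj$schema), .lai_ensemble_schema)
  obj$ensemble
}
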