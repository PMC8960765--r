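# Per-date 30 m reference LAI. Coarse-sensor LAI scenes are only available
# on acquisition dates; to target an arbitrary day each scene is carried
# across its acquisition gap with a multiplicative LAI-change factor derived
# from a multivariate regression of coarse LAI on the 7 fine-sensor
# vegetation indices (aggregated to 30 m, trained on the day-coincident
# multi-date pool). Candidates from several scenes are then temporally
# weighted, outlier-screened and averaged pixel-wise.

#' Default reference-sampling configuration
#'
#' `tau`: e-folding time (days) of the temporal weight
#' `exp(-|gap| / tau)`; `window`: maximum acquisition gap considered (days);
#' `k_mad`: outlier screen half-width in scaled MADs about the weighted
#' median; `mad_floor`: lower bound (LAI) on the screening MAD so that
#' near-consensus candidate sets do not collapse the band to zero width;
#' `clip_max` / `eps`: bounds on the change factor (factor confined to
#' `[1/clip_max, clip_max]`, denominator floored at `eps` LAI);
#' `min_pool_pixels`: minimum rows to fit the change model.
#'
#' @return named list of settings.
#' @export
reference_defaults <- function() {
  list(tau = 10, window = 24, k_mad = 2, mad_floor = 0.1,
       clip_max = 5, eps = 0.1, min_pool_pixels = 50)
}

#' Fit the LAI-change regression
#'
#' Ordinary least squares of coarse-sensor LAI on the 7 shared vegetation
#' indices plus an intercept, pooled over day-coincident (coarse LAI,
#' 30 m-aggregated fine VI) scene pairs. A rank-deficient design falls back
#' to a ridge fit and is flagged.
#'
#' @param coarse_lai_scenes list of 30 m LAI [sat_raster]s, one per
#'   acquisition date (dates taken from the rasters).
#' @param fine_vi_stacks_30m list of 30 m [sat_raster]s of the 7 shared
#'   indices, same dates and grid.
#' @param config see [reference_defaults()].
#' @param ridge ridge penalty used only on fallback (default 1e-6).
#' @return object of class `change_model`: coefficients (intercept first),
#'   `r2`, `n`, `dates`, `ridged` flag.
#' @export
fit_change_model <- function(coarse_lai_scenes, fine_vi_stacks_30m,
                             config = reference_defaults(), ridge = 1e-6) {
  config <- utils::modifyList(reference_defaults(), config)
  if (length(coarse_lai_scenes) < 2L)
    stopf("need >= 2 coincident scene pairs to fit the change model")
  if (length(coarse_lai_scenes) != length(fine_vi_stacks_30m))
    stopf("scene lists differ in length")
  feats <- vi_abbreviations("both")
  rows_X <- list(); rows_y <- list(); dates <- as.Date(character())
  for (i in seq_along(coarse_lai_scenes)) {
    lai_r <- coarse_lai_scenes[[i]]; vi_r <- fine_vi_stacks_30m[[i]]
    if (is.null(lai_r$date) || is.null(vi_r$date) ||
        !identical(as.Date(lai_r$date), as.Date(vi_r$date)))
      stopf("pair %d is not day-coincident", i)
    if (!identical(dim(lai_r$values)[1:2], dim(vi_r$values)[1:2]))
      stopf("pair %d: grids differ", i)
    d <- dim(vi_r$values)
    X <- matrix(vi_r$values[, , match(feats, vi_r$bands)], d[1] * d[2],
                length(feats), dimnames = list(NULL, feats))
    y <- as.vector(raster_band(lai_r, 1L))
    ok <- stats::complete.cases(X) & is.finite(y)
    rows_X[[i]] <- X[ok, , drop = FALSE]; rows_y[[i]] <- y[ok]
    dates <- c(dates, as.Date(lai_r$date))
  }
  X <- do.call(rbind, rows_X); y <- do.call(c, rows_y)
  if (nrow(X) < config$min_pool_pixels)
    stopf("change-model pool has %d rows; need >= %d", nrow(X), config$min_pool_pixels)
  D <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(D, y)
  ridged <- FALSE
  coefs <- fit$coefficients
  if (anyNA(coefs)) {            # rank-deficient pool: ridge fallback
    ridged <- TRUE
    A <- crossprod(D) + diag(c(0, rep(ridge, ncol(X))))
    coefs <- drop(solve(A, crossprod(D, y)))
    names(coefs) <- colnames(D)
  }
  pred <- drop(D %*% coefs)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(list(coefficients = coefs, r2 = r2, n = length(y),
                 dates = dates, features = feats, ridged = ridged),
            class = "change_model")
}

#' @export
print.change_model <- function(x, ...) {
  cat(sprintf("<change_model> %d pooled pixels over %d dates, R2 = %.4f%s\n",
              x$n, length(x$dates), x$r2, if (x$ridged) " (ridge fallback)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.change_model <- function(object, vi_stack_30m, ...) {
  d <- dim(vi_stack_30m$values)
  X <- matrix(vi_stack_30m$values[, , match(object$features, vi_stack_30m$bands)],
              d[1] * d[2], length(object$features))
  if (anyNA(match(object$features, vi_stack_30m$bands)))
    stopf("VI stack lacks change-model predictor(s)")
  pred <- drop(cbind(1, X) %*% object$coefficients)
  pred <- pmax(pred, 0)
  sat_raster(array(pred, c(d[1], d[2], 1L)), "lai_hat", vi_stack_30m$res,
             vi_stack_30m$origin, vi_stack_30m$date, kind = "lai",
             nodata = vi_stack_30m$nodata)
}

#' Relative LAI-change factor between two dates
#'
#' `factor = Lhat(target) / max(Lhat(source), eps)`, where `Lhat` is the
#' change-model prediction from the fine-sensor VIs at 30 m; the factor is
#' confined to `[1/clip_max, clip_max]`.
#'
#' @param change_model a [fit_change_model()] fit.
#' @param fine_vi_target_date,fine_vi_source_date 30 m VI stacks.
#' @param config see [reference_defaults()].
#' @return single-band [sat_raster] of change factors.
#' @export
relative_change <- function(change_model, fine_vi_target_date, fine_vi_source_date,
                            config = reference_defaults()) {
  config <- utils::modifyList(reference_defaults(), config)
  if (!identical(dim(fine_vi_target_date$values)[1:2],
                 dim(fine_vi_source_date$values)[1:2]) ||
      abs(fine_vi_target_date$res - fine_vi_source_date$res) > 1e-9)
    stopf("VI stacks are on different grids")
  lt <- as.vector(raster_band(stats::predict(change_model, fine_vi_target_date), 1L))
  ls <- as.vector(raster_band(stats::predict(change_model, fine_vi_source_date), 1L))
  fac <- lt / pmax(ls, config$eps)
  fac <- pmin(pmax(fac, 1 / config$clip_max), config$clip_max)
  d <- dim(fine_vi_target_date$values)
  sat_raster(array(fac, c(d[1], d[2], 1L)), "change_factor",
             fine_vi_target_date$res, fine_vi_target_date$origin,
             fine_vi_target_date$date, kind = "other",
             nodata = fine_vi_target_date$nodata)
}

weighted_median <- function(x, w) {
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Assemble the per-date 30 m reference-LAI tile
#'
#' For each coarse-sensor scene within the temporal window, the scene LAI is
#' carried to the target date with its [relative_change()] factor; the
#' candidates are weighted by `exp(-|gap|/tau)`, screened against the
#' weighted median +/- `k_mad` scaled MADs (the nearest-date candidate is
#' always retained), and averaged.
#'
#' @param target_date target `Date`.
#' @param coarse_lai_scenes list of dated 30 m LAI [sat_raster]s.
#' @param fine_vi_series function(date) -> 30 m VI stack, or a list of dated
#'   VI stacks covering the target and all scene dates.
#' @param change_model a [fit_change_model()] fit.
#' @param config see [reference_defaults()].
#' @return object of class `reference_tile`: rasters `lai`, `weight`,
#'   `n_used`, `n_screened`, plus `source_dates`.
#' @export
build_reference_tile <- function(target_date, coarse_lai_scenes, fine_vi_series,
                                 change_model, config = reference_defaults()) {
  config <- utils::modifyList(reference_defaults(), config)
  target_date <- as.Date(target_date)
  get_vi <- if (is.function(fine_vi_series)) fine_vi_series else {
    dates <- as.Date(vapply(fine_vi_series, function(r) format(as.Date(r$date)), ""))
    function(d) {
      i <- match(as.Date(d), dates)
      if (is.na(i)) stopf("no fine VI stack for %s", format(as.Date(d)))
      fine_vi_series[[i]]
    }
  }
  scene_dates <- as.Date(vapply(coarse_lai_scenes, function(r) format(as.Date(r$date)), ""))
  gaps <- as.numeric(scene_dates - target_date)
  sel <- which(abs(gaps) <= config$window)
  if (!length(sel)) stopf("no coarse scene within +/-%d days of %s",
                          config$window, format(target_date))
  vi_target <- get_vi(target_date)
  cand <- list(); wts <- numeric(0)
  for (i in sel) {
    scene <- coarse_lai_scenes[[i]]
    if (abs(gaps[i]) < 0.5) {            # same-day scene: no correction needed
      cand[[length(cand) + 1L]] <- as.vector(raster_band(scene, 1L))
    } else {
      fac <- relative_change(change_model, vi_target, get_vi(scene_dates[i]), config)
      cand[[length(cand) + 1L]] <-
        as.vector(raster_band(scene, 1L)) * as.vector(raster_band(fac, 1L))
    }
    wts <- c(wts, exp(-abs(gaps[i]) / config$tau))
  }
  C <- do.call(cbind, cand)              # [pixel, candidate]
  nearest <- which.min(abs(gaps[sel]))
  npix <- nrow(C)
  lai <- wsum <- rep(NA_real_, npix)
  n_used <- n_screened <- rep(0, npix)
  for (p in seq_len(npix)) {
    x <- C[p, ]; ok <- is.finite(x)
    if (!any(ok)) next
    xs <- x[ok]; ws <- wts[ok]
    m <- weighted_median(xs, ws)
    madv <- stats::median(abs(xs - m)) * 1.4826
    keep <- abs(xs - m) <= config$k_mad * max(madv, config$mad_floor)
    keep_idx <- which(ok)
    if (nearest %in% keep_idx) keep[match(nearest, keep_idx)] <- TRUE
    if (!any(keep)) keep[which.max(ws)] <- TRUE
    lai[p] <- sum(xs[keep] * ws[keep]) / sum(ws[keep])
    wsum[p] <- sum(ws[keep])
    n_used[p] <- sum(keep)
    n_screened[p] <- sum(!keep)
  }
  lai <- pmax(lai, 0)
  g <- coarse_lai_scenes[[sel[1L]]]
  d <- dim(g$values)
  mk <- function(v, nm, kind = "other")
    sat_raster(array(v, c(d[1], d[2], 1L)), nm, g$res, g$origin, target_date,
               kind = kind, nodata = g$nodata)
  structure(list(lai = mk(lai, "lai", "lai"), weight = mk(wsum, "weight"),
                 n_used = mk(n_used, "n_used"),
                 n_screened = mk(n_screened, "n_screened"),
                 source_dates = scene_dates[sel], target_date = target_date),
            class = "reference_tile")
}

#' @export
print.reference_tile <- function(x, ...) {
  v <- raster_band(x$lai, 1L)
  cat(sprintf("<reference_tile> %s from %d scene(s) [%s]\n",
              format(x$target_date), length(x$source_dates),
              paste(format(x$source_dates), collapse = ", ")))
  cat(sprintf("  LAI %.2f..%.2f, screened pixels: %d\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              sum(raster_band(x$n_screened, 1L) > 0)))
  invisible(x)
}

#' Write a reference tile as a 4-band GeoTIFF
#' @param tile a `reference_tile`.
#' @param path output path.
#' @export
write_reference_tile <- function(tile, path) {
  d <- dim(tile$lai$values)
  v <- array(c(tile$lai$values, tile$weight$values, tile$n_used$values,
               tile$n_screened$values), c(d[1], d[2], 4L))
  r <- sat_raster(v, c("lai", "weight", "n_used", "n_screened"),
                  tile$lai$res, tile$lai$origin, tile$target_date,
                  kind = "other", nodata = tile$lai$nodata)
  write_raster(r, path)
}
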