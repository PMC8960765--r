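# Validation protocol and phenology analytics: pairing of in-situ plot LAI
# with window-extracted map LAI, RMSE / relative RMSE / R-squared, per-stage
# box statistics, and growth-curve feature detection (peak, plateau,
# senescence onset, green-zero date).

#' Pair field observations with retrieved LAI maps
#'
#' One row per (plot, date): the in-situ value next to the mean of the
#' `window` x `window` fine-pixel block around the plot center (7 x 7 pixels
#' = 21 x 21 m at 3 m) extracted from the matching date's raster.
#'
#' @param field_table observation data frame (see
#'   [read_field_observations()]).
#' @param lai_series named list of LAI [sat_raster]s keyed by `yyyy-mm-dd`
#'   date strings (or a `lai_daily_series` from [run_daily_pipeline()]).
#' @param window odd window size in pixels (default 7).
#' @return data frame with the observation columns plus `lai_retrieved`.
#' @export
pair_observations <- function(field_table, lai_series, window = 7L) {
  if (inherits(lai_series, "lai_daily_series"))
    lai_series <- stats::setNames(lapply(lai_series$days, `[[`, "lai"),
                                  vapply(lai_series$days, function(d) format(d$date), ""))
  out <- field_table
  out$lai_retrieved <- NA_real_
  for (i in seq_len(nrow(out))) {
    key <- format(as.Date(out$date[i]))
    r <- lai_series[[key]]
    if (is.null(r)) stopf("no retrieved raster for date %s", key)
    out$lai_retrieved[i] <- extract_window_mean(r, c(out$x[i], out$y[i]), window)
  }
  out
}

#' Agreement metrics between in-situ and retrieved LAI
#'
#' `rmse = sqrt(mean((retrieved - insitu)^2))`; `rrmse_percent = 100 rmse /
#' mean(insitu)`; `r2` from the ordinary least-squares regression of
#' retrieved on in-situ (`method = "identity"` instead scores residuals
#' about the 1:1 line).
#'
#' @param paired data frame with columns `lai` (in-situ) and
#'   `lai_retrieved`, as from [pair_observations()].
#' @param method R-squared convention: `"ols"` (default) or `"identity"`.
#' @return list: `rmse`, `rrmse_percent`, `r2`, `n`, `slope`, `intercept`.
#' @export
lai_metrics <- function(paired, method = c("ols", "identity")) {
  method <- match.arg(method)
  ok <- is.finite(paired$lai) & is.finite(paired$lai_retrieved)
  x <- paired$lai[ok]; y <- paired$lai_retrieved[ok]
  if (length(x) < 2L) stopf("need at least 2 paired observations")
  rmse <- sqrt(mean((y - x)^2))
  mx <- mean(x)
  rrmse <- if (mx == 0) { warnf("zero in-situ mean: rRMSE undefined"); NA_real_ }
           else 100 * rmse / mx
  fit <- stats::lm(y ~ x)
  mss <- sum((stats::fitted(fit) - mean(y))^2)
  rss <- sum(stats::residuals(fit)^2)
  # a retrieval with no variance explains nothing regardless of convention
  r2 <- if (stats::var(y) == 0) 0
        else if (method == "ols") mss / (mss + rss)
        else 1 - sum((y - x)^2) / sum((y - mean(y))^2)
  list(rmse = rmse, rrmse_percent = rrmse, r2 = r2, n = length(x),
       slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}

#' Within-field LAI box statistics for one stage
#'
#' Type-7 (linear interpolation) quartiles of the masked pixel values;
#' whisker bounds at Q1 - 1.5 IQR and Q3 + 1.5 IQR; values beyond the
#' whiskers are counted as outliers (excluded from box display, not from
#' quartiles).
#'
#' @param lai_raster LAI [sat_raster].
#' @param field_mask logical matrix selecting the field's pixels.
#' @param stage_label stage code attached to the row.
#' @return one-row data frame: `stage`, `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `mean`, `n`, `n_outliers`.
#' @export
stage_stats <- function(lai_raster, field_mask, stage_label = NA_character_) {
  v <- raster_band(lai_raster, 1L)[field_mask]
  v <- v[is.finite(v)]
  if (!length(v)) stopf("empty field mask")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  wl <- q[1] - 1.5 * iqr; wh <- q[3] + 1.5 * iqr
  data.frame(stage = stage_label, q1 = q[1], median = q[2], q3 = q[3],
             whisker_low = wl, whisker_high = wh, mean = mean(v),
             n = length(v), n_outliers = sum(v < wl | v > wh))
}

#' Detect phenology features in a daily field-mean LAI series
#'
#' The series is smoothed with a 7-day centered moving mean; the peak is its
#' maximum; the plateau is the maximal interval around the peak staying
#' within `delta` of the peak for at least `min_plateau` days; senescence
#' onset is the first post-plateau date opening `k_decline` consecutive days
#' of negative slope; the green-zero date is the first date the raw series
#' drops below `zero_level`.
#'
#' @param series data frame with `date` (daily, >= 30 days) and `lai`.
#' @param delta plateau tolerance as a fraction of peak (default 0.05).
#' @param min_plateau minimum plateau length in days (default 7).
#' @param k_decline consecutive declining days for senescence (default 5).
#' @param zero_level green-zero threshold (default 0.2 LAI).
#' @return list: `peak_date`, `peak_lai`, `plateau_start`, `plateau_end`,
#'   `senescence_onset`, `green_zero_date` (`NA` where absent) and `flags`.
#' @export
detect_phenology_features <- function(series, delta = 0.05, min_plateau = 7L,
                                      k_decline = 5L, zero_level = 0.2) {
  if (nrow(series) < 30L) stopf("need a daily series of at least 30 days")
  o <- order(series$date)
  dates <- as.Date(series$date)[o]; lai <- series$lai[o]
  if (any(diff(as.numeric(dates)) != 1)) stopf("series must be daily and gap-free")
  sm <- stats::filter(lai, rep(1 / 7, 7), sides = 2)
  sm[is.na(sm)] <- lai[is.na(sm)]      # endpoints: fall back to raw values
  flags <- character(0)
  res <- list(peak_date = as.Date(NA), peak_lai = NA_real_,
              plateau_start = as.Date(NA), plateau_end = as.Date(NA),
              senescence_onset = as.Date(NA), green_zero_date = as.Date(NA))
  if (max(sm) <= zero_level) {
    flags <- c(flags, "no_peak")
    below <- which(lai < zero_level)
    if (length(below)) res$green_zero_date <- dates[below[1L]]
    res$flags <- flags
    return(res)
  }
  ipk <- which.max(sm)
  res$peak_date <- dates[ipk]; res$peak_lai <- sm[ipk]
  hi <- sm >= (1 - delta) * sm[ipk]
  i0 <- ipk; while (i0 > 1L && hi[i0 - 1L]) i0 <- i0 - 1L
  i1 <- ipk; while (i1 < length(sm) && hi[i1 + 1L]) i1 <- i1 + 1L
  if (i1 - i0 + 1L >= min_plateau) {
    res$plateau_start <- dates[i0]; res$plateau_end <- dates[i1]
  } else flags <- c(flags, "no_plateau")
  slope <- diff(sm)
  onset <- NA_integer_
  i_from <- max(i1, ipk); i_to <- length(slope) - k_decline + 1L
  if (i_from <= i_to) for (i in i_from:i_to) {
    if (all(slope[i:(i + k_decline - 1L)] < 0)) { onset <- i; break }
  }
  if (!is.na(onset)) res$senescence_onset <- dates[onset] else
    flags <- c(flags, "no_senescence")
  after <- which(lai < zero_level & seq_along(lai) > ipk)
  if (length(after)) res$green_zero_date <- dates[after[1L]] else
    flags <- c(flags, "no_green_zero")
  res$flags <- flags
  res
}

#' Evaluation plots
#'
#' Scatter of retrieved vs in-situ LAI with the 1:1 line and the OLS fit,
#' and per-stage box-whisker panels, drawn with base graphics.
#'
#' @param paired paired-observation data frame.
#' @param ... passed to `plot()`.
#' @export
plot_lai_scatter <- function(paired, ...) {
  m <- lai_metrics(paired)
  lim <- range(c(paired$lai, paired$lai_retrieved), na.rm = TRUE)
  graphics::plot(paired$lai, paired$lai_retrieved, xlim = lim, ylim = lim,
                 xlab = "in-situ LAI (m2/m2)", ylab = "retrieved LAI (m2/m2)",
                 pch = 19, col = grDevices::adjustcolor("forestgreen", 0.6), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(m$intercept, m$slope, col = "firebrick")
  graphics::legend("topleft", bty = "n", legend = c(
    sprintf("R2 = %.3f", m$r2), sprintf("RMSE = %.3f", m$rmse),
    sprintf("rRMSE = %.2f%%", m$rrmse_percent), sprintf("n = %d", m$n)))
  invisible(m)
}

#' @rdname plot_lai_scatter
#' @param stats data frame of [stage_stats()] rows (one per stage, in order).
#' @export
plot_stage_boxes <- function(stats, ...) {
  n <- nrow(stats)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = range(c(stats$whisker_low, stats$whisker_high)),
                 xaxt = "n", xlab = "stage", ylab = "LAI (m2/m2)", ...)
  graphics::axis(1, at = seq_len(n), labels = stats$stage)
  for (i in seq_len(n)) {
    graphics::rect(i - 0.3, stats$q1[i], i + 0.3, stats$q3[i], col = "palegreen3")
    graphics::segments(i - 0.3, stats$median[i], i + 0.3, stats$median[i], lwd = 2)
    graphics::segments(i, stats$whisker_low[i], i, stats$q1[i], lty = 3)
    graphics::segments(i, stats$q3[i], i, stats$whisker_high[i], lty = 3)
  }
  invisible(stats)
}
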