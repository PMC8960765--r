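# End-to-end daily production: coarse scenes -> 30 m LAI via the RF
# ensemble; day-coincident (coarse LAI, aggregated fine VI) pairs -> change
# model; per day: reference tile -> rule model trained at 30 m -> 3 m LAI.

#' Run the daily 3 m LAI pipeline over a synthetic campaign
#'
#' For every requested day: compute the fine-sensor VI stack at 3 m and its
#' 30 m block-mean, assemble the change-corrected, weighted,
#' outlier-screened 30 m reference tile, train the date-specific rule model
#' on sampled 30 m pixels, and predict LAI at 3 m. Days that fail at any
#' stage are recorded with their reason and the run continues.
#'
#' @param truth a `campaign_truth` from [generate_truth()] (provides the
#'   scenes and the acquisition schedule).
#' @param ensemble a fitted [train_lai_ensemble()] model for the coarse
#'   sensor.
#' @param dates `Date` vector of target days (default: every day of the
#'   season).
#' @param config reference/downscaler settings; see [reference_defaults()]
#'   and [downscaler_defaults()].
#' @param sample_fraction fraction of valid 30 m pixels used for rule-model
#'   training (default 1: the full 30 m budget, matching one training sample
#'   per whole 30 m cell of the tile).
#' @param out_dir optional directory; per-day LAI GeoTIFFs and a JSON
#'   diagnostics file are written there.
#' @param seed integer seed for subsampling.
#' @return object of class `lai_daily_series`: per-day entries (`date`,
#'   `lai` raster, `r2`, `n_rules`, `n_samples`), the change model and the
#'   coarse-LAI scene list.
#' @export
run_daily_pipeline <- function(truth, ensemble, dates = NULL,
                               config = list(), sample_fraction = 1,
                               out_dir = NULL, seed = 1) {
  ref_cfg <- utils::modifyList(reference_defaults(), config$reference %||% list())
  ds_cfg <- utils::modifyList(downscaler_defaults(), config$downscaler %||% list())
  dates <- as.Date(dates %||% truth$dates)
  if (!length(dates)) stopf("empty date range")
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # Coarse-sensor branch: 19-index stacks -> ensemble LAI per acquisition.
  cprofile <- coarse_sensor(truth$config$scene$res * 10)
  fprofile <- fine_sensor(truth$config$scene$res)
  both_vi <- vi_abbreviations("both")
  coarse_lai <- list(); fine_vi30_pool <- list()
  for (i in seq_along(truth$coarse_dates)) {
    d <- truth$coarse_dates[i]
    vi19 <- compute_vi_stack(coarse_scene(truth, d), cprofile)
    coarse_lai[[i]] <- stats::predict(ensemble, vi19)$lai
    # day-coincident fine predictors on the same 30 m grid
    fine_vi <- compute_vi_stack(fine_scene(truth, d), fprofile, both_vi)
    fine_vi30_pool[[i]] <- aggregate_block_mean(fine_vi, 10L)
  }
  change_model <- fit_change_model(coarse_lai, fine_vi30_pool, ref_cfg)

  vi30_cache <- stats::setNames(fine_vi30_pool,
                                format(truth$coarse_dates))
  get_vi30 <- function(d, stack3m = NULL) {
    key <- format(as.Date(d))
    if (!is.null(vi30_cache[[key]])) return(vi30_cache[[key]])
    stack <- stack3m %||% compute_vi_stack(fine_scene(truth, d), fprofile, both_vi)
    aggregate_block_mean(stack, 10L)
  }

  days <- list(); failures <- list()
  for (d in as.list(dates)) {
    res <- tryCatch({
      vi3m <- compute_vi_stack(fine_scene(truth, d), fprofile, both_vi)
      ref <- build_reference_tile(d, coarse_lai, get_vi30, change_model, ref_cfg)
      design <- sample_training_pixels(ref, get_vi30(d, vi3m), sample_fraction,
                                       seed = day_seed(seed, d))
      model <- train_rule_model(design, ds_cfg, seed = day_seed(seed, d), date = d)
      lai3m <- stats::predict(model, vi3m)
      if (!is.null(out_dir))
        write_raster(lai3m, file.path(out_dir, sprintf("lai_%s.tif", format(d))))
      list(date = d, lai = lai3m, r2 = model$r2, n_rules = length(model$rules),
           n_samples = model$n_train, ref_sources = length(ref$source_dates))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[format(d)]] <- conditionMessage(res)
      message(sprintf("day %s failed: %s", format(d), conditionMessage(res)))
    } else days[[length(days) + 1L]] <- res
  }
  out <- structure(list(days = days, failures = failures,
                        change_model = change_model, coarse_lai = coarse_lai,
                        dates = dates, seed = seed),
                   class = "lai_daily_series")
  if (!is.null(out_dir)) {
    diag <- lapply(days, function(x) list(date = format(x$date), r2 = x$r2,
                                          n_rules = x$n_rules,
                                          n_samples = x$n_samples))
    jsonlite::write_json(list(days = diag, failures = failures,
                              change_model_r2 = change_model$r2),
                         file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.lai_daily_series <- function(x, ...) {
  r2 <- vapply(x$days, `[[`, 0, "r2")
  cat(sprintf("<lai_daily_series> %d day(s) produced, %d failed\n",
              length(x$days), length(x$failures)))
  if (length(r2))
    cat(sprintf("  training R2: min %.4f / median %.4f\n", min(r2), stats::median(r2)))
  cat(sprintf("  change model: R2 = %.4f over %d pooled pixels\n",
              x$change_model$r2, x$change_model$n))
  invisible(x)
}

#' Daily field-mean LAI series from a produced campaign
#'
#' @param series a `lai_daily_series`.
#' @param truth the `campaign_truth` (field footprints).
#' @param field_id field name.
#' @return data frame with `date` and `lai` (field-mean retrieved LAI).
#' @export
field_mean_series <- function(series, truth, field_id) {
  fi <- match(field_id, vapply(truth$config$fields, `[[`, "", "field_id"))
  if (is.na(fi)) stopf("unknown field '%s'", field_id)
  mask <- !is.na(truth$field_map) & truth$field_map == fi
  data.frame(
    date = as.Date(vapply(series$days, function(d) format(d$date), "")),
    lai = vapply(series$days, function(d) mean(raster_band(d$lai, 1L)[mask],
                                               na.rm = TRUE), 0))
}
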