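test_that("pairing produces one row per plot and date and errors on gaps", {
  tr <- fx_campaign()
  obs <- fx_obs()
  dts <- sort(unique(obs$date))
  series <- setNames(lapply(dts, function(d) truth_lai(tr, d)), format(dts))
  paired <- pair_observations(obs, series)
  expect_equal(nrow(paired), 222L)
  expect_true(all(is.finite(paired$lai_retrieved)))
  # identity: noiseless observations against the truth rasters they came from
  obs0 <- simulate_imz_sampling(tr, imz_sampling_dates(campaign_config()), noise_cv = 0)
  p0 <- pair_observations(obs0, series)
  m0 <- lai_metrics(p0)
  expect_gt(m0$r2, 0.999)
  expect_lt(m0$rmse, 0.05)   # 7x7 window vs 20x20 m footprint: near-identical
  # a missing date is reported by name
  expect_error(pair_observations(obs, series[-3]),
               format(dts[3]))
})

test_that("agreement metrics match hand-computed cases", {
  hand <- data.frame(lai = c(2, 4), lai_retrieved = c(3, 3))
  m <- lai_metrics(hand)
  expect_equal(m$rmse, 1.0)
  expect_equal(m$rrmse_percent, 100 / 3)
  expect_equal(m$r2, 0.0)
  expect_equal(m$n, 2L)
  ident <- data.frame(lai = c(1, 2, 3.5), lai_retrieved = c(1, 2, 3.5))
  mi <- lai_metrics(ident)
  expect_equal(mi$rmse, 0)
  expect_equal(mi$r2, 1)
  expect_equal(mi$slope, 1)
  expect_equal(mi$intercept, 0)
  expect_error(lai_metrics(data.frame(lai = 2, lai_retrieved = 2)), "at least 2")
  expect_warning(mz <- lai_metrics(data.frame(lai = c(0, 0), lai_retrieved = c(1, 2))),
                 "rRMSE undefined")
  expect_true(is.na(mz$rrmse_percent))
  # identity-residual convention penalizes bias that OLS absorbs
  biased <- data.frame(lai = 1:10, lai_retrieved = 1:10 + 2)
  expect_equal(lai_metrics(biased, method = "ols")$r2, 1)
  expect_lt(lai_metrics(biased, method = "identity")$r2, 1)
})

test_that("stage box statistics follow the type-7 quantile convention", {
  const <- mk_raster(matrix(4, 10, 10))
  s <- stage_stats(const, matrix(TRUE, 10, 10), "VT")
  expect_equal(c(s$q1, s$median, s$q3), c(4, 4, 4))
  expect_equal(s$whisker_low, 4); expect_equal(s$whisker_high, 4)
  r100 <- mk_raster(matrix(1:100, 10, 10))
  s2 <- stage_stats(r100, matrix(TRUE, 10, 10), "R1")
  expect_equal(s2$q1, 25.75)
  expect_equal(s2$median, 50.5)
  expect_equal(s2$q3, 75.25)
  expect_equal(s2$whisker_low, 25.75 - 1.5 * (75.25 - 25.75))
  expect_true(s2$q1 <= s2$median && s2$median <= s2$q3)
  expect_error(stage_stats(const, matrix(FALSE, 10, 10)), "empty")
})

test_that("stage medians follow the seasonal ordering on simulated truth", {
  tr <- fx_campaign()
  cp <- tr$curves[[1]]
  mask <- !is.na(tr$field_map) & tr$field_map == 1
  med_at <- function(stage) {
    # first season day labelled with this stage
    days <- seq(tr$config$scene$season_start, tr$config$scene$season_end, by = "day")
    lab <- vapply(days, function(d) laifusion:::stage_from_curve(cp, d) %||% "", "")
    d <- days[match(stage, lab)]
    stage_stats(truth_lai(tr, d), mask, stage)$median
  }
  m_v2 <- med_at("V2"); m_v6 <- med_at("V6"); m_vt <- med_at("VT")
  m_r4 <- med_at("R4"); m_r6 <- med_at("R6")
  expect_gte(m_vt, m_v6)
  expect_gte(m_v6, m_v2)
  expect_lt(m_r6, m_r4)
})

test_that("phenology features are recovered from synthetic growth curves", {
  t0 <- as.Date("2019-04-15")
  days <- t0 + 0:199
  cp <- list(lai_max = 5.4, t1 = as.numeric(t0) + 55, t2 = as.numeric(t0) + 145,
             k1 = 0.15, k2 = 0.10, planting = as.numeric(t0) + 5)
  lai <- lai_truth_curve(cp, days)
  truth_peak <- days[which.max(lai)]
  ph <- detect_phenology_features(data.frame(date = days, lai = lai))
  expect_lte(abs(as.numeric(ph$peak_date - truth_peak)), 2)
  expect_true(!is.na(ph$plateau_start) && !is.na(ph$plateau_end))
  expect_true(ph$plateau_start <= ph$peak_date && ph$peak_date <= ph$plateau_end)
  expect_gte(as.numeric(ph$plateau_end - ph$plateau_start), 7)
  expect_true(ph$senescence_onset >= ph$plateau_end)
  expect_true(ph$green_zero_date > ph$senescence_onset)
  # monotone series: no senescence, flagged
  mono <- data.frame(date = days[1:60], lai = seq(0.1, 4, length.out = 60))
  phm <- detect_phenology_features(mono)
  expect_true(is.na(phm$senescence_onset))
  expect_true("no_senescence" %in% phm$flags)
  # all-zero series: no peak, green-zero at the first date
  phz <- detect_phenology_features(data.frame(date = days[1:40], lai = rep(0, 40)))
  expect_true("no_peak" %in% phz$flags)
  expect_equal(phz$green_zero_date, days[1])
  expect_error(detect_phenology_features(data.frame(date = days[1:10], lai = 1:10)),
               "30 days")
})

test_that("evaluation plots render without error", {
  paired <- data.frame(lai = runif(50, 0, 6))
  paired$lai_retrieved <- paired$lai + rnorm(50, 0, 0.3)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, 400, 400)
  m <- plot_lai_scatter(paired)
  st <- rbind(stage_stats(mk_raster(matrix(runif(100, 1, 2), 10, 10)), matrix(TRUE, 10, 10), "V6"),
              stage_stats(mk_raster(matrix(runif(100, 3, 5), 10, 10)), matrix(TRUE, 10, 10), "VT"))
  plot_stage_boxes(st)
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
  expect_equal(m$n, 50L)
})
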