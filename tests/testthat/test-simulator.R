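base_curve <- list(lai_max = 5, t1 = 50, t2 = 140, k1 = 0.15, k2 = 0.10, planting = 0)

test_that("the growth curve honors its limit and shape contracts", {
  expect_lt(lai_truth_curve(base_curve, 0), 0.01)
  expect_equal(lai_truth_curve(base_curve, 0), 0)   # re-zeroed at planting
  # symmetric rates: argmax at the midpoint of the two inflections
  sym <- list(lai_max = 5, t1 = 50, t2 = 150, k1 = 0.12, k2 = 0.12, planting = 0)
  tt <- seq(0, 250, by = 1)
  expect_lte(abs(tt[which.max(lai_truth_curve(sym, tt))] - 100), 1)
  # single interior maximum, non-negative, returns to ~0
  v <- lai_truth_curve(base_curve, tt)
  expect_true(all(v >= 0))
  pk <- which.max(v)
  expect_true(all(diff(v[seq_len(pk)]) >= 0))
  expect_true(all(diff(v[pk:length(v)]) <= 0))
  expect_lt(v[length(v)], 0.01)
  expect_equal(lai_truth_curve(utils::modifyList(base_curve, list(lai_max = 0)), tt),
               rep(0, length(tt)))
  expect_error(lai_truth_curve(list(lai_max = 5, t1 = 100, t2 = 50, k1 = .1, k2 = .1), 10),
               "t2 must exceed t1")
})

test_that("truth generation is seeded, structured and respects field contrasts", {
  cfg <- fx_small_config()
  tr <- fx_small_campaign()
  expect_identical(tr$lmax$values, generate_truth(cfg, seed = 11)$lmax$values)
  expect_false(identical(tr$lmax$values, generate_truth(cfg, seed = 12)$lmax$values))
  expect_equal(nrow(tr$imz_centers), 18L)
  expect_equal(as.integer(table(tr$imz_centers$field_id)), rep(6L, 3))
  # irrigated fields peak above the rain-fed field
  peak <- truth_lai(tr, as.Date("2019-07-14"))
  fm <- function(fi) mean(raster_band(peak, 1)[tr$field_map == fi], na.rm = TRUE)
  expect_gt(fm(1), fm(3))
  expect_gt(fm(2), fm(3))
  # background is bare soil
  expect_true(all(raster_band(peak, 1)[is.na(tr$field_map)] == 0))
  # zero heterogeneity collapses to a constant peak surface per field
  cfg0 <- cfg
  cfg0$fields <- lapply(cfg0$fields, function(f) {
    f$het_amplitude <- 0; f$n_patches <- 0L; f
  })
  tr0 <- generate_truth(cfg0, seed = 1)
  lm1 <- raster_band(tr0$lmax, 1)[which(tr0$field_map == 1)]
  expect_equal(diff(range(lm1)), 0)
  # overlapping fields are rejected
  cfg_bad <- cfg
  cfg_bad$fields[[2]]$rows <- cfg_bad$fields[[1]]$rows
  cfg_bad$fields[[2]]$cols <- cfg_bad$fields[[1]]$cols
  expect_error(generate_truth(cfg_bad, seed = 1), "overlap")
})

test_that("scene rendering honors noise limits and grid nesting", {
  tr <- fx_small_campaign()
  d <- as.Date("2019-07-01")
  lai3 <- truth_lai(tr, d)
  # noiseless zero-LAI scene is exactly the soil spectrum
  zero <- sat_raster(array(0, dim(lai3$values)), "lai", lai3$res, lai3$origin,
                     d, kind = "lai")
  sc0 <- render_scene(zero, coarse_sensor(3), tr, noise = list(sigma = 0, fine_bias = 0))
  soil <- toy_soil_spectrum(laifusion:::scene_canopy_params(tr, d, 0))
  for (b in seq_len(9))
    expect_equal(as.vector(sc0$values[, , b]), rep(unname(soil[1, b]), 200 * 200),
                 tolerance = 1e-12)
  # a constant-LAI scene renders identically at 3 m aggregated and at 30 m
  const <- sat_raster(array(2.5, dim(lai3$values)), "lai", 3, lai3$origin, d, kind = "lai")
  fine <- render_scene(const, fine_sensor(3), tr, noise = list(sigma = 0, fine_bias = 0))
  const30 <- aggregate_block_mean(const, 10L)
  coarse <- render_scene(const30, coarse_sensor(30), tr, noise = list(sigma = 0, fine_bias = 0))
  for (b in fine_sensor()$bands)
    expect_equal(as.vector(raster_band(coarse, b)),
                 as.vector(raster_band(aggregate_block_mean(fine, 10L), b)),
                 tolerance = 1e-12, label = b)
  # Monte-Carlo check of the configured noise level
  noisy <- render_scene(const, fine_sensor(3), tr, noise = list(sigma = 0.01, fine_bias = 0))
  for (b in fine_sensor()$bands) {
    sdv <- sd(raster_band(noisy, b)[1:100, 1:100] - raster_band(fine, b)[1:100, 1:100])
    expect_gt(sdv, 0.008); expect_lt(sdv, 0.012)
  }
  # determinism per (seed, date)
  again <- render_scene(const, fine_sensor(3), tr, noise = list(sigma = 0.01, fine_bias = 0))
  expect_identical(noisy$values, again$values)
})

test_that("the coarse schedule is irregular and the fine stream daily", {
  tr <- fx_small_campaign()
  cfg <- tr$config
  all_days <- seq(cfg$scene$season_start, cfg$scene$season_end, by = "day")
  sched <- all_days[seq(1, length(all_days), by = cfg$coarse$revisit)]
  expect_true(all(tr$coarse_dates %in% sched))
  expect_lt(length(tr$coarse_dates), length(sched))   # dropouts occurred
  expect_gt(length(tr$coarse_dates), 0.4 * length(sched))
  # fine scenes exist for any day in season (spot check)
  for (d in as.list(all_days[c(1, 100, length(all_days))]))
    expect_s3_class(fine_scene(tr, d), "sat_raster")
  expect_error(coarse_scene(tr, as.Date("2019-04-16") + 1000), "no coarse acquisition")
})

test_that("IMZ sampling reproduces the observation design and its noise model", {
  tr <- fx_campaign()
  dates <- imz_sampling_dates(campaign_config())
  obs <- simulate_imz_sampling(tr, dates, seed = 5)
  expect_equal(nrow(obs), 222L)
  expect_equal(nrow(obs), 6L * (13L + 13L + 11L))
  expect_true(all(obs$lai >= 0))
  expect_true(all(is.na(obs$stage) | obs$stage %in%
                    c("V2", "V6", "V11", "VT", paste0("R", 1:6))))
  # noiseless sampling equals the footprint truth mean exactly
  obs0 <- simulate_imz_sampling(tr, list(Ne1 = as.Date("2019-07-14")), noise_cv = 0)
  lr <- truth_lai(tr, as.Date("2019-07-14"))
  mu <- laifusion:::imz_truth_mean(tr, lr, obs0$x[1], obs0$y[1], 20)
  expect_equal(obs0$lai[1], mu)
  # sampling before planting observes zero LAI
  pre <- simulate_imz_sampling(tr, list(Ne1 = as.Date("2019-04-16")), noise_cv = 0)
  expect_true(all(pre$lai == 0))
  # lognormal noise is unbiased in the mean and seeded
  o1 <- simulate_imz_sampling(tr, dates, seed = 9)
  expect_identical(o1$lai, simulate_imz_sampling(tr, dates, seed = 9)$lai)
  expect_false(identical(o1$lai, obs$lai))
})
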