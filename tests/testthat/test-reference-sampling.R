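# Helper: a 30 m VI stack of the 7 shared indices with random but smooth
# fields, plus a coarse LAI raster linked to it by a known relation.
vi_stack_7 <- function(n = 20, seed = 1, date = NULL, jitter = 0) {
  set.seed(seed)
  labs <- vi_abbreviations("both")
  mats <- setNames(lapply(labs, function(x) matrix(runif(n * n, 0.05, 0.9), n, n)), labs)
  if (jitter > 0) mats <- lapply(mats, function(m) m + rnorm(length(m), 0, jitter))
  mk_stack(mats, res = 30, date = date)
}

test_that("the change model recovers an exact linear pool", {
  dates <- as.Date("2019-06-01") + c(0, 6, 14)
  vis <- lapply(seq_along(dates), function(i) vi_stack_7(seed = i, date = dates[i]))
  lais <- lapply(vis, function(v)
    mk_raster(4 * raster_band(v, "NDVI"), res = 30, date = v$date))
  cm <- fit_change_model(lais, vis)
  expect_false(cm$ridged)
  co <- cm$coefficients
  expect_lt(abs(co[["NDVI"]] - 4), 1e-6)
  expect_lt(max(abs(co[setdiff(names(co), "NDVI")])), 1e-6)
  expect_gt(cm$r2, 1 - 1e-9)
  # duplicating the whole pool leaves the least-squares fit unchanged
  cm2 <- fit_change_model(c(lais, lais), c(vis, vis))
  expect_equal(cm2$coefficients, cm$coefficients, tolerance = 1e-9)
})

test_that("change-model preconditions are enforced", {
  v1 <- vi_stack_7(n = 4, seed = 1, date = as.Date("2019-06-01"))
  l1 <- mk_raster(matrix(2, 4, 4), res = 30, date = v1$date)
  expect_error(fit_change_model(list(l1), list(v1)), ">= 2")
  v2 <- vi_stack_7(n = 4, seed = 2, date = as.Date("2019-06-07"))
  l2 <- mk_raster(matrix(2, 4, 4), res = 30, date = v2$date)
  expect_error(fit_change_model(list(l1, l2), list(v1, v2)), "pool has")
  l2$date <- as.Date("2019-06-08")
  expect_error(fit_change_model(list(l1, l2), list(v1, v2)), "coincident")
})

test_that("relative change is the ratio of change-model predictions", {
  dates <- as.Date("2019-06-01") + c(0, 8)
  vis <- lapply(1:2, function(i) vi_stack_7(seed = i, date = dates[i]))
  lais <- lapply(vis, function(v) mk_raster(4 * raster_band(v, "NDVI"),
                                            res = 30, date = v$date))
  cm <- fit_change_model(lais, vis)
  # identical stacks: factor 1 everywhere
  f1 <- relative_change(cm, vis[[1]], vis[[1]])
  expect_equal(as.vector(raster_band(f1, 1)), rep(1, 400), tolerance = 1e-9)
  # target twice the source: constant-NDVI stacks give factor 2
  mk_const <- function(nd) {
    labs <- vi_abbreviations("both")
    mk_stack(setNames(lapply(labs, function(x)
      matrix(ifelse(x == "NDVI", nd, 0.4), 20, 20)), labs), res = 30)
  }
  f2 <- relative_change(cm, mk_const(0.8), mk_const(0.4))
  expect_equal(as.vector(raster_band(f2, 1)), rep(2, 400), tolerance = 1e-6)
  # zero predicted source LAI: factor clipped at clip_max
  f3 <- relative_change(cm, mk_const(0.5), mk_const(0))
  expect_true(all(raster_band(f3, 1) <= reference_defaults()$clip_max))
})

test_that("reference-tile identity and screening hand cases hold", {
  target <- as.Date("2019-07-01")
  labs <- vi_abbreviations("both")
  const_vi <- function(d) mk_stack(setNames(lapply(labs, function(x)
    matrix(0.5, 6, 6)), labs), res = 30, date = d)
  vis <- lapply(as.list(target + c(0, -5, -10, 15)), const_vi)
  lai_const <- function(v, d) mk_raster(matrix(v, 6, 6), res = 30, date = d)
  cm <- fit_change_model(list(lai_const(3, target), lai_const(3, target - 5)),
                         vis[1:2])
  # single same-day scene: the reference IS that scene
  ref <- build_reference_tile(target, list(lai_const(3.7, target)), vis, cm)
  expect_equal(as.vector(raster_band(ref$lai, 1)), rep(3.7, 36))
  expect_true(all(raster_band(ref$n_used, 1) == 1))
  # three identical candidates: consensus, nothing screened
  scenes <- list(lai_const(3.0, target - 5), lai_const(3.0, target - 10),
                 lai_const(3.0, target + 15))
  ref2 <- build_reference_tile(target, scenes, vis, cm)
  expect_equal(as.vector(raster_band(ref2$lai, 1)), rep(3, 36))
  expect_true(all(raster_band(ref2$n_screened, 1) == 0))
  expect_true(all(raster_band(ref2$n_used, 1) == 3))
  # candidates {3.0, 3.1, 9.0}: the outlier is screened, the survivors
  # averaged with temporal weights (hand-computed expectation)
  scenes3 <- list(lai_const(3.0, target - 5), lai_const(3.1, target - 10),
                  lai_const(9.0, target + 15))
  ref3 <- build_reference_tile(target, scenes3, vis, cm)
  w <- exp(-c(5, 10) / 10)
  expected <- sum(c(3.0, 3.1) * w) / sum(w)
  expect_equal(as.vector(raster_band(ref3$lai, 1)), rep(expected, 36), tolerance = 1e-9)
  expect_true(all(raster_band(ref3$n_screened, 1) == 1))
  expect_error(build_reference_tile(target, scenes3[3], vis, cm,
                                    config = list(window = 10)), "no coarse scene")
})

test_that("a static crop yields a reference equal to the coarse LAI within noise", {
  set.seed(88)
  target <- as.Date("2019-07-01")
  labs <- vi_abbreviations("both")
  base <- matrix(runif(400, 0.2, 0.8), 20, 20)
  const_vi <- function(d) mk_stack(setNames(lapply(seq_along(labs), function(i)
    base * (0.5 + i / 10)), labs), res = 30, date = d)
  truth <- 2 + 3 * base
  dates <- target + c(-10, -5, 0, 5, 10)
  scenes <- lapply(as.list(dates), function(d)
    mk_raster(truth + rnorm(400, 0, 0.05), res = 30, date = d))
  vis <- lapply(as.list(c(dates, target)), const_vi)
  cm <- fit_change_model(scenes[c(3, 4)], vis[c(3, 4)])
  ref <- build_reference_tile(target, scenes, vis, cm)
  rv <- as.vector(raster_band(ref$lai, 1))
  expect_lt(sqrt(mean((rv - as.vector(truth))^2)), 0.1)
})

test_that("change correction beats nearest-scene sampling on a growing crop", {
  # per-pixel double-logistic season on a 12x12 30 m grid, scenes every 10
  # days, evaluated against truth on 26 intermediate target dates
  set.seed(5)
  n <- 12
  lmax <- matrix(runif(n * n, 3, 6), n, n)
  t0 <- as.Date("2019-05-01")
  curve <- function(d) {
    tt <- as.numeric(d - t0)
    lmax * (1 / (1 + exp(-0.12 * (tt - 45))) - 1 / (1 + exp(-0.10 * (tt - 140))))
  }
  base <- data.frame(cab = 55, cw = 0.018, cm = 0.007, n_struct = 1.5, ala = 55,
                     hotspot = 0.2, psoil = 0.45, sza = 30, vza = 5, raa = 90)
  vi_of <- function(d) {
    lai <- as.vector(curve(d))
    R <- toy_forward(cbind(lai = lai, base))
    labs <- vi_abbreviations("both")
    mk_stack(setNames(lapply(labs, function(a)
      matrix(laifusion:::vi_eval(a, as.list(as.data.frame(R))), n, n)), labs),
      res = 30, date = d)
  }
  scene_dates <- t0 + seq(0, 100, by = 10)
  scenes <- lapply(as.list(scene_dates), function(d)
    mk_raster(pmax(curve(d) + rnorm(n * n, 0, 0.05), 0), res = 30, date = d))
  vis <- lapply(as.list(scene_dates), vi_of)
  cm <- fit_change_model(scenes, vis)
  targets <- t0 + seq(23, 73, by = 2)
  rmse_corr <- rmse_near <- numeric(0)
  for (d in as.list(targets)) {
    ref <- build_reference_tile(d, scenes, function(dd) vi_of(dd), cm,
                                config = list(window = 12))
    tv <- as.vector(curve(d))
    rmse_corr <- c(rmse_corr, sqrt(mean((as.vector(raster_band(ref$lai, 1)) - tv)^2)))
    nearest <- scenes[[which.min(abs(as.numeric(scene_dates - d)))]]
    rmse_near <- c(rmse_near, sqrt(mean((as.vector(raster_band(nearest, 1)) - tv)^2)))
  }
  expect_gte(length(targets), 20)
  expect_lt(mean(rmse_corr), mean(rmse_near))
  # determinism
  ref_a <- build_reference_tile(targets[1], scenes, function(dd) vi_of(dd), cm)
  ref_b <- build_reference_tile(targets[1], scenes, function(dd) vi_of(dd), cm)
  expect_identical(ref_a$lai$values, ref_b$lai$values)
})

test_that("reference tiles persist as 4-band GeoTIFFs", {
  target <- as.Date("2019-07-01")
  labs <- vi_abbreviations("both")
  vis <- lapply(as.list(target + c(0, -5)), function(d)
    mk_stack(setNames(lapply(labs, function(x) matrix(0.5, 6, 6)), labs),
             res = 30, date = d))
  lai_const <- function(v, d) mk_raster(matrix(v, 6, 6), res = 30, date = d)
  cm <- fit_change_model(list(lai_const(3, target), lai_const(3, target - 5)), vis)
  ref <- build_reference_tile(target, list(lai_const(3.5, target)), vis, cm)
  f <- withr::local_tempfile(fileext = ".tif")
  write_reference_tile(ref, f)
  back <- read_raster(f)
  expect_identical(back$bands, c("lai", "weight", "n_used", "n_screened"))
  expect_equal(raster_band(back, "lai"), raster_band(ref$lai, 1), tolerance = 1e-6)
})
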