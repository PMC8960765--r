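test_that("GeoTIFF round trip is lossless at float32 precision", {
  set.seed(42)
  v <- array(runif(10 * 10 * 2, 0, 7), c(10, 10, 2))
  v[3, 4, 1] <- NA
  r <- sat_raster(v, c("lai", "weight"), res = 30, origin = c(120, 4500),
                  date = "2019-06-14", kind = "other")
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(r, f)
  r2 <- read_raster(f)
  expect_identical(r2$bands, r$bands)
  expect_equal(r2$res, r$res)
  expect_equal(r2$origin, r$origin)
  expect_equal(r2$date, as.Date("2019-06-14"))
  expect_equal(r2$nodata, r$nodata)
  expect_true(is.na(r2$values[3, 4, 1]))
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  # a second write/read of the already float32-quantized data is bit-exact
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_raster(r2, f2)
  expect_identical(read_raster(f2)$values, r2$values)
})

test_that("constant-raster round trip reproduces values exactly", {
  r <- sat_raster(array(0.25, c(10, 10, 2)), c("b490", "b560"), 3, c(0, 30),
                  kind = "reflectance")
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(r, f)
  expect_identical(read_raster(f)$values, r$values)
})

test_that("writing validates the declared value kind", {
  r <- sat_raster(array(1.2, c(4, 4, 1)), "b490", 3, c(0, 12), kind = "reflectance")
  f <- withr::local_tempfile(fileext = ".tif")
  expect_error(write_raster(r, f), "outside \\[0, 1\\]")
  r2 <- sat_raster(array(-0.5, c(4, 4, 1)), "lai", 3, c(0, 12), kind = "lai")
  expect_error(write_raster(r2, f), "below 0")
  expect_error(read_raster(file.path(tempdir(), "nope.tif")), "no such file")
})

test_that("simulator fine scenes carry the declared sensor geometry", {
  tr <- fx_small_campaign()
  sc <- fine_scene(tr, as.Date("2019-06-20"))
  expect_identical(sc$bands, c("b490", "b560", "b665", "b865"))
  expect_equal(sc$res, 3)
  expect_identical(sc$kind, "reflectance")
  expect_equal(sc$date, as.Date("2019-06-20"))
})

test_that("block-mean aggregation matches hand arithmetic and conventions", {
  # hand case: one 2x2 block
  r <- mk_raster(matrix(c(1, 3, 2, 4), 2, 2), res = 3)
  a <- aggregate_block_mean(r, 2L)
  expect_equal(as.vector(raster_band(a, 1)), 2.5)
  expect_equal(a$res, 6)
  # constants stay constant
  rc <- mk_raster(matrix(5, 20, 20), res = 3)
  expect_true(all(raster_band(aggregate_block_mean(rc, 10L), 1) == 5))
  # all-nodata block yields nodata; mixed block skips NA
  m <- matrix(1, 4, 4); m[1:2, 1:2] <- NA; m[3, 3] <- NA
  am <- aggregate_block_mean(mk_raster(m, res = 3), 2L)
  expect_true(is.na(raster_band(am, 1)[1, 1]))
  expect_equal(raster_band(am, 1)[2, 2], 1)
  # trailing partial blocks are dropped with a message
  expect_message(ap <- aggregate_block_mean(mk_raster(matrix(1, 5, 7), res = 3), 2L),
                 "partial")
  expect_identical(dim(ap$values)[1:2], c(2L, 3L))
  expect_error(aggregate_block_mean(rc, 0), "positive integer")
})

test_that("aggregation conserves the global mean over fully covered areas", {
  set.seed(7)
  m <- matrix(runif(60 * 60, 0, 6), 60, 60)
  a <- aggregate_block_mean(mk_raster(m, res = 3), 10L)
  expect_equal(mean(raster_band(a, 1)), mean(m), tolerance = 1e-9)
})

test_that("window extraction averages the centered pixel block", {
  m <- matrix(5, 30, 30)
  r <- mk_raster(m, res = 3, origin = c(0, 90))
  ctr <- c(10 * 3 - 1.5, 90 - (15 * 3 - 1.5))  # center of pixel (15, 10)
  expect_equal(extract_window_mean(r, ctr, 7L), 5)
  # column ramp: symmetry about the center column
  ramp <- matrix(rep(1:30, times = 30), 30, 30, byrow = TRUE)  # value = column index
  rr <- mk_raster(ramp, res = 3, origin = c(0, 90))
  expect_equal(extract_window_mean(rr, ctr, 7L), 10)
  # window 1 equals point sampling of the containing pixel
  expect_equal(extract_window_mean(rr, ctr, 1L), ramp[15, 10])
  expect_error(extract_window_mean(rr, ctr, 4L), "odd")
  expect_error(extract_window_mean(rr, c(200, 200), 7L), "edge")
  expect_error(extract_window_mean(rr, c(1.5, 88.5), 7L), "edge")
})

test_that("coordinate-to-pixel mapping uses the floor rule", {
  r <- mk_raster(matrix(0, 10, 10), res = 3, origin = c(0, 30))
  rc <- laifusion:::map_to_cell(r, c(0, 2.999, 3, 4.5), c(30, 30, 30, 28.5))
  expect_equal(unname(rc[, "col"]), c(1, 1, 2, 2))
  expect_equal(unname(rc[, "row"]), c(1, 1, 1, 1))
})

test_that("field-observation CSV round trips and validates stage codes", {
  obs <- data.frame(field_id = "Ne1", imz_id = "Ne1-IMZ1", x = 100.5, y = 200.5,
                    date = as.Date("2019-07-01"), lai = 3.25,
                    stage = c("VT", NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_field_observations(obs, f)
  back <- read_field_observations(f)
  expect_equal(back$lai, obs$lai)
  expect_equal(back$date, obs$date)
  expect_identical(back$stage, c("VT", NA))
  obs$stage <- "Z9"
  expect_error(write_field_observations(obs, f), "unknown stage")
  obs$stage <- "VT"; obs$lai <- -1
  expect_error(write_field_observations(obs, f), ">= 0")
})
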