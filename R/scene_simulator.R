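# Synthetic two-sensor maize campaign with known truth: three rectangular
# fields (two irrigated, one rain-fed) on a 600 x 600 pixel 3 m scene,
# per-pixel double-logistic LAI trajectories with spatially correlated
# heterogeneity and underperforming patches, daily gap-free 4-band fine
# scenes, 9-band coarse scenes on a 5-day schedule with random dropouts,
# and destructive plot sampling in six 20 x 20 m intensive measurement
# zones (IMZs) per field.

#' Field specification
#'
#' @param field_id field name.
#' @param rows,cols 3 m pixel ranges (inclusive) of the rectangular field.
#' @param planting_date planting `Date`.
#' @param lai_max_mean field-mean peak LAI (irrigated ~5.5, rain-fed ~4.2).
#' @param senescence_onset `Date` around which decline begins.
#' @param het_length heterogeneity correlation length in m.
#' @param het_amplitude multiplicative heterogeneity standard deviation.
#' @param n_patches,patch_size,patch_depth underperforming patches: count,
#'   radius in m, multiplicative depression (0-1, lower = deeper).
#' @return object of class `field_spec`.
#' @export
field_spec <- function(field_id, rows, cols, planting_date, lai_max_mean,
                       senescence_onset, het_length = 60, het_amplitude = 0.10,
                       n_patches = 4, patch_size = 45, patch_depth = 0.7) {
  planting_date <- as.Date(planting_date); senescence_onset <- as.Date(senescence_onset)
  if (lai_max_mean < 0) stopf("lai_max_mean must be > 0")
  if (planting_date >= senescence_onset) stopf("planting must precede senescence onset")
  structure(list(field_id = field_id, rows = rows, cols = cols,
                 planting_date = planting_date, lai_max_mean = lai_max_mean,
                 senescence_onset = senescence_onset, het_length = het_length,
                 het_amplitude = het_amplitude, n_patches = n_patches,
                 patch_size = patch_size, patch_depth = patch_depth),
            class = "field_spec")
}

#' Default campaign configuration
#'
#' A 600 x 600 pixel scene at 3 m (1.8 x 1.8 km) holding three maize fields
#' that mirror the study layout: two irrigated fields planted four days
#' apart (peak LAI ~5.5) and one rain-fed field (peak ~4.2, earlier
#' senescence). Season mid-April to end of October; the coarse sensor
#' revisits every 5 days with 30% random dropouts; reflectance noise 0.01
#' (1 sigma) per band plus a small fine-sensor residual harmonization bias;
#' destructive IMZ sampling noise 8% CV.
#'
#' @return nested configuration list.
#' @export
campaign_config <- function() {
  list(
    scene = list(n_rows = 600L, n_cols = 600L, res = 3, origin = c(0, 1800),
                 season_start = as.Date("2019-04-15"),
                 season_end = as.Date("2019-10-31")),
    fields = list(
      field_spec("Ne1", c(40, 250), c(40, 270), "2019-04-19", 5.5, "2019-09-02"),
      field_spec("Ne2", c(40, 250), c(320, 560), "2019-04-23", 5.5, "2019-09-05"),
      field_spec("Ne3", c(330, 560), c(120, 470), "2019-04-24", 4.2, "2019-08-27",
                 het_amplitude = 0.14)),
    growth = list(k1 = 0.16, k2 = 0.10, greenup_lag = 50, decline_lead = 8),
    coarse = list(revisit = 5L, dropout = 0.3),
    noise = list(sigma = 0.01, fine_bias = 0.005, imz_cv = 0.08),
    imz = list(per_field = 6L, size_m = 20))
}

#' Double-logistic LAI growth curve
#'
#' `L(t) = Lmax (s(k1 (t - t1)) - s(k2 (t - t2)))` with logistic `s`,
#' `t1 < t2`, re-zeroed at planting: values are offset by the planting-date
#' value and clipped at zero, so LAI(planting) = 0 exactly and the curve has
#' a single interior maximum and returns to zero by season end.
#'
#' @param params list with `lai_max`, `t1`, `t2`, `k1`, `k2`, `planting`
#'   (times as `Date` or numeric days).
#' @param t evaluation times (`Date` or numeric, same scale as the params).
#' @return LAI values.
#' @export
lai_truth_curve <- function(params, t) {
  tn <- as.numeric(t); t1 <- as.numeric(params$t1); t2 <- as.numeric(params$t2)
  if (t2 <= t1) stopf("t2 must exceed t1")
  sig <- function(z) 1 / (1 + exp(-z))
  raw <- function(tt) params$lai_max * (sig(params$k1 * (tt - t1)) - sig(params$k2 * (tt - t2)))
  p0 <- if (!is.null(params$planting)) raw(as.numeric(params$planting)) else 0
  v <- pmax(0, raw(tn) - p0)
  if (!is.null(params$planting)) v[tn < as.numeric(params$planting)] <- 0
  v
}

field_curve_params <- function(fs, growth) {
  list(lai_max = fs$lai_max_mean,
       t1 = as.numeric(fs$planting_date) + growth$greenup_lag,
       t2 = as.numeric(fs$senescence_onset) + growth$decline_lead,
       k1 = growth$k1, k2 = growth$k2,
       planting = as.numeric(fs$planting_date))
}

# Smooth correlated multiplicative field: white noise on a coarse grid at
# the correlation length, bilinearly interpolated to the pixel grid.
correlated_field <- function(n_rows, n_cols, res, corr_m, amplitude) {
  if (amplitude <= 0) return(matrix(1, n_rows, n_cols))
  step <- max(2L, round(corr_m / res))
  gr <- seq(1L, n_rows + step, by = step); gc <- seq(1L, n_cols + step, by = step)
  z <- matrix(stats::rnorm(length(gr) * length(gc), 0, amplitude), length(gr), length(gc))
  ri <- pmin((seq_len(n_rows) - 1) / step + 1, length(gr) - 1e-9)
  ci <- pmin((seq_len(n_cols) - 1) / step + 1, length(gc) - 1e-9)
  r0 <- floor(ri); c0 <- floor(ci); fr <- ri - r0; fc <- ci - c0
  zr <- z[r0, , drop = FALSE] * (1 - fr) + z[pmin(r0 + 1, length(gr)), , drop = FALSE] * fr
  out <- zr[, c0, drop = FALSE] * rep(1 - fc, each = n_rows) +
         zr[, pmin(c0 + 1, length(gc)), drop = FALSE] * rep(fc, each = n_rows)
  pmax(1 + out, 0.2)
}

#' Generate the campaign truth
#'
#' Builds the per-pixel peak-LAI (Lmax) surface — field mean x correlated
#' heterogeneity x patch depressions — the field map, the IMZ centers (six
#' per field on a 2 x 3 grid), and the coarse-sensor acquisition schedule
#' with random dropouts. Daily truth rasters are derived on demand by
#' [truth_lai()].
#'
#' @param config see [campaign_config()].
#' @param seed integer seed; the truth is fully reproducible from
#'   `(config, seed)`.
#' @return object of class `campaign_truth`.
#' @export
generate_truth <- function(config = campaign_config(), seed = 1) {
  sc <- config$scene
  occupied <- matrix(FALSE, sc$n_rows, sc$n_cols)
  for (fs in config$fields) {
    blk <- occupied[fs$rows[1]:fs$rows[2], fs$cols[1]:fs$cols[2]]
    if (any(blk)) stopf("fields overlap at %s", fs$field_id)
    occupied[fs$rows[1]:fs$rows[2], fs$cols[1]:fs$cols[2]] <- TRUE
  }
  lmax <- matrix(0, sc$n_rows, sc$n_cols)
  field_map <- matrix(NA_integer_, sc$n_rows, sc$n_cols)
  imz <- list()
  with_seed(seed, {
    for (fi in seq_along(config$fields)) {
      fs <- config$fields[[fi]]
      nr <- fs$rows[2] - fs$rows[1] + 1L; nc <- fs$cols[2] - fs$cols[1] + 1L
      het <- correlated_field(nr, nc, sc$res, fs$het_length, fs$het_amplitude)
      if (fs$n_patches > 0) {
        pr <- stats::runif(fs$n_patches, 0.1, 0.9) * nr
        pc <- stats::runif(fs$n_patches, 0.1, 0.9) * nc
        rad <- fs$patch_size / sc$res
        rows_i <- matrix(seq_len(nr), nr, nc); cols_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        for (p in seq_len(fs$n_patches)) {
          d2 <- (rows_i - pr[p])^2 + (cols_i - pc[p])^2
          het <- het * (1 - (1 - fs$patch_depth) * exp(-d2 / (2 * rad^2)))
        }
      }
      lmax[fs$rows[1]:fs$rows[2], fs$cols[1]:fs$cols[2]] <- fs$lai_max_mean * het
      field_map[fs$rows[1]:fs$rows[2], fs$cols[1]:fs$cols[2]] <- fi
      # IMZ centers: 2 x 3 grid well inside the field
      rfr <- fs$rows[1] + (fs$rows[2] - fs$rows[1]) * c(0.3, 0.7)
      cfr <- fs$cols[1] + (fs$cols[2] - fs$cols[1]) * c(0.25, 0.5, 0.75)
      k <- 0L
      for (rr in rfr) for (cc in cfr) {
        k <- k + 1L
        imz[[length(imz) + 1L]] <- data.frame(
          field_id = fs$field_id, imz_id = paste0(fs$field_id, "-IMZ", k),
          x = sc$origin[1] + (cc - 0.5) * sc$res,
          y = sc$origin[2] - (rr - 0.5) * sc$res)
      }
    }
    all_dates <- seq(sc$season_start, sc$season_end, by = "day")
    sched <- all_dates[seq(1L, length(all_dates), by = config$coarse$revisit)]
    keep <- stats::runif(length(sched)) >= config$coarse$dropout
    keep[1L] <- TRUE   # anchor the schedule
    coarse_dates <- sched[keep]
    structure(list(config = config, seed = seed,
                   lmax = sat_raster(array(lmax, c(sc$n_rows, sc$n_cols, 1L)),
                                     "lmax", sc$res, sc$origin, kind = "lai"),
                   field_map = field_map,
                   curves = lapply(config$fields, field_curve_params,
                                   growth = config$growth),
                   imz_centers = do.call(rbind, imz),
                   coarse_dates = coarse_dates, dates = all_dates),
              class = "campaign_truth")
  })
}

#' @export
print.campaign_truth <- function(x, ...) {
  sc <- x$config$scene
  cat(sprintf("<campaign_truth> %dx%d px @ %g m, %s..%s, %d field(s), %d coarse date(s)\n",
              sc$n_rows, sc$n_cols, sc$res, format(sc$season_start),
              format(sc$season_end), length(x$config$fields), length(x$coarse_dates)))
  invisible(x)
}

#' Daily truth LAI raster
#'
#' Per pixel, the double-logistic curve of its field scaled by the pixel's
#' Lmax surface; background pixels are bare soil (LAI 0).
#'
#' @param truth a `campaign_truth`.
#' @param date target `Date`.
#' @return 3 m single-band LAI [sat_raster].
#' @export
truth_lai <- function(truth, date) {
  date <- as.Date(date)
  sc <- truth$config$scene
  lai <- matrix(0, sc$n_rows, sc$n_cols)
  lmax <- raster_band(truth$lmax, 1L)
  for (fi in seq_along(truth$curves)) {
    cp <- truth$curves[[fi]]
    # unit-amplitude curve; pixel Lmax scales it
    unit <- lai_truth_curve(utils::modifyList(cp, list(lai_max = 1)), date)
    sel <- !is.na(truth$field_map) & truth$field_map == fi
    lai[sel] <- lmax[sel] * unit
  }
  sat_raster(array(lai, c(sc$n_rows, sc$n_cols, 1L)), "lai", sc$res, sc$origin,
             date, kind = "lai")
}

# Scene-level canopy parameters for one date: fixed mid-season values with a
# small deterministic daily jitter.
scene_canopy_params <- function(truth, date, lai) {
  j <- with_seed(day_seed(truth$seed, date, salt = 5L), stats::rnorm(4, 0, 1))
  data.frame(lai = lai,
             cab = 55 + 2 * j[1], cw = 0.018 + 0.001 * j[2],
             cm = 0.007, n_struct = 1.5, ala = 55 + 2 * j[3],
             hotspot = 0.2, psoil = 0.45 + 0.03 * j[4], sza = 30, vza = 5, raa = 90)
}

#' Render a reflectance scene from a truth LAI raster
#'
#' Reflectance comes from the forward model at the pixel LAI (non-LAI canopy
#' parameters fixed per date with small jitter), plus zero-mean Gaussian
#' noise and, for the fine sensor, a per-band residual harmonization bias;
#' values are clipped to (0, 1). Coarse scenes must be rendered from the
#' 10 x 10 block-mean of the 3 m truth (see [coarse_scene()]).
#'
#' @param truth_raster LAI [sat_raster] on the sensor's grid.
#' @param profile [sensor_profile] (band subset is taken from it).
#' @param truth the `campaign_truth` (scene parameters + seeds).
#' @param noise list with `sigma` (per-band Gaussian sd) and `fine_bias`
#'   (bias magnitude for the fine sensor); defaults from the campaign config.
#' @param forward_model forward model (default [toy_forward()]).
#' @return reflectance [sat_raster] with the profile's bands.
#' @export
render_scene <- function(truth_raster, profile, truth, noise = NULL,
                         forward_model = toy_forward) {
  noise <- noise %||% truth$config$noise
  date <- truth_raster$date
  lai <- as.vector(raster_band(truth_raster, 1L))
  params <- scene_canopy_params(truth, date, lai)
  refl <- forward_model(params)                    # [n, 9] coarse bands
  refl <- refl[, profile$bands, drop = FALSE]
  nb <- length(profile$bands)
  salt <- if (identical(profile$name, "fine")) 11L else 13L
  refl <- with_seed(day_seed(truth$seed, date, salt = salt), {
    if (noise$sigma > 0)
      refl <- refl + matrix(stats::rnorm(length(refl), 0, noise$sigma),
                            nrow(refl), nb)
    if (identical(profile$name, "fine") && (noise$fine_bias %||% 0) > 0)
      refl <- refl + matrix(stats::runif(nb, -noise$fine_bias, noise$fine_bias),
                            nrow(refl), nb, byrow = TRUE)
    refl
  })
  refl <- pmin(pmax(refl, 1e-4), 0.999)
  d <- dim(truth_raster$values)
  sat_raster(array(refl, c(d[1], d[2], nb)), profile$bands,
             truth_raster$res, truth_raster$origin, date,
             kind = "reflectance")
}

#' Render the daily fine-sensor scene / a scheduled coarse scene
#'
#' @param truth a `campaign_truth`.
#' @param date target `Date`; for [coarse_scene()] it must be one of the
#'   scheduled acquisition dates.
#' @return reflectance [sat_raster].
#' @export
fine_scene <- function(truth, date) {
  render_scene(truth_lai(truth, date), fine_sensor(truth$config$scene$res), truth)
}

#' @rdname fine_scene
#' @export
coarse_scene <- function(truth, date) {
  date <- as.Date(date)
  if (!date %in% truth$coarse_dates)
    stopf("no coarse acquisition on %s", format(date))
  lai30 <- aggregate_block_mean(truth_lai(truth, date), 10L)
  render_scene(lai30, coarse_sensor(truth$config$scene$res * 10), truth)
}

# Mean truth LAI over the IMZ footprint (pixels whose centers fall in the
# size_m x size_m square around the center).
imz_truth_mean <- function(truth, lai_raster, x, y, size_m = 20) {
  half <- size_m / 2
  r <- lai_raster
  rc <- map_to_cell(r, c(x - half + 1e-9, x + half - 1e-9),
                    c(y + half - 1e-9, y - half + 1e-9))
  rows <- rc[1, "row"]:rc[2, "row"]; cols <- rc[1, "col"]:rc[2, "col"]
  mean(raster_band(r, 1L)[rows, cols], na.rm = TRUE)
}

#' Simulate destructive IMZ sampling
#'
#' One observation per IMZ and date: the truth LAI averaged over the
#' 20 x 20 m footprint, perturbed by lognormal noise with the configured
#' coefficient of variation (emulating 5-7-plant destructive sampling scaled
#' by plant population), plus a phenology-stage label derived from the
#' field-mean growth curve.
#'
#' @param truth a `campaign_truth`.
#' @param dates_by_field named list: field_id -> vector of sampling `Date`s.
#' @param noise_cv coefficient of variation (default from config).
#' @param seed integer seed.
#' @return field-observation data frame (see [read_field_observations()]).
#' @export
simulate_imz_sampling <- function(truth, dates_by_field, noise_cv = NULL, seed = 1) {
  noise_cv <- noise_cv %||% truth$config$noise$imz_cv
  rows <- list()
  for (fi in seq_along(truth$config$fields)) {
    fs <- truth$config$fields[[fi]]
    dates <- as.Date(dates_by_field[[fs$field_id]])
    if (!length(dates)) next
    if (any(dates < truth$config$scene$season_start |
            dates > truth$config$scene$season_end))
      stopf("sampling dates outside the campaign for %s", fs$field_id)
    centers <- truth$imz_centers[truth$imz_centers$field_id == fs$field_id, ]
    for (d in seq_along(dates)) {
      lr <- truth_lai(truth, dates[d])
      stage <- stage_from_curve(truth$curves[[fi]], dates[d])
      for (k in seq_len(nrow(centers))) {
        mu <- imz_truth_mean(truth, lr, centers$x[k], centers$y[k],
                             truth$config$imz$size_m)
        rows[[length(rows) + 1L]] <- data.frame(
          field_id = fs$field_id, imz_id = centers$imz_id[k],
          x = centers$x[k], y = centers$y[k], date = dates[d],
          lai = mu, stage = stage %||% NA_character_)
      }
    }
  }
  obs <- do.call(rbind, rows)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- with_seed(seed, stats::rlnorm(nrow(obs), -sdlog^2 / 2, sdlog))
    obs$lai <- obs$lai * fac
  }
  obs
}

# Stage label from the field-mean curve position at `date`. Thresholds are
# fractions of peak LAI; the plateau (>= 95% of peak) is split evenly in
# time into R1..R4.
stage_from_curve <- function(cp, date, thresholds = NULL) {
  th <- utils::modifyList(list(v2 = 0.02, v6 = 0.15, v11 = 0.45, vt = 0.85,
                               plateau = 0.95, r5 = 0.5), thresholds %||% list())
  tgrid <- seq(as.numeric(cp$planting), as.numeric(cp$t2) + 120, by = 1)
  L <- lai_truth_curve(cp, tgrid)
  peak <- max(L); tpk <- tgrid[which.max(L)]
  if (peak <= 0) return(NA_character_)
  tn <- as.numeric(as.Date(date))
  f <- lai_truth_curve(cp, tn) / peak
  plate <- range(tgrid[L >= th$plateau * peak])
  if (tn < plate[1]) {                     # ascending limb
    if (f < th$v2) return(NA_character_)
    if (f < th$v6) return("V2")
    if (f < th$v11) return("V6")
    if (f < th$vt) return("V11")
    return("VT")
  }
  if (tn <= plate[2]) {                    # plateau: quarters -> R1..R4
    q <- ceiling(4 * (tn - plate[1] + 1) / (plate[2] - plate[1] + 1))
    return(paste0("R", min(max(q, 1), 4)))
  }
  if (f >= th$r5) return("R5")        # dent: distinct but moderate decline
  "R6"                                # maturity: green LAI largely gone
}

#' Scheduled sampling dates mirroring the study design
#'
#' Thirteen dates between late May and late September for the two irrigated
#' fields and eleven between late May and mid September for the rain-fed
#' field (roughly 10-12 days apart).
#'
#' @param config campaign configuration (dates are clipped to the season).
#' @return named list of `Date` vectors keyed by field id.
#' @export
imz_sampling_dates <- function(config = campaign_config()) {
  d13 <- seq(as.Date("2019-05-23"), as.Date("2019-09-25"), length.out = 13)
  d11 <- seq(as.Date("2019-05-29"), as.Date("2019-09-18"), length.out = 11)
  list(Ne1 = as.Date(round(as.numeric(d13)), origin = "1970-01-01"),
       Ne2 = as.Date(round(as.numeric(d13)), origin = "1970-01-01"),
       Ne3 = as.Date(round(as.numeric(d11)), origin = "1970-01-01"))
}
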