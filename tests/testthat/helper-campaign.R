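# Heavy shared fixtures, built once per test session and memoized. All
# fixtures are deterministic (fixed seeds) so every test file sees the same
# objects regardless of execution order.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Default study campaign: 600 x 600 px at 3 m, three maize fields.
fx_campaign <- function() memo("campaign", function() generate_truth(campaign_config(), seed = 1))

# Default-scale radiative-transfer training set and forest ensemble.
fx_training_set <- function() memo("training_set", function() build_training_set(n = 50000, seed = 7))

fx_ensemble <- function() memo("ensemble", function() train_lai_ensemble(fx_training_set(), seed = 1))

# A 30-day greenup-to-peak production window plus all plot-sampling dates,
# produced in a single pipeline run (one shared coarse branch).
fx_window_dates <- function() seq(as.Date("2019-06-14"), as.Date("2019-07-13"), by = "day")

fx_obs <- function() memo("obs", function()
  simulate_imz_sampling(fx_campaign(), imz_sampling_dates(campaign_config()), seed = 5))

fx_run <- function() memo("run", function() {
  dates <- sort(unique(c(fx_window_dates(), as.Date(fx_obs()$date))))
  run_daily_pipeline(fx_campaign(), fx_ensemble(), dates, seed = 1)
})

# Small campaign (200 x 200 px) for fast module-level integration tests.
fx_small_config <- function() {
  cfg <- campaign_config()
  cfg$scene$n_rows <- 200L; cfg$scene$n_cols <- 200L; cfg$scene$origin <- c(0, 600)
  cfg$fields <- list(
    field_spec("Ne1", c(20, 90), c(20, 90), "2019-04-19", 5.5, "2019-09-02"),
    field_spec("Ne2", c(20, 90), c(110, 180), "2019-04-23", 5.5, "2019-09-05"),
    field_spec("Ne3", c(110, 180), c(40, 160), "2019-04-24", 4.2, "2019-08-27"))
  cfg
}

fx_small_campaign <- function() memo("small_campaign", function() generate_truth(fx_small_config(), seed = 11))
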