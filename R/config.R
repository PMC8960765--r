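# YAML configuration for the command-line entry point. The file is a nested
# list mirroring campaign_config() plus `reference`, `downscaler`,
# `training` and `dates` sections; anything omitted falls back to package
# defaults.

#' Load a pipeline configuration from YAML
#'
#' Sections: `scene`, `fields` (list of field specs), `growth`, `coarse`,
#' `noise`, `imz` (all merged over [campaign_config()]); `training`
#' (`n`, `num_trees`, `noise_sigma`); `reference` ([reference_defaults()]);
#' `downscaler` ([downscaler_defaults()]); `dates` (`start`, `end`);
#' `seed`.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return nested configuration list with `campaign`, `training`,
#'   `reference`, `downscaler`, `dates`, `seed`.
#' @export
load_pipeline_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  camp <- campaign_config()
  for (sec in c("scene", "growth", "coarse", "noise", "imz"))
    if (!is.null(user[[sec]])) camp[[sec]] <- utils::modifyList(camp[[sec]], user[[sec]])
  camp$scene$season_start <- as.Date(camp$scene$season_start)
  camp$scene$season_end <- as.Date(camp$scene$season_end)
  if (!is.null(user$fields))
    camp$fields <- lapply(user$fields, function(f)
      field_spec(f$field_id, unlist(f$rows), unlist(f$cols), f$planting_date,
                 f$lai_max_mean, f$senescence_onset,
                 het_length = f$het_length %||% 60,
                 het_amplitude = f$het_amplitude %||% 0.10,
                 n_patches = f$n_patches %||% 4,
                 patch_size = f$patch_size %||% 45,
                 patch_depth = f$patch_depth %||% 0.7))
  utrain <- user$training %||% list()
  # YAML 1.1 reads a bare `n` key as a boolean, so the sample count is
  # spelled `n_samples` in config files
  if (!is.null(utrain$n_samples)) utrain$n <- utrain$n_samples
  if (!is.null(utrain[["FALSE"]])) utrain$n <- utrain[["FALSE"]]
  utrain$n_samples <- NULL; utrain[["FALSE"]] <- NULL
  list(campaign = camp,
       training = utils::modifyList(list(n = 50000, num_trees = 200,
                                         noise_sigma = 0.01), utrain),
       reference = utils::modifyList(reference_defaults(), user$reference %||% list()),
       downscaler = utils::modifyList(downscaler_defaults(), user$downscaler %||% list()),
       dates = list(start = as.Date((user$dates %||% list())$start %||% camp$scene$season_start),
                    end = as.Date((user$dates %||% list())$end %||% camp$scene$season_end)),
       seed = user$seed %||% 1L)
}
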