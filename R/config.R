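#' Default engine configuration
#'
#' Sections mirror the modules: `grid` (conceptual Amsler grid geometry),
#' `amsler` (test schedule defaults), `exercises` (catalogue version),
#' `recommender` (learning rate `alpha`, challenge margin `delta`, target
#' success `band`, `rolling_window`) and `simulator` (synthetic patient
#' defaults).
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    grid = list(width_cm = 10, height_cm = 10, spacing_cm = 0.5,
                working_distance_cm = 30, diagonal_lines = TRUE,
                thick_center = TRUE),
    amsler = list(n_stimuli = 50L, display_s = 3, response_window_s = 3,
                  followup_neighborhood_cells = 2L),
    exercises = list(version = "revised"),
    recommender = list(alpha = 0.3, delta = 0.1, band = c(0.6, 0.8),
                       rolling_window = 10L),
    simulator = list()
  )
}

#' Load a YAML/JSON configuration file over the defaults
#'
#' Missing keys fall back to [default_config()]; `NULL` path returns the
#' defaults unchanged.
#'
#' @param path YAML or JSON config file, or `NULL`
#' @return nested named list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop_rehab(sprintf("config file '%s' not found", path), "eyerehab_usage_error")
  }
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_rehab(sprintf("cannot parse config '%s': %s", path, conditionMessage(e)),
               "eyerehab_usage_error")
  })
  if (!is.list(user)) {
    stop_rehab(sprintf("config '%s' is not a mapping", path), "eyerehab_usage_error")
  }
  utils::modifyList(cfg, user)
}

config_grid <- function(cfg) {
  g <- cfg$grid
  grid_spec(g$width_cm, g$height_cm, g$spacing_cm, g$working_distance_cm,
            g$diagonal_lines %||% FALSE, g$thick_center %||% FALSE)
}
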