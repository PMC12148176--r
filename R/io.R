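# Tabular input/output and geometry helpers. The interchange format is
# headered CSV (comma, UTF-8, "." decimal); blink rows may have blank
# positions.

#' Read a gaze-sample table
#'
#' Expects a delimited text file with header columns `time_ms`, `x`, `y`,
#' `label` (`FIX`/`SACC`/`BLINK`) and `participant_id`. Positions may be
#' blank only on `BLINK` rows. The time grid must be uniform; violations are
#' reported with the first offending row.
#'
#' @param path Path to a CSV file.
#' @return A validated `gaze_recording`.
#' @export
read_gaze_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_ms", "x", "y", "label", "participant_id")
  miss <- setdiff(needed, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  rec <- new_gaze_recording(
    time_ms = as.numeric(d$time_ms), x = as.numeric(d$x),
    y = as.numeric(d$y), label = as.character(d$label),
    participant_id = as.character(d$participant_id),
    sampling_interval = if (nrow(d) > 1) diff(as.numeric(d$time_ms))[1] else 1
  )
  validate_gaze_recording(rec)
  rec
}

#' Write a gaze-sample table
#' @param rec A `gaze_recording`.
#' @param path Output CSV path. Missing (blink) positions are written blank.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(rec, path) {
  write.csv(as.data.frame(rec), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial-response table
#' @param path CSV with columns `participant_id`, `flicker_freq`,
#'   `true_side`, `answer`.
#' @return A validated data frame.
#' @export
read_trial_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "flicker_freq", "true_side", "answer")
  miss <- setdiff(needed, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  bad <- which(!(d$true_side %in% c("left", "right")))
  if (length(bad)) stop(sprintf("invalid true_side at row %d", bad[1]))
  bad <- which(!(d$answer %in% c("left", "right", "not_sure")))
  if (length(bad)) stop(sprintf("invalid answer at row %d", bad[1]))
  d$participant_id <- as.character(d$participant_id)
  d
}

#' Write a trial-response table
#' @param trials Trial-response data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Visual angle subtended by a stimulus
#'
#' `theta = atan(size / distance)` in degrees, with the stimulus size in cm
#' and the viewing distance in metres. A 2.5 cm cross at 1 m subtends 1.4
#' degrees; a 35 cm separation at 1 m subtends 19 degrees.
#'
#' @param size_cm Stimulus extent in cm (>= 0).
#' @param distance_m Viewing distance in metres (> 0).
#' @return Angle in degrees (full precision; round at display time).
#' @examples
#' round(visual_angle(2.5, 1), 1)
#' @export
visual_angle <- function(size_cm, distance_m) {
  if (any(distance_m <= 0)) stop("`distance_m` must be positive")
  if (any(size_cm < 0)) stop("`size_cm` must be non-negative")
  atan(size_cm / (100 * distance_m)) * 180 / pi
}

#' Full pipeline configuration
#'
#' Every tunable of the end-to-end analysis lives here: cohort size, the
#' simulator settings ([simulation_config()] fields), the tremor-to-CFFT
#' link, screen geometry, and the analysis flags of each stage.
#'
#' @param n_participants Cohort size.
#' @param sim A [simulation_config()].
#' @param link_params,tremor_band,tremor_amp,drift_diffusion,detection_slope
#'   Cohort-sampling parameters, see [sample_profiles()].
#' @param threshold_freqs Detection thresholds analysed, Hz.
#' @param include_emd Compute the 12 EMD feature families (slower) in
#'   addition to the 4 spectral ones.
#' @param classifier_families Feature families offered to the classifier.
#' @param reversal_k,reversal_lags,reversal_n_min Reversal-statistic
#'   settings.
#' @param min_segment,emd_min_segment,grid_step Spectral/EMD settings.
#' @param subset_search Search feature-family subsets in the inner CV.
#' @param distance_m,screen_px Viewing geometry (1 m; 1920x1080).
#' @param seed Integer master seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(n_participants = 12,
                       sim = simulation_config(),
                       link_params = list(slope = 1, intercept = -45,
                                          noise_sd = 0),
                       tremor_band = c(70, 150),
                       tremor_amp = 0.01,
                       drift_diffusion = 0.001,
                       detection_slope = 0.5,
                       threshold_freqs = c(60, 120),
                       include_emd = TRUE,
                       classifier_families = spectrum_families(),
                       reversal_k = c(2, 4, 8),
                       reversal_lags = 1:10,
                       reversal_n_min = 100,
                       min_segment = 128,
                       emd_min_segment = 64,
                       grid_step = 0.5,
                       subset_search = TRUE,
                       distance_m = 1,
                       screen_px = c(1920, 1080),
                       seed = 1) {
  stopifnot(n_participants >= 1, inherits(sim, "sim_config"))
  structure(
    list(n_participants = as.integer(n_participants), sim = sim,
         link_params = link_params, tremor_band = tremor_band,
         tremor_amp = tremor_amp, drift_diffusion = drift_diffusion,
         detection_slope = detection_slope,
         threshold_freqs = threshold_freqs, include_emd = include_emd,
         classifier_families = classifier_families,
         reversal_k = reversal_k, reversal_lags = reversal_lags,
         reversal_n_min = reversal_n_min, min_segment = min_segment,
         emd_min_segment = emd_min_segment, grid_step = grid_step,
         subset_search = subset_search, distance_m = distance_m,
         screen_px = screen_px, seed = seed),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [run_config()] defaults; keys under `sim`
#' override [simulation_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  cfg_args <- raw
  cfg_args$sim <- do.call(simulation_config, sim_args)
  do.call(run_config, cfg_args)
}
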