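#' Configuration of the synthetic gaze experiment
#'
#' Bundles every tunable of the gaze generator and of the simulated flicker
#' task. Defaults emulate a two-target flicker-identification session on a
#' 1 kHz eye tracker: two crosses 19 degrees apart, one flickering at 30, 60
#' or 120 Hz, three trials per frequency.
#'
#' @param sampling_interval Sampling step in ms (1 = 1 kHz tracking).
#' @param duration Recording length in seconds.
#' @param target_separation Angular distance between the two stimulus
#'   crosses, degrees of visual angle.
#' @param target_size Width/height of each cross, degrees.
#' @param fixation_mean_duration Mean fixation duration in ms. Individual
#'   fixations are 100 ms plus an exponential with the remaining mean.
#' @param saccade_duration Duration of the between-target saccade, ms.
#' @param microsaccade_rate Rate of small intra-fixation gaze jumps, 1/s.
#' @param microsaccade_amp Typical microsaccade amplitude, degrees.
#' @param noise_sd Standard deviation of white measurement noise on each
#'   position sample, degrees.
#' @param blink_rate Blink rate, 1/s. Blink spans carry missing positions.
#' @param blink_duration Blink duration, ms.
#' @param tremor_waveform `"circular"` (x and y components in quadrature, so
#'   the velocity direction rotates at the tremor frequency) or `"linear"`
#'   (oscillation along a random fixed axis).
#' @param tremor_coherence Phase-coherence time of the tremor in ms: the
#'   oscillator phase accumulates Gaussian jitter with variance
#'   `2 * lag / tremor_coherence` (rad^2). `Inf` gives a deterministic
#'   sinusoid. The default, 10 ms, makes the tremor burst-like, coherent
#'   over roughly one to two cycles in the 70-150 Hz band.
#' @param flicker_frequencies Flicker frequencies shown in the task, Hz.
#' @param trials_per_frequency Trials per flicker frequency.
#' @param seed Optional integer seed used by the simulators when no explicit
#'   seed is passed to them.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- simulation_config(duration = 5, seed = 1)
#' cfg$target_separation
#' @export
simulation_config <- function(sampling_interval = 1,
                              duration = 30,
                              target_separation = 19,
                              target_size = 1.4,
                              fixation_mean_duration = 300,
                              saccade_duration = 50,
                              microsaccade_rate = 1.5,
                              microsaccade_amp = 0.25,
                              noise_sd = 0.001,
                              blink_rate = 0.05,
                              blink_duration = 150,
                              tremor_waveform = c("circular", "linear"),
                              tremor_coherence = 10,
                              flicker_frequencies = c(30, 60, 120),
                              trials_per_frequency = 3,
                              seed = NULL) {
  tremor_waveform <- match.arg(tremor_waveform)
  check_number(sampling_interval, "sampling_interval", 0, strict = TRUE)
  check_number(duration, "duration", 0, strict = TRUE)
  check_number(target_separation, "target_separation", 0)
  check_number(fixation_mean_duration, "fixation_mean_duration", 0, strict = TRUE)
  check_number(saccade_duration, "saccade_duration", 0, strict = TRUE)
  check_number(microsaccade_rate, "microsaccade_rate", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(blink_rate, "blink_rate", 0)
  if (!is.numeric(flicker_frequencies) || length(flicker_frequencies) < 1 ||
      any(flicker_frequencies <= 0)) {
    stop("`flicker_frequencies` must be a non-empty vector of positive Hz values")
  }
  check_number(trials_per_frequency, "trials_per_frequency", 1)
  if (!(is.infinite(tremor_coherence) || tremor_coherence > 0)) {
    stop("`tremor_coherence` must be positive (or Inf for a coherent tone)")
  }
  structure(
    list(
      sampling_interval = sampling_interval,
      duration = duration,
      target_separation = target_separation,
      target_size = target_size,
      fixation_mean_duration = fixation_mean_duration,
      saccade_duration = saccade_duration,
      microsaccade_rate = microsaccade_rate,
      microsaccade_amp = microsaccade_amp,
      noise_sd = noise_sd,
      blink_rate = blink_rate,
      blink_duration = blink_duration,
      tremor_waveform = tremor_waveform,
      tremor_coherence = tremor_coherence,
      flicker_frequencies = flicker_frequencies,
      trials_per_frequency = trials_per_frequency,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic gaze configuration\n")
  cat(sprintf("  sampling: %g ms step, %g s duration\n",
              x$sampling_interval, x$duration))
  cat(sprintf("  targets: %g deg apart, %g deg wide\n",
              x$target_separation, x$target_size))
  cat(sprintf("  fixation/saccade: %g / %g ms; microsaccades %g /s; blinks %g /s\n",
              x$fixation_mean_duration, x$saccade_duration,
              x$microsaccade_rate, x$blink_rate))
  cat(sprintf("  tremor: %s waveform, coherence %g ms; noise sd %g deg\n",
              x$tremor_waveform, x$tremor_coherence, x$noise_sd))
  cat(sprintf("  task: flicker at {%s} Hz, %d trials each\n",
              paste(x$flicker_frequencies, collapse = ", "),
              as.integer(x$trials_per_frequency)))
  invisible(x)
}
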