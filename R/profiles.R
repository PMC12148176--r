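#' Construct a participant profile
#'
#' A profile collects the latent per-participant parameters of the generative
#' model: the microtremor frequency and amplitude, the intensity of ocular
#' drift, the latent critical flicker fusion threshold (CFFT) and the
#' steepness of the psychometric detection curve.
#'
#' @param participant_id Opaque identifier.
#' @param tremor_freq Microtremor oscillation frequency, Hz. Conventionally
#'   reported in the 70-150 Hz band.
#' @param tremor_amp Tremor amplitude, degrees of visual angle.
#' @param drift_diffusion Random-walk intensity of ocular drift, deg^2/s.
#' @param cfft Latent flicker-fusion threshold, Hz.
#' @param detection_slope Steepness of the logistic detection curve, 1/Hz.
#'
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, tremor_freq, tremor_amp = 0.01,
                                drift_diffusion = 0.001, cfft,
                                detection_slope = 0.5) {
  check_number(tremor_freq, "tremor_freq", 0, strict = TRUE)
  check_number(tremor_amp, "tremor_amp", 0)
  check_number(drift_diffusion, "drift_diffusion", 0)
  check_number(cfft, "cfft", 0, strict = TRUE)
  check_number(detection_slope, "detection_slope", 0)
  structure(
    list(participant_id = as.character(participant_id),
         tremor_freq = tremor_freq, tremor_amp = tremor_amp,
         drift_diffusion = drift_diffusion, cfft = cfft,
         detection_slope = detection_slope),
    class = "participant_profile"
  )
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "Participant %s: tremor %.1f Hz (amp %.4g deg), drift %.4g deg^2/s, CFFT %.1f Hz\n",
    x$participant_id, x$tremor_freq, x$tremor_amp, x$drift_diffusion, x$cfft))
  invisible(x)
}

#' Draw a cohort of participant profiles
#'
#' Tremor frequencies are drawn uniformly from `tremor_band` and the latent
#' CFFT is generated from the linear link
#' `cfft = slope * tremor_freq + intercept + e`, `e ~ N(0, noise_sd)`.
#' The link is the generative stand-in for the empirical association between
#' microtremor frequency and flicker-fusion threshold; its default maps the
#' 70-150 Hz tremor band onto CFFTs of 25-105 Hz, so roughly half of a
#' cohort resolves a 60 Hz flicker and essentially none resolves 120 Hz
#' other than by guessing.
#'
#' @param n_participants Number of profiles to draw (>= 1).
#' @param config A [simulation_config()]; supplies the default seed.
#' @param link_params List with elements `slope` (Hz per Hz), `intercept`
#'   (Hz) and `noise_sd` (Hz) of the tremor-to-CFFT link.
#' @param tremor_band Length-2 band (Hz) for the uniform tremor-frequency
#'   draw. A degenerate band `c(f, f)` pins every draw at `f`.
#' @param tremor_amp,drift_diffusion,detection_slope Shared profile
#'   parameters, see [participant_profile()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#'
#' @return A list of [participant_profile()] objects.
#' @examples
#' profs <- sample_profiles(3, simulation_config(), seed = 1)
#' sapply(profs, function(p) p$tremor_freq)
#' @export
sample_profiles <- function(n_participants,
                            config = simulation_config(),
                            link_params = list(slope = 1, intercept = -45,
                                               noise_sd = 0),
                            tremor_band = c(70, 150),
                            tremor_amp = 0.01,
                            drift_diffusion = 0.001,
                            detection_slope = 0.5,
                            seed = config$seed) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("`n_participants` must be a positive count")
  }
  n <- as.integer(n_participants)
  if (length(tremor_band) != 2 || any(tremor_band <= 0) ||
      tremor_band[1] > tremor_band[2]) {
    stop("`tremor_band` must be c(low, high) with 0 < low <= high")
  }
  slope <- link_params$slope %||% 1
  intercept <- link_params$intercept %||% -45
  link_noise <- link_params$noise_sd %||% 0
  if (!is.null(seed)) set.seed(seed)
  tf <- runif(n, tremor_band[1], tremor_band[2])
  cfft <- slope * tf + intercept + rnorm(n, 0, link_noise)
  if (any(cfft <= 0)) {
    warning("tremor-CFFT link produced non-positive thresholds; truncated at 1 Hz")
    cfft <- pmax(cfft, 1)
  }
  lapply(seq_len(n), function(i) {
    participant_profile(
      participant_id = sprintf("P%03d", i),
      tremor_freq = tf[i], tremor_amp = tremor_amp,
      drift_diffusion = drift_diffusion, cfft = cfft[i],
      detection_slope = detection_slope
    )
  })
}
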