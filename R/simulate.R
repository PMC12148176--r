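# Synthetic gaze recordings and simulated flicker-trial responses.

new_gaze_recording <- function(time_ms, x, y, label, participant_id,
                               sampling_interval) {
  rec <- data.frame(time_ms = time_ms, x = x, y = y, label = label,
                    participant_id = participant_id,
                    stringsAsFactors = FALSE)
  structure(rec, class = c("gaze_recording", "data.frame"),
            sampling_interval = sampling_interval)
}

gaze_labels <- c("FIX", "SACC", "BLINK")

validate_gaze_recording <- function(rec) {
  needed <- c("time_ms", "x", "y", "label", "participant_id")
  miss <- setdiff(needed, names(rec))
  if (length(miss)) {
    stop("gaze recording is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(rec$label %in% gaze_labels))
  if (length(bad)) {
    stop(sprintf("unknown event label '%s' at row %d", rec$label[bad[1]], bad[1]))
  }
  dt <- diff(rec$time_ms)
  if (length(dt)) {
    off <- which(abs(dt - dt[1]) > 1e-6 | dt <= 0)
    if (length(off)) {
      stop(sprintf("non-uniform time grid: step changes at row %d", off[1] + 1L))
    }
  }
  not_blink <- rec$label != "BLINK"
  bad_pos <- which(not_blink & (!is.finite(rec$x) | !is.finite(rec$y)))
  if (length(bad_pos)) {
    stop(sprintf("missing or non-finite position on non-BLINK row %d", bad_pos[1]))
  }
  invisible(rec)
}

#' Sampling interval of a gaze recording or velocity series
#' @param x A `gaze_recording` or `velocity_series`.
#' @return Sampling step in ms.
#' @export
sampling_interval <- function(x) attr(x, "sampling_interval")

#' @export
print.gaze_recording <- function(x, ...) {
  tab <- table(factor(x$label, levels = gaze_labels))
  cat(sprintf("Gaze recording: participant %s, %d samples @ %g ms (%.1f s)\n",
              x$participant_id[1], nrow(x), sampling_interval(x),
              nrow(x) * sampling_interval(x) / 1000))
  cat(sprintf("  labels: FIX %d (%.0f%%), SACC %d, BLINK %d\n",
              tab["FIX"], 100 * tab["FIX"] / nrow(x), tab["SACC"], tab["BLINK"]))
  invisible(x)
}

# One fixation span: drift random walk + tremor oscillation + white noise,
# around a fixed target, with optional intra-fixation microsaccade jumps.
fixation_span <- function(m, profile, config, centre) {
  dt <- config$sampling_interval
  dt_s <- dt / 1000
  step_sd <- sqrt(profile$drift_diffusion * dt_s)
  drift_x <- cumsum(rnorm(m, 0, step_sd))
  drift_y <- cumsum(rnorm(m, 0, step_sd))
  # stochastic-phase oscillator: deterministic advance + Gaussian jitter
  dphi <- rep(2 * pi * profile$tremor_freq * dt_s, m)
  if (is.finite(config$tremor_coherence)) {
    dphi <- dphi + rnorm(m, 0, sqrt(2 * dt / config$tremor_coherence))
  }
  theta <- runif(1, 0, 2 * pi) + cumsum(dphi)
  if (config$tremor_waveform == "circular") {
    trem_x <- profile$tremor_amp * cos(theta)
    trem_y <- profile$tremor_amp * sin(theta)
  } else {
    axis <- runif(1, 0, pi)
    osc <- profile$tremor_amp * cos(theta)
    trem_x <- osc * cos(axis)
    trem_y <- osc * sin(axis)
  }
  jump_x <- numeric(m)
  jump_y <- numeric(m)
  n_ms <- rpois(1, config$microsaccade_rate * m * dt_s)
  if (n_ms > 0) {
    at <- sample.int(m, min(n_ms, m))
    ang <- runif(length(at), 0, 2 * pi)
    amp <- abs(rnorm(length(at), config$microsaccade_amp,
                     config$microsaccade_amp / 3))
    jump_x[at] <- amp * cos(ang)
    jump_y[at] <- amp * sin(ang)
  }
  list(
    x = centre[1] + cumsum(jump_x) + drift_x + trem_x +
      rnorm(m, 0, config$noise_sd),
    y = centre[2] + cumsum(jump_y) + drift_y + trem_y +
      rnorm(m, 0, config$noise_sd)
  )
}

#' Simulate a gaze recording
#'
#' Generates a uniformly sampled gaze position trace alternating fixations on
#' two horizontally separated targets with smooth saccades between them.
#' During fixations the position is the sum of a drift random walk (variance
#' growing linearly in time at rate `drift_diffusion`), a small-amplitude
#' tremor oscillation at `tremor_freq`, occasional microsaccade jumps, and
#' white measurement noise. Every sample carries a ground-truth event label
#' (`FIX`, `SACC` or `BLINK`); blink spans have missing positions.
#'
#' @param profile A [participant_profile()].
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; with a fixed seed the recording is
#'   bit-reproducible.
#'
#' @return A `gaze_recording` data frame with columns `time_ms`, `x`, `y`
#'   (degrees), `label`, `participant_id`.
#' @examples
#' prof <- participant_profile("P1", tremor_freq = 100, cfft = 55)
#' rec <- simulate_recording(prof, simulation_config(duration = 2), seed = 1)
#' table(rec$label)
#' @export
simulate_recording <- function(profile, config = simulation_config(),
                               seed = config$seed) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(config, "sim_config"))
  dt <- config$sampling_interval
  total_ms <- config$duration * 1000
  n_real <- total_ms / dt
  if (abs(n_real - round(n_real)) > 1e-9) {
    stop("sampling interval does not divide the recording duration")
  }
  n <- as.integer(round(n_real))
  if (total_ms < min(100, config$fixation_mean_duration / 2)) {
    stop("recording duration is shorter than one fixation")
  }
  if (!is.null(seed)) set.seed(seed)

  x <- numeric(n)
  y <- numeric(n)
  label <- character(n)
  half_sep <- config$target_separation / 2
  side <- sample(c(-1, 1), 1)
  fix_min <- min(100, config$fixation_mean_duration / 2)
  fix_extra <- max(config$fixation_mean_duration - fix_min, 1e-6)
  i <- 1L
  while (i <= n) {
    centre <- c(side * half_sep, 0)
    fd <- fix_min + rexp(1, 1 / fix_extra)
    m <- min(max(1L, as.integer(round(fd / dt))), n - i + 1L)
    span <- fixation_span(m, profile, config, centre)
    idx <- i:(i + m - 1L)
    x[idx] <- span$x
    y[idx] <- span$y
    label[idx] <- "FIX"
    i <- i + m
    if (i > n) break
    side <- -side
    target <- c(side * half_sep, 0)
    m2 <- min(max(2L, as.integer(round(config$saccade_duration / dt))),
              n - i + 1L)
    ramp <- (1 - cos(pi * seq_len(m2) / m2)) / 2
    start <- c(x[i - 1L], y[i - 1L])
    idx <- i:(i + m2 - 1L)
    x[idx] <- start[1] + (target[1] - start[1]) * ramp +
      rnorm(m2, 0, config$noise_sd)
    y[idx] <- start[2] + (target[2] - start[2]) * ramp +
      rnorm(m2, 0, config$noise_sd)
    label[idx] <- "SACC"
    i <- i + m2
  }

  if (config$blink_rate > 0) {
    n_blinks <- rpois(1, config$blink_rate * config$duration)
    blink_len <- max(1L, as.integer(round(config$blink_duration / dt)))
    if (n_blinks > 0 && n > blink_len) {
      starts <- sample.int(n - blink_len, min(n_blinks, n - blink_len))
      for (s in starts) {
        idx <- s:(s + blink_len - 1L)
        x[idx] <- NA_real_
        y[idx] <- NA_real_
        label[idx] <- "BLINK"
      }
    }
  }

  new_gaze_recording(
    time_ms = (seq_len(n) - 1L) * dt, x = x, y = y, label = label,
    participant_id = profile$participant_id, sampling_interval = dt
  )
}

#' Simulate flicker-identification trial responses
#'
#' For every flicker frequency `f` in the configuration, the participant
#' answers `trials_per_frequency` two-target trials. A response is correct
#' with probability
#' `p(f) = 1/3 + (2/3) * logistic(detection_slope * (cfft - f))` -- chance
#' level 1/3 for the three answer options (left, right, "not sure") plus a
#' logistic detection term governed by the latent CFFT. Incorrect responses
#' pick uniformly between the wrong side and "not sure"; the flickering side
#' is randomized per trial.
#'
#' @inheritParams simulate_recording
#' @param seed Optional integer seed.
#' @return A data frame with columns `participant_id`, `flicker_freq`,
#'   `true_side`, `answer`.
#' @examples
#' prof <- participant_profile("P1", tremor_freq = 120, cfft = 75)
#' simulate_trials(prof, simulation_config(), seed = 1)
#' @export
simulate_trials <- function(profile, config = simulation_config(),
                            seed = config$seed) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(config, "sim_config"))
  if (length(config$flicker_frequencies) < 1) {
    stop("`flicker_frequencies` must be non-empty")
  }
  if (!is.null(seed)) set.seed(seed)
  chance <- 1 / 3
  freqs <- rep(config$flicker_frequencies,
               each = as.integer(config$trials_per_frequency))
  n <- length(freqs)
  true_side <- sample(c("left", "right"), n, replace = TRUE)
  p_correct <- chance + (1 - chance) *
    plogis(profile$detection_slope * (profile$cfft - freqs))
  correct <- runif(n) < p_correct
  wrong_side <- ifelse(true_side == "left", "right", "left")
  miss <- ifelse(runif(n) < 0.5, wrong_side, "not_sure")
  data.frame(
    participant_id = profile$participant_id,
    flicker_freq = freqs,
    true_side = true_side,
    answer = ifelse(correct, true_side, miss),
    stringsAsFactors = FALSE
  )
}
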