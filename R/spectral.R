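# Normalized power spectra of velocity components and the cumulative
# power spectrum C_X(f').

# Raw one-sided periodogram of a gap-free segment (mean-subtracted).
# Returns NULL when the segment carries no variance.
segment_periodogram <- function(s, dt, window = "none") {
  s <- s - mean(s)
  n <- length(s)
  if (window == "hann") {
    s <- s * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  p <- Mod(fft(s))^2
  half <- n %/% 2
  if (half < 1) return(NULL)
  fs <- 1000 / dt                      # Hz
  freq <- (1:half) * fs / n            # DC excluded
  power <- p[2:(half + 1)]
  tot <- sum(power)
  if (tot <= 0 || !is.finite(tot)) return(NULL)
  list(freq = freq, cum = cumsum(power) / tot, n = n)
}

#' Normalized power spectrum of a velocity component
#'
#' Computes `Ps = |F|^2` per contiguous valid segment of the chosen
#' component, after per-segment mean subtraction (the DC bin is excluded).
#' Segment spectra are combined on a common frequency grid as length-weighted
#' averages of their normalized cumulative curves, and the total spectral
#' mass over `(0, f_nyq]` is 1. With 1 ms sampling the Nyquist frequency is
#' 500 Hz.
#'
#' @param v A `velocity_series`.
#' @param component `"vx"` or `"vy"`.
#' @param min_segment Minimum segment length in samples; shorter valid runs
#'   are skipped.
#' @param grid_step Width of the common evaluation grid, Hz.
#' @param window `"none"` (default) or `"hann"` taper per segment.
#' @return A `spectrum_summary` data frame with columns `freq` (bin upper
#'   edges), `power` (normalized mass per bin) and `cumulative`.
#' @export
power_spectrum <- function(v, component = c("vx", "vy"), min_segment = 128,
                           grid_step = 0.5, window = c("none", "hann")) {
  stopifnot(inherits(v, "velocity_series"))
  component <- match.arg(component)
  window <- match.arg(window)
  dt <- sampling_interval(v)
  f_nyq <- 1000 / dt / 2
  vals <- v[[component]]
  runs <- true_runs(v$valid & is.finite(vals))
  lens <- if (nrow(runs)) runs[, "end"] - runs[, "start"] + 1L else integer(0)
  grid <- seq(grid_step, f_nyq, by = grid_step)
  cum_acc <- numeric(length(grid))
  w_acc <- 0
  n_seg <- 0L
  if (nrow(runs)) {
    for (r in seq_len(nrow(runs))) {
      if (lens[r] < min_segment) next
      seg <- vals[runs[r, "start"]:runs[r, "end"]]
      pg <- segment_periodogram(seg, dt, window)
      if (is.null(pg)) next
      cum_grid <- approx(x = c(0, pg$freq), y = c(0, pg$cum), xout = grid,
                         rule = 2)$y
      cum_acc <- cum_acc + pg$n * cum_grid
      w_acc <- w_acc + pg$n
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0L) {
    stop_tl(
      sprintf("no valid segment of length >= %d with spectral mass (%d segments seen)",
              min_segment, length(lens)),
      "tremorlink_insufficient_data", segment_lengths = lens
    )
  }
  cumulative <- cum_acc / w_acc
  cumulative[length(cumulative)] <- 1  # exact normalization at Nyquist
  cumulative <- cummax(cumulative)     # guard monotonicity against interp fuzz
  power <- diff(c(0, cumulative))
  structure(
    data.frame(freq = grid, power = power, cumulative = cumulative),
    class = c("spectrum_summary", "data.frame"),
    variable = paste(attr(v, "variant"), component, sep = "_"),
    participant_id = attr(v, "participant_id"),
    f_nyq = f_nyq, n_segments = n_seg, grid_step = grid_step
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  pk <- x$freq[which.max(x$power)]
  cat(sprintf("Spectrum of %s: %d segments, grid %g Hz up to %g Hz; peak bin %g Hz\n",
              attr(x, "variable"), attr(x, "n_segments"),
              attr(x, "grid_step"), attr(x, "f_nyq"), pk))
  invisible(x)
}

#' Cumulative power up to a frequency
#'
#' `C_X(f') `: the normalized spectral mass at or below the bin containing
#' `f'`. `C_X(0) = 0` (DC excluded) and `C_X(f_nyq) = 1`.
#'
#' @param summary A `spectrum_summary` from [power_spectrum()].
#' @param f_prime Query frequency in Hz, within `[0, f_nyq]`.
#' @return A value in `[0, 1]`.
#' @export
cumulative_spectrum <- function(summary, f_prime) {
  stopifnot(inherits(summary, "spectrum_summary"))
  f_nyq <- attr(summary, "f_nyq")
  if (!is.finite(f_prime) || f_prime < 0 || f_prime > f_nyq) {
    stop(sprintf("`f_prime` must lie in [0, %g] Hz", f_nyq))
  }
  if (f_prime == 0) return(0)
  step <- attr(summary, "grid_step")
  idx <- min(max(1L, as.integer(ceiling((f_prime - 1e-9) / step))),
             nrow(summary))
  summary$cumulative[idx]
}
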