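# Trial-response bookkeeping: detection criterion, group labels,
# chance-level probability, detection fractions and the exponential
# frequency-tolerance fit.

#' Label flicker detection per participant and frequency
#'
#' A participant is labeled as detecting flicker at frequency `f` when at
#' least `min_correct` of their `trials_per_frequency` trials at `f` name
#' the true flickering side. "Not sure" counts as incorrect. Participants
#' detecting at `f` form the group `P>f`; the remainder form `P<f`.
#'
#' @param trials Data frame of trial responses with columns
#'   `participant_id`, `flicker_freq`, `true_side`, `answer`.
#' @param trials_per_frequency Expected trials per participant per
#'   frequency; an incomplete protocol is an error naming the participant.
#' @param min_correct Detection criterion (default 2 of 3).
#' @return A `detection_labels` data frame with columns `participant_id`,
#'   `flicker_freq`, `n_correct`, `detected`.
#' @export
label_detection <- function(trials, trials_per_frequency = 3, min_correct = 2) {
  needed <- c("participant_id", "flicker_freq", "true_side", "answer")
  miss <- setdiff(needed, names(trials))
  if (length(miss)) stop("trials are missing column(s): ",
                         paste(miss, collapse = ", "))
  counts <- aggregate(answer ~ participant_id + flicker_freq, data = trials,
                      FUN = length)
  bad <- counts$participant_id[counts$answer != trials_per_frequency]
  n_per <- table(trials$participant_id)
  expected <- trials_per_frequency * length(unique(trials$flicker_freq))
  bad <- unique(c(as.character(bad), names(n_per)[n_per != expected]))
  if (length(bad)) {
    stop_tl(paste0("incomplete trial protocol for participant(s): ",
                   paste(sort(bad), collapse = ", ")),
            "tremorlink_incomplete_protocol", participants = bad)
  }
  trials$correct <- trials$answer == trials$true_side
  agg <- aggregate(correct ~ participant_id + flicker_freq, data = trials,
                   FUN = sum)
  names(agg)[names(agg) == "correct"] <- "n_correct"
  agg$detected <- agg$n_correct >= min_correct
  agg <- agg[order(agg$participant_id, agg$flicker_freq), ]
  rownames(agg) <- NULL
  structure(agg, class = c("detection_labels", "data.frame"),
            min_correct = min_correct,
            trials_per_frequency = trials_per_frequency)
}

#' Chance probability of passing the detection criterion by guessing
#'
#' Exact binomial tail `P(X >= min_successes)` for `X ~ Bin(n_trials,
#' p_success)`. With three trials, guessing probability 1/3 and a 2-of-3
#' criterion this is 7/27, the false-detection rate of a pure guesser.
#'
#' @param n_trials Number of trials.
#' @param p_success Per-trial success probability.
#' @param min_successes Criterion threshold.
#' @return The tail probability.
#' @examples
#' chance_probability(3, 1/3, 2) # 7/27
#' @export
chance_probability <- function(n_trials, p_success, min_successes) {
  check_number(n_trials, "n_trials", 0)
  check_number(min_successes, "min_successes", 0)
  if (!is.numeric(p_success) || p_success < 0 || p_success > 1) {
    stop("`p_success` must be a probability in [0, 1]")
  }
  if (min_successes > n_trials) stop("`min_successes` cannot exceed `n_trials`")
  pbinom(min_successes - 1, n_trials, p_success, lower.tail = FALSE)
}

#' Fraction of participants detecting each flicker frequency
#'
#' @param labels A `detection_labels` from [label_detection()].
#' @return A data frame with columns `flicker_freq` and `fraction`
#'   (the size of `P>f` relative to the cohort).
#' @export
detection_fractions <- function(labels) {
  stopifnot(inherits(labels, "detection_labels"))
  agg <- aggregate(detected ~ flicker_freq, data = labels, FUN = mean)
  names(agg)[names(agg) == "detected"] <- "fraction"
  agg[order(agg$flicker_freq), ]
}

#' Exponential frequency-tolerance fit
#'
#' Fits `P(f) = exp(-f / f_ell)` to detection fractions by unweighted least
#' squares, where `f_ell` is the frequency tolerance: the frequency scale
#' over which the fraction of participants still resolving flicker decays by
#' `1/e`. With a single point the closed form `-f / log(P)` is used.
#'
#' @param fractions Data frame with columns `flicker_freq` and `fraction`
#'   (as returned by [detection_fractions()]), fractions in `(0, 1]`.
#' @return A list with `f_ell` (Hz), `fitted`, `residuals`.
#' @examples
#' d <- data.frame(flicker_freq = c(30, 60, 120),
#'                 fraction = exp(-c(30, 60, 120) / 70))
#' fit_frequency_tolerance(d)$f_ell
#' @export
fit_frequency_tolerance <- function(fractions) {
  f <- fractions$flicker_freq
  p <- fractions$fraction
  if (is.null(f) || is.null(p)) {
    stop("`fractions` needs columns `flicker_freq` and `fraction`")
  }
  keep <- is.finite(f) & is.finite(p) & p > 0 & p <= 1 & f > 0
  f <- f[keep]
  p <- p[keep]
  if (length(f) < 1) stop("no usable (frequency, fraction) points")
  if (all(p == 1)) {
    stop("degenerate input: all fractions equal 1, no decay to fit")
  }
  if (length(f) == 1) {
    f_ell <- -f / log(p)
  } else {
    sse <- function(lfl) sum((p - exp(-f / exp(lfl)))^2)
    opt <- optimize(sse, interval = log(c(1e-2, 1e6)), tol = 1e-12)
    f_ell <- exp(opt$minimum)
  }
  fitted <- exp(-f / f_ell)
  list(f_ell = f_ell, fitted = fitted, residuals = p - fitted)
}
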