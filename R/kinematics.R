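# Gaze-velocity kinematics and the direction-reversal statistic.

new_velocity_series <- function(t, vx, vy, valid, variant, dt,
                                participant_id = NA_character_) {
  v <- data.frame(t = t, vx = vx, vy = vy, valid = valid)
  structure(v, class = c("velocity_series", "data.frame"),
            variant = variant, sampling_interval = dt,
            participant_id = participant_id)
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("Velocity series (%s): %d samples @ %g ms, %d valid (%.0f%%)\n",
              attr(x, "variant"), nrow(x), sampling_interval(x),
              sum(x$valid), 100 * mean(x$valid)))
  invisible(x)
}

#' Planar gaze velocity by forward differences
#'
#' `v(t) = (X(t+tau) - X(t)) / tau` over one sampling step `tau`. The result
#' has one sample fewer than the recording; samples whose endpoints include a
#' blink (missing position) are marked invalid.
#'
#' @param rec A `gaze_recording` with at least 2 samples.
#' @return A `velocity_series` (variant `"raw"`) with columns `t` (time of
#'   the leading endpoint, ms), `vx`, `vy` (deg/ms) and `valid`.
#' @export
compute_velocity <- function(rec) {
  validate_gaze_recording(rec)
  n <- nrow(rec)
  if (n < 2) stop("need at least 2 samples to differentiate")
  dt <- sampling_interval(rec)
  vx <- diff(rec$x) / dt
  vy <- diff(rec$y) / dt
  valid <- is.finite(vx) & is.finite(vy)
  vx[!valid] <- NA_real_
  vy[!valid] <- NA_real_
  new_velocity_series(rec$time_ms[-n], vx, vy, valid, "raw", dt,
                      rec$participant_id[1])
}

#' Normalized (unit) gaze velocity
#'
#' Divides each valid velocity sample by its Euclidean norm, keeping only
#' the direction of motion. Zero-norm samples have no direction and are
#' marked invalid.
#'
#' @param v A raw `velocity_series` from [compute_velocity()].
#' @return A `velocity_series` with variant `"unit"`; on valid samples
#'   `vx^2 + vy^2 = 1`.
#' @export
unit_velocity <- function(v) {
  stopifnot(inherits(v, "velocity_series"))
  if (!identical(attr(v, "variant"), "raw")) {
    stop("`unit_velocity()` expects the raw velocity variant")
  }
  nrm <- sqrt(v$vx^2 + v$vy^2)
  valid <- v$valid & is.finite(nrm) & nrm > 0
  vx <- ifelse(valid, v$vx / nrm, NA_real_)
  vy <- ifelse(valid, v$vy / nrm, NA_real_)
  new_velocity_series(v$t, vx, vy, valid, "unit", sampling_interval(v),
                      attr(v, "participant_id"))
}

#' Fixational gaze velocity
#'
#' Forward-difference velocity restricted to sample pairs whose both
#' endpoints are labeled `FIX`; all other samples are invalid. Microtremors
#' are fixational movements, so this variant removes the much faster
#' saccadic dynamics that would otherwise dominate.
#'
#' @param rec A labeled `gaze_recording`.
#' @return A `velocity_series` with variant `"fixational"`.
#' @export
fixational_velocity <- function(rec) {
  v <- compute_velocity(rec)
  n <- nrow(rec)
  fix_pair <- rec$label[-n] == "FIX" & rec$label[-1] == "FIX"
  valid <- v$valid & fix_pair
  if (!any(rec$label == "FIX")) {
    warning("recording has no FIX samples; fixational velocity is empty")
  }
  vx <- ifelse(valid, v$vx, NA_real_)
  vy <- ifelse(valid, v$vy, NA_real_)
  new_velocity_series(v$t, vx, vy, valid, "fixational", sampling_interval(v),
                      attr(v, "participant_id"))
}

#' Angle between two planar velocity vectors
#'
#' `phi = arccos( a . b / (|a| |b|) )` in `[0, pi]`, evaluated in the
#' numerically stable `atan2(|a x b|, a . b)` form so that identical and
#' antipodal vectors give exactly 0 and `pi` (the plain arccos of a clipped
#' cosine loses ~1e-8 near the ends).
#'
#' @param a,b Numeric length-2 vectors; both must be nonzero.
#' @return Angle in radians, in `[0, pi]`.
#' @examples
#' angle_between(c(1, 0), c(0, 1)) # pi/2
#' @export
angle_between <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  if (all(a == 0) || all(b == 0)) {
    stop_tl("angle undefined for a zero velocity vector", "tremorlink_zero_vector")
  }
  atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a * b))
}

#' Direction-reversal probability curve
#'
#' For each lag `tau`, the probability that the angle `phi(t, t + tau)`
#' between the velocity at `t` and the velocity at `t + tau` falls in the
#' near-reversal band `A_k = [(1 - 1/k) pi, pi]`. `A_k` has measure `1/k` of
#' the angle range, so for isotropic independent directions the probability
#' is `1/k`; a persistent oscillation pushes it towards 1 at lags near half
#' the oscillation period.
#'
#' @param v A `velocity_series` (typically the fixational variant).
#' @param k Integer interval-narrowness parameter(s), each >= 2.
#' @param tau_grid Lags in ms; must be multiples of the sampling step.
#' @param n_min Minimum number of valid sample pairs per lag; below it the
#'   probability is reported as missing.
#' @return A `reversal_curve` data frame with columns `k`, `tau`, `pr`,
#'   `n_pairs`.
#' @export
reversal_probability <- function(v, k = c(2, 4, 8), tau_grid = 1:10,
                                 n_min = 100) {
  stopifnot(inherits(v, "velocity_series"))
  if (any(k < 2) || any(k != round(k))) stop("`k` must be integers >= 2")
  dt <- sampling_interval(v)
  steps <- tau_grid / dt
  if (any(abs(steps - round(steps)) > 1e-9) || any(steps < 1)) {
    stop("every lag in `tau_grid` must be a positive multiple of the sampling step")
  }
  steps <- as.integer(round(steps))
  nrm <- sqrt(v$vx^2 + v$vy^2)
  ok <- v$valid & is.finite(nrm) & nrm > 0
  n <- nrow(v)
  out <- vector("list", length(steps))
  for (j in seq_along(steps)) {
    L <- steps[j]
    if (L >= n) {
      out[[j]] <- data.frame(k = k, tau = tau_grid[j], pr = NA_real_,
                             n_pairs = 0L)
      next
    }
    i1 <- seq_len(n - L)
    i2 <- i1 + L
    pair_ok <- ok[i1] & ok[i2]
    np <- sum(pair_ok)
    if (np == 0) {
      out[[j]] <- data.frame(k = k, tau = tau_grid[j], pr = NA_real_,
                             n_pairs = 0L)
      next
    }
    cosphi <- clip((v$vx[i1] * v$vx[i2] + v$vy[i1] * v$vy[i2]) /
                     (nrm[i1] * nrm[i2]))
    phi <- acos(cosphi[pair_ok])
    pr <- vapply(k, function(kk) mean(phi >= (1 - 1 / kk) * pi), numeric(1))
    if (np < n_min) pr[] <- NA_real_
    out[[j]] <- data.frame(k = k, tau = tau_grid[j], pr = pr, n_pairs = np)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$k, res$tau), ]
  rownames(res) <- NULL
  if (all(is.na(res$pr))) {
    message("reversal curve: no lag reached the minimum pair count")
  }
  structure(res, class = c("reversal_curve", "data.frame"),
            n_min = n_min, variant = attr(v, "variant"))
}

#' Peak of a reversal curve
#'
#' The lag at which the reversal probability is maximal, per value of `k`.
#' Ties are broken towards the smallest lag.
#'
#' @param curve A `reversal_curve` from [reversal_probability()].
#' @return A data frame with columns `k`, `tau_max` (ms), `pr_max`.
#' @export
reversal_peak <- function(curve) {
  stopifnot(inherits(curve, "reversal_curve"))
  if (all(is.na(curve$pr))) {
    stop_tl("reversal curve has no non-missing entries", "tremorlink_all_missing")
  }
  res <- lapply(split(curve, curve$k), function(d) {
    d <- d[order(d$tau), ]
    if (all(is.na(d$pr))) return(NULL)
    i <- which.max(d$pr)  # which.max takes the first, i.e. smallest lag
    data.frame(k = d$k[1], tau_max = d$tau[i], pr_max = d$pr[i])
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Convert a periodicity interval to a frequency interval
#'
#' A gaze-direction reversal every `T/2` ms corresponds to an oscillation of
#' period `T`; `f = 1000 / T` converts a period interval in ms to Hz, with
#' the bound order swapped.
#'
#' @param period_bounds Length-2 interval `c(lower, upper)` in ms, both > 0.
#' @return Length-2 frequency interval in Hz.
#' @examples
#' period_to_frequency(c(6, 8)) # 125 to 166.7 Hz
#' @export
period_to_frequency <- function(period_bounds) {
  stopifnot(length(period_bounds) == 2)
  if (any(period_bounds <= 0) || period_bounds[1] > period_bounds[2]) {
    stop("`period_bounds` must satisfy 0 < lower <= upper")
  }
  c(1000 / period_bounds[2], 1000 / period_bounds[1])
}
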