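# Empirical mode decomposition by sifting, Hilbert-Huang instantaneous
# amplitude/phase/frequency, and the distribution of instantaneous frequency.

# Indices of local maxima and minima. Plateaus are handled by carrying the
# last nonzero slope sign forward, so a flat top counts once.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) == 0) return(list(max = integer(0), min = integer(0)))
  pos <- seq_along(s)
  last <- cummax(ifelse(s != 0, pos, 0L))
  filled <- ifelse(last == 0, 0, s[pmax(last, 1L)])
  i <- seq_len(n - 2)
  list(
    max = which(filled[i] > 0 & s[i + 1] < 0) + 1L,
    min = which(filled[i] < 0 & s[i + 1] > 0) + 1L
  )
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# Cubic-spline envelope through extrema, with mirror extension of up to
# `nmir` extrema beyond each end to tame boundary swings.
spline_envelope <- function(idx, vals, n, nmir = 2) {
  xi <- idx
  yi <- vals
  m <- length(idx)
  take <- seq_len(min(nmir, m))
  xl <- 2 - idx[take]
  yl <- vals[take]
  take2 <- m - seq_len(min(nmir, m)) + 1L
  xr <- 2 * n - idx[take2]
  yr <- vals[take2]
  xx <- c(xl, xi, xr)
  yy <- c(yl, yi, yr)
  keep <- !duplicated(xx)
  xx <- xx[keep]
  yy <- yy[keep]
  o <- order(xx)
  method <- if (length(xx) >= 4) "fmm" else "natural"
  splinefun(xx[o], yy[o], method = method)(seq_len(n))
}

sift_once <- function(h) {
  ext <- local_extrema(h)
  if (length(ext$max) < 2 || length(ext$min) < 2) return(NULL)
  n <- length(h)
  upper <- spline_envelope(ext$max, h[ext$max], n)
  lower <- spline_envelope(ext$min, h[ext$min], n)
  h - (upper + lower) / 2
}

imf_criterion_ok <- function(h) {
  ext <- local_extrema(h)
  abs((length(ext$max) + length(ext$min)) - zero_crossings(h)) <= 1
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterative
#' sifting: cubic-spline envelopes are fit through the local maxima and
#' minima, and their mean is subtracted until the candidate satisfies the
#' IMF criterion (numbers of extrema and zero crossings differing by at most
#' one) and the normalized change between consecutive sifts falls below
#' `sd_tol`. IMFs come out ordered from high to low frequency; extraction
#' stops when the residual is monotone, has fewer than 3 extrema, or
#' `max_imfs` is reached. The input always equals the sum of the IMFs plus
#' the residual.
#'
#' @param signal Numeric vector (a gap-free valid segment), length >= 16,
#'   all finite.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param sd_tol Sifting stop threshold on
#'   `sum((h_prev - h)^2) / sum(h_prev^2)`.
#' @param max_sift Hard cap on sift iterations per IMF.
#' @return An `imf_set`: list with `imfs` (list of numeric vectors),
#'   `residual`, and `sift_report` (iterations and stop reason per IMF).
#' @examples
#' t <- 0:999
#' s <- sin(2 * pi * 150 * t / 1000) + sin(2 * pi * 20 * t / 1000)
#' d <- emd_decompose(s)
#' length(d$imfs)
#' @export
emd_decompose <- function(signal, max_imfs = 6, sd_tol = 0.2, max_sift = 100) {
  if (length(signal) < 16) stop("signal too short for EMD (need >= 16 samples)")
  if (any(!is.finite(signal))) stop("signal must be finite (use a valid segment)")
  r <- as.numeric(signal)
  imfs <- list()
  report <- list()
  repeat {
    if (length(imfs) >= max_imfs) break
    ext <- local_extrema(r)
    n_ext <- length(ext$max) + length(ext$min)
    if (n_ext < 3) break
    h <- r
    iters <- 0L
    reason <- "max_sift"
    while (iters < max_sift) {
      h1 <- sift_once(h)
      if (is.null(h1)) { reason <- "too_few_extrema"; break }
      iters <- iters + 1L
      sd_val <- sum((h - h1)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h1
      if (sd_val < sd_tol && imf_criterion_ok(h)) { reason <- "converged"; break }
    }
    imfs[[length(imfs) + 1L]] <- h
    report[[length(report) + 1L]] <- data.frame(
      imf = length(imfs), iterations = iters, reason = reason
    )
    r <- r - h
  }
  structure(
    list(imfs = imfs,
         residual = r,
         sift_report = if (length(report)) do.call(rbind, report) else
           data.frame(imf = integer(0), iterations = integer(0),
                      reason = character(0))),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("EMD: %d IMF(s) of length %d, residual range [%.3g, %.3g]\n",
              length(x$imfs),
              if (length(x$imfs)) length(x$imfs[[1]]) else length(x$residual),
              min(x$residual), max(x$residual)))
  invisible(x)
}

#' Hilbert-Huang analysis of an IMF
#'
#' Forms the analytic signal `Z(t) = S(t) + j H{S(t)}` via the discrete
#' (FFT-based) Hilbert transform and returns the instantaneous amplitude
#' `a(t) = |Z|`, the unwrapped instantaneous phase `theta(t) = arg(Z)`, and
#' the instantaneous frequency as the centered difference of the phase
#' divided by `2 pi dt` (Hz), with one-sided differences at the ends.
#' The first and last 5% of samples are flagged as boundary to suppress
#' Hilbert edge effects in downstream summaries.
#'
#' @param imf Numeric vector, typically one IMF from [emd_decompose()].
#' @param dt Sampling step in ms.
#' @return A `hilbert_analysis` list with `ia`, `ip`, `inst_freq` (Hz),
#'   `interior` (logical mask excluding the boundary) and `dt`.
#' @export
hilbert_analysis <- function(imf, dt = 1) {
  n <- length(imf)
  if (n < 4) stop("IMF too short for Hilbert analysis")
  if (all(imf == 0)) {
    stop_tl("all-zero IMF: instantaneous phase undefined", "tremorlink_zero_imf")
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(imf) * h, inverse = TRUE) / n
  ia <- Mod(z)
  ip <- unwrap_phase(Arg(z))
  dt_s <- dt / 1000
  inst <- numeric(n)
  inst[2:(n - 1)] <- (ip[3:n] - ip[1:(n - 2)]) / (2 * 2 * pi * dt_s)
  inst[1] <- (ip[2] - ip[1]) / (2 * pi * dt_s)
  inst[n] <- (ip[n] - ip[n - 1]) / (2 * pi * dt_s)
  edge <- max(1L, ceiling(0.05 * n))
  interior <- rep(TRUE, n)
  interior[seq_len(edge)] <- FALSE
  interior[(n - edge + 1L):n] <- FALSE
  structure(list(ia = ia, ip = ip, inst_freq = inst, interior = interior,
                 dt = dt),
            class = "hilbert_analysis")
}

#' Distribution of instantaneous frequency
#'
#' Histogram of interior instantaneous-frequency samples on `grid_step` Hz
#' bins over `[0, f_max]`, normalized to unit mass, with its running
#' cumulative. Negative IF samples (non-IMF-like local behavior) are
#' excluded and counted.
#'
#' @param h A `hilbert_analysis`, or a numeric vector of IF samples in Hz.
#' @param grid_step Bin width, Hz.
#' @param f_max Upper edge of the support, Hz (Nyquist for 1 kHz sampling).
#' @param min_samples Minimum number of usable interior samples.
#' @return An `if_distribution` data frame with columns `freq` (bin upper
#'   edges), `density` (per Hz) and `cdf`; attributes record the numbers of
#'   used, negative and above-range samples.
#' @export
if_distribution <- function(h, grid_step = 0.5, f_max = 500,
                            min_samples = 16) {
  vals <- if (inherits(h, "hilbert_analysis")) h$inst_freq[h$interior] else
    as.numeric(h)
  if (length(vals) < 1) {
    stop_tl("no interior instantaneous-frequency samples",
            "tremorlink_insufficient_data")
  }
  n_neg <- sum(vals < 0)
  n_over <- sum(vals > f_max)
  vals <- vals[vals >= 0 & vals <= f_max]
  if (length(vals) < min_samples) {
    stop_tl(sprintf("only %d usable IF samples (< %d)", length(vals),
                    min_samples),
            "tremorlink_insufficient_data")
  }
  nbins <- as.integer(round(f_max / grid_step))
  bin <- pmin(pmax(ceiling(vals / grid_step), 1L), nbins)
  counts <- tabulate(bin, nbins)
  mass <- counts / sum(counts)
  structure(
    data.frame(freq = seq_len(nbins) * grid_step,
               density = mass / grid_step,
               cdf = cumsum(mass)),
    class = c("if_distribution", "data.frame"),
    n_used = length(vals), n_negative = n_neg, n_above = n_over,
    grid_step = grid_step, f_max = f_max
  )
}

#' Interpolated cdf of instantaneous frequency
#'
#' Linear interpolation of the IF cdf between bin edges, anchored at
#' `cdf(0) = 0`.
#'
#' @param dist An `if_distribution`.
#' @param f Query frequency in Hz, within `[0, f_max]`.
#' @return A value in `[0, 1]`.
#' @export
cdf_at <- function(dist, f) {
  stopifnot(inherits(dist, "if_distribution"))
  f_max <- attr(dist, "f_max")
  if (!is.finite(f) || f < 0 || f > f_max) {
    stop(sprintf("`f` must lie in [0, %g] Hz", f_max))
  }
  approx(x = c(0, dist$freq), y = c(0, dist$cdf), xout = f)$y
}
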