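# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clip to [lo, hi]; used to absorb floating-point overshoot before acos().
clip <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# Unwrap a phase series so consecutive jumps never exceed pi in magnitude.
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

# Runs of TRUE in a logical vector, as a two-column matrix (start, end).
true_runs <- function(valid) {
  r <- rle(as.logical(valid))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# Signal an error carrying a condition class so callers can catch it.
stop_tl <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "tremorlink_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Stratified fold assignment: within each class, spread members evenly
# across k folds in random order.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- which(y == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    stop(sprintf("`%s` must be a single finite number %s %s", name,
                 if (strict) ">" else ">=", lower), call. = FALSE)
  }
  invisible(x)
}
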