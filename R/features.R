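# Per-participant feature curves: cumulative power spectra of the four
# velocity components and IF cdfs of their first IMFs, all on a common
# 0.5 Hz grid, plus assembly of the classifier feature matrix.

velocity_components <- function(rec) {
  raw <- compute_velocity(rec)
  list(unit = unit_velocity(raw), fix = fixational_velocity(rec))
}

# Pool interior instantaneous-frequency samples of IMFs S1..n_imfs across
# all valid segments of one velocity component.
pooled_if_samples <- function(v, component, n_imfs = 3, min_segment = 64,
                              max_imfs = 4) {
  vals <- v[[component]]
  runs <- true_runs(v$valid & is.finite(vals))
  pools <- replicate(n_imfs, numeric(0), simplify = FALSE)
  if (!nrow(runs)) return(pools)
  dt <- sampling_interval(v)
  for (r in seq_len(nrow(runs))) {
    len <- runs[r, "end"] - runs[r, "start"] + 1L
    if (len < min_segment) next
    seg <- vals[runs[r, "start"]:runs[r, "end"]]
    dec <- tryCatch(emd_decompose(seg, max_imfs = max_imfs),
                    error = function(e) NULL)
    if (is.null(dec)) next
    for (s in seq_len(min(n_imfs, length(dec$imfs)))) {
      ha <- tryCatch(hilbert_analysis(dec$imfs[[s]], dt = dt),
                     error = function(e) NULL)
      if (is.null(ha)) next
      pools[[s]] <- c(pools[[s]], ha$inst_freq[ha$interior])
    }
  }
  pools
}

#' Feature curves for one participant
#'
#' Computes, on a common frequency grid over `(0, 500]` Hz, the 16 feature
#' curves used to separate the detection groups: the cumulative power
#' spectrum `C_X(f')` of each velocity component
#' (`vx_unit`, `vy_unit`, `vx_fix`, `vy_fix`) and, when `include_emd` is
#' `TRUE`, the instantaneous-frequency cdf of IMFs S1-S3 of each component.
#' Families whose data are insufficient (e.g. no segment long enough) come
#' back as all-missing curves with a warning.
#'
#' @param rec A `gaze_recording`.
#' @param grid_step Common grid resolution, Hz.
#' @param min_segment Minimum segment length (samples) for spectra.
#' @param emd_min_segment Minimum segment length (samples) for EMD.
#' @param include_emd Compute the 12 EMD families as well as the 4 spectral
#'   ones.
#' @return A long data frame with columns `participant_id`, `family`,
#'   `freq`, `value`.
#' @export
feature_curves <- function(rec, grid_step = 0.5, min_segment = 128,
                           emd_min_segment = 64, include_emd = TRUE) {
  comps <- velocity_components(rec)
  id <- rec$participant_id[1]
  grid <- seq(grid_step, 500, by = grid_step)
  rows <- list()
  add <- function(fam, values) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant_id = id, family = fam, freq = grid, value = values,
      stringsAsFactors = FALSE)
  }
  for (variant in c("unit", "fix")) {
    v <- comps[[variant]]
    for (comp in c("vx", "vy")) {
      fam <- sprintf("C_%s_%s", comp, variant)
      spec <- tryCatch(
        power_spectrum(v, comp, min_segment = min_segment,
                       grid_step = grid_step),
        tremorlink_insufficient_data = function(e) NULL)
      if (is.null(spec)) {
        warning(sprintf("participant %s: insufficient data for %s", id, fam))
        add(fam, rep(NA_real_, length(grid)))
      } else {
        add(fam, spec$cumulative)
      }
      if (include_emd) {
        pools <- pooled_if_samples(v, comp, min_segment = emd_min_segment)
        for (s in seq_along(pools)) {
          fam_s <- sprintf("cdf_%s_%s_S%d", comp, variant, s)
          dist <- tryCatch(
            if_distribution(pools[[s]], grid_step = grid_step),
            tremorlink_insufficient_data = function(e) NULL)
          if (is.null(dist)) {
            warning(sprintf("participant %s: insufficient IF samples for %s",
                            id, fam_s))
            add(fam_s, rep(NA_real_, length(grid)))
          } else {
            add(fam_s, dist$cdf)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Feature curves for a cohort of recordings
#'
#' @param recordings A list of `gaze_recording` objects.
#' @param ... Passed to [feature_curves()].
#' @return Long data frame stacking every participant's curves.
#' @export
cohort_feature_curves <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, feature_curves, ...))
}

#' Assemble the classifier feature matrix
#'
#' One row per participant; each selected family contributes its curve value
#' at that family's separating frequency `f*` (taken from `results` at the
#' requested detection threshold). The binary outcome is detection at the
#' threshold; the positive class is "detected" (`P>f`).
#'
#' @param results An `f_star_result` covering the requested families and
#'   threshold.
#' @param curves Long feature-curve data frame (see [feature_curves()]).
#' @param labels A `detection_labels`.
#' @param threshold_freq Detection threshold defining the outcome, Hz.
#' @param families Feature families to include; defaults to the four
#'   velocity-component spectrum families.
#' @return A `feature_matrix` data frame with columns `participant_id`, one
#'   column per family, and `label` (factor, levels `not_detected`,
#'   `detected`).
#' @export
assemble_features <- function(results, curves, labels, threshold_freq,
                              families = spectrum_families()) {
  if (!length(families)) stop("`families` must be a non-empty subset")
  stopifnot(inherits(labels, "detection_labels"))
  lab <- labels[labels$flicker_freq == threshold_freq, ]
  if (!nrow(lab)) stop(sprintf("no labels at %g Hz", threshold_freq))
  ids <- sort(unique(lab$participant_id))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  f_star_map <- numeric(0)
  for (fam in families) {
    row <- results[results$family == fam &
                     results$threshold_freq == threshold_freq, ]
    if (nrow(row) != 1) {
      stop(sprintf("no f* result for family '%s' at %g Hz", fam,
                   threshold_freq))
    }
    fs <- row$f_star
    f_star_map[fam] <- fs
    d <- curves[curves$family == fam & abs(curves$freq - fs) < 1e-9, ]
    vals <- d$value[match(ids, d$participant_id)]
    if (any(!is.finite(vals))) {
      stop(sprintf("participant %s is missing a value for family '%s'",
                   ids[which(!is.finite(vals))[1]], fam))
    }
    out[[fam]] <- vals
  }
  out$label <- factor(ifelse(lab$detected[match(ids, lab$participant_id)],
                             "detected", "not_detected"),
                      levels = c("not_detected", "detected"))
  structure(out, class = c("feature_matrix", "data.frame"),
            threshold_freq = threshold_freq, f_star = f_star_map)
}
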