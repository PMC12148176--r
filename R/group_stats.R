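# Group-separation statistics: Mann-Whitney U test and the per-family
# scan for the frequency f* separating the P>f and P<f groups.

#' The 16 feature families, in reporting order
#'
#' Four cumulative-power-spectrum families (one per velocity component) and
#' twelve instantaneous-frequency cdf families (each component crossed with
#' the first three IMFs).
#' @return Character vector of family names.
#' @export
feature_families <- function() {
  comps <- c("vx_unit", "vy_unit", "vx_fix", "vy_fix")
  c(paste0("C_", comps),
    as.vector(t(outer(comps, 1:3, function(v, s) paste0("cdf_", v, "_S", s)))))
}

#' The four cumulative-spectrum feature families
#' @return Character vector (`C_vx_unit`, `C_vy_unit`, `C_vx_fix`,
#'   `C_vy_fix`), the candidate classifier inputs.
#' @export
spectrum_families <- function() paste0("C_", c("vx_unit", "vy_unit",
                                               "vx_fix", "vy_fix"))

#' Mann-Whitney U test
#'
#' Rank-sum test of the null hypothesis that two samples originate from the
#' same distribution. Uses the exact null distribution when the smaller
#' sample has at most 8 observations and there are no ties, and the normal
#' approximation with tie correction otherwise (midranks for ties, no
#' continuity correction, so identical samples give p = 1).
#'
#' @param a,b Numeric samples, both non-empty.
#' @return A list with `U` (the statistic for `a`) and `p` (two-sided).
#' @export
mwu_test <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    # fully tied: U is exactly its null mean, no evidence against the null
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

# Long feature curves -> participants x freq matrix for one family.
family_matrix <- function(curves, fam) {
  d <- curves[curves$family == fam, c("participant_id", "freq", "value")]
  if (!nrow(d)) return(NULL)
  freqs <- sort(unique(d$freq))
  ids <- sort(unique(d$participant_id))
  m <- matrix(NA_real_, length(ids), length(freqs),
              dimnames = list(ids, NULL))
  m[cbind(match(d$participant_id, ids), match(d$freq, freqs))] <- d$value
  list(m = m, freqs = freqs)
}

#' Find the group-separating frequency f*
#'
#' Scans the feature curves on their frequency grid and, per family, finds
#' the frequency `f*` where the detecting (`P>f`) and non-detecting (`P<f`)
#' groups differ the most. The default mode maximizes the absolute
#' difference in group means and reports the Mann-Whitney p-value there;
#' `mode = "min_p"` instead minimizes the MWU p-value over the grid. Ties go
#' to the smallest frequency. No multiple-testing correction is applied
#' across the grid or across families, so the reported p-value at `f*` is
#' selection-inflated; treat it as descriptive.
#'
#' @param curves Long data frame of per-participant feature curves with
#'   columns `participant_id`, `family`, `freq`, `value` (values in
#'   `[0, 1]`; all features are cumulative curves).
#' @param labels A `detection_labels` from [label_detection()].
#' @param threshold_freq Which detection frequency defines the groups
#'   (typically 60 or 120 Hz).
#' @param mode `"mean_diff"` (default) or `"min_p"`.
#' @param families Families to scan; defaults to every family present.
#' @return An `f_star_result` data frame with one row per family: `family`,
#'   `threshold_freq`, `f_star`, `mean_diff` (mean of `P>f` minus mean of
#'   `P<f` at `f*`), `p_value`, group means and sizes.
#' @export
find_f_star <- function(curves, labels, threshold_freq,
                        mode = c("mean_diff", "min_p"), families = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(labels, "detection_labels"))
  lab <- labels[labels$flicker_freq == threshold_freq, ]
  if (!nrow(lab)) {
    stop(sprintf("no detection labels at threshold %g Hz", threshold_freq))
  }
  families <- families %||% unique(curves$family)
  out <- vector("list", length(families))
  for (fi in seq_along(families)) {
    fam <- families[fi]
    fm <- family_matrix(curves, fam)
    if (is.null(fm)) stop(sprintf("no curves found for family '%s'", fam))
    ids <- rownames(fm$m)
    det <- lab$detected[match(ids, lab$participant_id)]
    usable <- !is.na(det) & apply(fm$m, 1, function(r) all(is.finite(r)))
    if (sum(usable & det) < 2 || sum(usable & !det) < 2) {
      stop(sprintf(
        "family '%s': need >= 2 participants per group at %g Hz (have %d / %d)",
        fam, threshold_freq, sum(usable & det), sum(usable & !det)))
    }
    m_gt <- fm$m[usable & det, , drop = FALSE]
    m_lt <- fm$m[usable & !det, , drop = FALSE]
    mu_gt <- colMeans(m_gt)
    mu_lt <- colMeans(m_lt)
    if (mode == "mean_diff") {
      i <- which.max(abs(mu_gt - mu_lt))
      test <- mwu_test(m_gt[, i], m_lt[, i])
      p_star <- test$p
    } else {
      pvals <- vapply(seq_along(fm$freqs), function(j) {
        mwu_test(m_gt[, j], m_lt[, j])$p
      }, numeric(1))
      i <- which.min(pvals)
      p_star <- pvals[i]
    }
    out[[fi]] <- data.frame(
      family = fam, threshold_freq = threshold_freq, f_star = fm$freqs[i],
      mean_diff = mu_gt[i] - mu_lt[i], p_value = p_star,
      mean_gt = mu_gt[i], mean_lt = mu_lt[i],
      n_gt = nrow(m_gt), n_lt = nrow(m_lt),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("f_star_result", "data.frame"), mode = mode)
}

#' Summary table of group separation across all families and thresholds
#'
#' Stacks `f_star_result` rows into the canonical 16-family by 2-threshold
#' layout (family, threshold, f*, p-value, mean difference), erroring on
#' missing family/threshold combinations.
#'
#' @param results One or more `f_star_result` objects (or a list of them).
#' @param families Expected family order; defaults to [feature_families()].
#' @param thresholds Expected thresholds; defaults to the ones present.
#' @return A data frame ordered by family then threshold.
#' @export
summarize_separation <- function(results, families = feature_families(),
                                 thresholds = NULL) {
  if (inherits(results, "f_star_result")) results <- list(results)
  if (!length(results)) stop("no f* results supplied")
  tab <- do.call(rbind, lapply(results, as.data.frame))
  thresholds <- thresholds %||% sort(unique(tab$threshold_freq))
  want <- expand.grid(family = families, threshold_freq = thresholds,
                      stringsAsFactors = FALSE)
  key_have <- paste(tab$family, tab$threshold_freq)
  key_want <- paste(want$family, want$threshold_freq)
  miss <- setdiff(key_want, key_have)
  if (length(miss)) {
    stop("missing f* results for: ", paste(miss, collapse = "; "))
  }
  tab <- tab[match(key_want, key_have),
             c("family", "threshold_freq", "f_star", "p_value", "mean_diff")]
  rownames(tab) <- NULL
  tab
}
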