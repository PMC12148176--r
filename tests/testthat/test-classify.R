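# Confusion metrics, SMOTE, and the nested-CV decision-tree evaluation.

make_feature_matrix <- function(x, labels, ids = sprintf("P%02d", seq_len(nrow(x)))) {
  d <- cbind(data.frame(participant_id = ids), as.data.frame(x))
  d$label <- factor(ifelse(labels, "detected", "not_detected"),
                    levels = c("not_detected", "detected"))
  structure(d, class = c("feature_matrix", "data.frame"),
            threshold_freq = 60, f_star = numeric(0))
}

test_that("metrics follow the confusion-count formulas", {
  m <- metrics_from_counts(30, 5, 39, 7)
  expect_equal(round(m$accuracy, 2), 0.85)
  expect_equal(round(m$sensitivity, 2), 0.81)
  expect_equal(round(m$specificity, 2), 0.89)
  expect_equal(round(m$precision, 2), 0.86)
  expect_equal(m$accuracy, 69 / 81)

  m <- metrics_from_counts(10, 0, 10, 0)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "precision")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1))

  # undefined rates are missing, not zero
  m <- metrics_from_counts(0, 0, 10, 0)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_equal(m$specificity, 1)
  expect_error(metrics_from_counts(-1, 0, 0, 0), "non-negative")
})

test_that("SMOTE balances the classes by interpolating minority points", {
  set.seed(20)
  x <- data.frame(a = c(rnorm(20), rnorm(6, 5)), b = c(rnorm(20), rnorm(6, 5)))
  y <- factor(rep(c("not_detected", "detected"), c(20, 6)),
              levels = c("not_detected", "detected"))
  bal <- smote_balance(x, y)
  expect_equal(as.vector(table(bal$y)), c(20, 20))
  # synthetic points lie within the minority bounding box
  new_pts <- bal$x[-(1:26), ]
  expect_true(all(new_pts$a >= min(x$a[21:26]) - 1e-9 &
                    new_pts$a <= max(x$a[21:26]) + 1e-9))
  # already balanced input passes through untouched
  bal2 <- smote_balance(x[1:12, ], factor(rep(c("x", "y"), 6)))
  expect_equal(nrow(bal2$x), 12)
  # singleton minority is replicated
  bal3 <- smote_balance(x[1:5, ], factor(c("x", "x", "x", "x", "y"),
                                         levels = c("x", "y")))
  expect_equal(as.vector(table(bal3$y)), c(4, 4))
})

test_that("a separable feature is classified perfectly", {
  n <- 40
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  fm <- make_feature_matrix(data.frame(C_vy_unit = ifelse(lab, 0.9, 0.1)), lab)
  rep <- train_eval(fm, seed = 1,
                    grid = expand.grid(maxdepth = 2, minsplit = 2,
                                       minbucket = 1))
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, n)
})

test_that("shuffled labels give chance accuracy and untouched test folds", {
  set.seed(21)
  n <- 60
  lab <- sample(rep(c(TRUE, FALSE), each = n / 2))  # balanced cohort
  x <- data.frame(C_vx_unit = runif(n), C_vy_unit = runif(n))
  fm <- make_feature_matrix(x, lab)
  grid <- expand.grid(maxdepth = c(2, 4), minsplit = c(2, 8),
                      minbucket = c(1, 4))
  rep <- train_eval(fm, seed = 2, grid = grid)
  maj <- max(table(fm$label)) / n
  se <- sqrt(maj * (1 - maj) / n)
  expect_lt(abs(rep$accuracy - maj), 3 * se)
  # pooled counts conserve the cohort and test folds keep the class ratio
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, n)
  ratios <- t(vapply(rep$folds, function(f) f$test_class_ratio, numeric(2)))
  expect_equal(colSums(ratios), c(sum(!lab), sum(lab)))

  # bit-reproducible under a fixed seed
  rep2 <- train_eval(fm, seed = 2, grid = grid)
  expect_identical(rep, rep2)

  expect_error(train_eval(make_feature_matrix(x, rep(TRUE, n)), seed = 1),
               "2 participants per class")
})

test_that("assembled features evaluate curves at f* and stay in [0, 1]", {
  set.seed(22)
  ids <- sprintf("P%02d", 1:10)
  det <- rep(c(TRUE, FALSE), 5)
  freqs <- seq(50, 500, by = 50)
  curves <- do.call(rbind, lapply(spectrum_families(), function(fam) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      v <- cumsum(runif(length(freqs)))
      data.frame(participant_id = ids[i], family = fam, freq = freqs,
                 value = v / max(v), stringsAsFactors = FALSE)
    }))
  }))
  labels <- structure(
    data.frame(participant_id = ids, flicker_freq = 60,
               n_correct = ifelse(det, 2L, 0L), detected = det),
    class = c("detection_labels", "data.frame"),
    min_correct = 2, trials_per_frequency = 3)
  res <- find_f_star(curves, labels, 60, families = spectrum_families())
  fm <- assemble_features(res, curves, labels, 60)
  expect_equal(nrow(fm), 10)
  expect_setequal(setdiff(names(fm), c("participant_id", "label")),
                  spectrum_families())
  vals <- as.matrix(fm[, spectrum_families()])
  expect_true(all(vals >= 0 & vals <= 1))
  # single-family assembly
  fm1 <- assemble_features(res, curves, labels, 60, families = "C_vy_unit")
  expect_equal(setdiff(names(fm1), c("participant_id", "label")), "C_vy_unit")
  expect_error(assemble_features(res, curves, labels, 60, families = character(0)),
               "non-empty")
})
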