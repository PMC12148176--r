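# Mann-Whitney U against enumeration, and the f* separation scan.

make_curves <- function(values, freqs, ids = rownames(values),
                        family = "C_vy_unit") {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(participant_id = ids[i], family = family, freq = freqs,
               value = values[i, ], stringsAsFactors = FALSE)
  }))
}

make_labels <- function(ids, detected, freq = 60) {
  structure(
    data.frame(participant_id = ids, flicker_freq = freq,
               n_correct = ifelse(detected, 3L, 0L), detected = detected),
    class = c("detection_labels", "data.frame"),
    min_correct = 2, trials_per_frequency = 3
  )
}

test_that("mwu_test matches hand counts and the enumeration oracle", {
  r <- mwu_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)

  # identical multisets: full overlap, p = 1 under midranks
  expect_equal(mwu_test(c(1, 2, 2, 5), c(1, 2, 2, 5))$p, 1)

  # complete separation: the smallest attainable exact two-sided p
  r <- mwu_test(1:5, 1:5 + 100)
  expect_equal(r$p, 2 / choose(10, 5))

  # enumeration oracle on random untied samples with n_a + n_b <= 10
  set.seed(16)
  for (i in 1:12) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    x <- sample(seq(0, 1, length.out = 50), na + nb)  # distinct values
    a <- x[seq_len(na)]
    b <- x[-seq_len(na)]
    expect_equal(mwu_test(a, b)$p, enum_mwu_p(a, b), tolerance = 1e-12)
  }
  expect_error(mwu_test(numeric(0), 1:3), "non-empty")
})

test_that("f* lands where the groups differ", {
  ids <- sprintf("P%02d", 1:12)
  det <- rep(c(TRUE, FALSE), each = 6)
  freqs <- seq(10, 100, by = 10)
  # identical curves except one bin where the groups split cleanly
  base <- matrix(0.5, 12, 10, dimnames = list(ids, NULL))
  base[det, 4] <- 0.9
  base[!det, 4] <- 0.1
  res <- find_f_star(make_curves(base, freqs), make_labels(ids, det), 60)
  expect_equal(res$f_star, 40)
  expect_equal(res$mean_diff, 0.8)

  # step-function cdfs stepping at 100 vs 150 Hz separate fully in between
  freqs <- seq(25, 250, by = 25)
  step_at <- ifelse(det, 150, 100)
  m <- outer(step_at, freqs, function(s, f) as.numeric(f >= s))
  rownames(m) <- ids
  res <- find_f_star(make_curves(m, freqs), make_labels(ids, det), 60)
  expect_gte(res$f_star, 100)
  expect_lte(res$f_star, 150)
  expect_equal(abs(res$mean_diff), 1)

  # invariant to participant ordering
  curves <- make_curves(m, freqs)
  set.seed(17)
  res2 <- find_f_star(curves[sample(nrow(curves)), ], make_labels(ids, det), 60)
  expect_equal(res2, res)

  # identical curves across everyone: no separation anywhere
  same <- matrix(rep(seq(0.1, 1, length.out = 10), each = 12), 12, 10,
                 dimnames = list(ids, NULL))
  res3 <- find_f_star(make_curves(same, freqs), make_labels(ids, det), 60)
  expect_equal(res3$mean_diff, 0)
  expect_equal(res3$p_value, 1)

  expect_error(
    find_f_star(make_curves(m, freqs),
                make_labels(ids, rep(TRUE, 12)), 60),
    ">= 2 participants")
})

test_that("permuted labels still yield small selected p-values (selection bias)", {
  # with labels independent of curves, the p-value AT the selected f* is
  # selection-inflated towards small values; it is not uniform
  set.seed(18)
  ids <- sprintf("P%02d", 1:20)
  freqs <- seq(5, 500, by = 5)
  m <- matrix(runif(20 * length(freqs)), 20, dimnames = list(ids, NULL))
  m <- t(apply(m, 1, function(r) cumsum(r) / sum(r)))  # random cdf curves
  curves <- make_curves(m, freqs)
  ps <- replicate(40, {
    det <- sample(rep(c(TRUE, FALSE), each = 10))
    find_f_star(curves, make_labels(ids, det), 60)$p_value
  })
  expect_lt(mean(ps), 0.5)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("the separation table has the full 16 x 2 layout in canonical order", {
  set.seed(19)
  ids <- sprintf("P%02d", 1:10)
  freqs <- seq(50, 500, by = 50)
  curves <- do.call(rbind, lapply(feature_families(), function(fam) {
    m <- matrix(runif(10 * length(freqs)), 10, dimnames = list(ids, NULL))
    m <- t(apply(m, 1, function(r) cumsum(r) / sum(r)))
    make_curves(m, freqs, family = fam)
  }))
  labels60 <- make_labels(ids, rep(c(TRUE, FALSE), 5), 60)
  labels120 <- make_labels(ids, rep(c(TRUE, FALSE), each = 5), 120)
  res <- list(find_f_star(curves, labels60, 60),
              find_f_star(curves, labels120, 120))
  tab <- summarize_separation(res)
  expect_equal(nrow(tab), 32)
  expect_equal(unique(tab$family), feature_families())
  expect_error(summarize_separation(res[[1]], thresholds = c(60, 120)),
               "missing f\\* results")
  expect_error(summarize_separation(list()), "no f\\* results")
})
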