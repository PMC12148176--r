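# Velocities, angles, and the direction-reversal statistic.

make_rec <- function(x, y, label = rep("FIX", length(x)), dt = 1) {
  tremorlink:::new_gaze_recording(
    time_ms = (seq_along(x) - 1) * dt, x = x, y = y, label = label,
    participant_id = "T", sampling_interval = dt
  )
}

test_that("forward-difference velocity handles constant, linear and smooth motion", {
  n <- 100
  v <- compute_velocity(make_rec(rep(1, n), rep(2, n)))
  expect_equal(v$vx, rep(0, n - 1))
  expect_equal(v$vy, rep(0, n - 1))

  t <- 0:(n - 1)
  v <- compute_velocity(make_rec(t, 0 * t))
  expect_equal(v$vx, rep(1, n - 1))

  # sinusoid: forward difference matches the half-step-shifted derivative
  # to second order in the sampling step
  t <- 0:999
  x <- sin(2 * pi * 0.05 * t)
  v <- compute_velocity(make_rec(x, 0 * x))
  truth <- 2 * pi * 0.05 * cos(2 * pi * 0.05 * (t[-1000] + 0.5))
  expect_lt(max(abs(v$vx - truth)), 2e-3)

  expect_error(compute_velocity(make_rec(1, 1)), "at least 2")
})

test_that("unit velocity normalizes valid samples and masks zero-norm ones", {
  rec <- make_rec(c(0, 3, 3, 4), c(0, 4, 4, 6))
  u <- unit_velocity(compute_velocity(rec))
  expect_equal(u$vx[1], 0.6)
  expect_equal(u$vy[1], 0.8)
  expect_false(u$valid[2])  # zero displacement has no direction
  expect_true(is.na(u$vx[2]))

  set.seed(1)
  rec <- make_rec(cumsum(rnorm(500)), cumsum(rnorm(500)))
  u <- unit_velocity(compute_velocity(rec))
  nrm <- sqrt(u$vx[u$valid]^2 + u$vy[u$valid]^2)
  expect_true(all(abs(nrm - 1) < 1e-9))
})

test_that("fixational velocity keeps exactly the FIX-FIX endpoint pairs", {
  n <- 10
  x <- as.numeric(1:n)
  all_fix <- fixational_velocity(make_rec(x, x))
  raw <- compute_velocity(make_rec(x, x))
  expect_equal(all_fix$vx, raw$vx)

  all_sacc <- suppressWarnings(fixational_velocity(make_rec(x, x, rep("SACC", n))))
  expect_equal(sum(all_sacc$valid), 0)

  # enumerated toy: FIX at odd positions only -> no adjacent FIX pair
  lab <- rep(c("FIX", "SACC"), 5)
  v <- fixational_velocity(make_rec(x, x, lab))
  expect_equal(sum(v$valid), 0)
  # two FIX runs of length 3 -> 2 valid pairs each
  lab <- c("FIX", "FIX", "FIX", "SACC", "SACC", "FIX", "FIX", "FIX", "SACC", "SACC")
  v <- fixational_velocity(make_rec(x, x, lab))
  expect_equal(which(v$valid), c(1, 2, 6, 7))

  expect_warning(fixational_velocity(make_rec(x, x, rep("SACC", n))), "no FIX")
})

test_that("angle_between matches geometry and is scale/order invariant", {
  expect_equal(angle_between(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(angle_between(c(1, 0), c(-1, 0)), pi)
  expect_equal(angle_between(c(1, 1), c(1, 0)), pi / 4)
  expect_error(angle_between(c(0, 0), c(1, 0)), "zero velocity")

  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(2)
    b <- rnorm(2)
    s <- runif(1, 0.1, 50)
    expect_equal(angle_between(a, b), angle_between(b, a))
    expect_equal(angle_between(a, b), angle_between(s * a, b), tolerance = 1e-12)
    expect_identical(angle_between(a, a), 0)
    expect_identical(angle_between(a, -a), pi)
  }
})

test_that("reversal probability matches the isotropic and rotating oracles", {
  # constant direction: never reverses
  v <- velocity_from_angles(rep(0.3, 500))
  cur <- reversal_probability(v, k = c(2, 4, 8), tau_grid = 1:5)
  expect_true(all(cur$pr == 0))

  # independent isotropic directions: phi uniform on [0, pi], so
  # Pr(A_k) = |A_k| / pi = 1/k
  set.seed(7)
  v <- velocity_from_angles(runif(20000, 0, 2 * pi))
  cur <- reversal_probability(v, k = c(2, 4, 8), tau_grid = c(1, 3))
  for (kk in c(2, 4, 8)) {
    pr <- cur$pr[cur$k == kk]
    se <- sqrt((1 / kk) * (1 - 1 / kk) / 20000)
    expect_true(all(abs(pr - 1 / kk) < 3 * se))
  }

  # deterministic rotation at 150 Hz: angle at lag tau is
  # fold(2 pi 0.15 tau); in A_8 exactly when it is >= 7 pi / 8
  v <- velocity_from_angles((0:5999) * 2 * pi * 0.15)
  cur <- reversal_probability(v, k = 8, tau_grid = 1:10)
  ang <- (1:10) * 2 * pi * 0.15 %% (2 * pi)
  fold <- pmin(ang %% (2 * pi), 2 * pi - ang %% (2 * pi))
  expect_equal(cur$pr, as.numeric(fold >= 7 * pi / 8))
  # a perfectly coherent rotation reverses at 3 ms (half period 3.33) and
  # again at 10 ms (1.5 periods); no other integer lag reaches A_8
  expect_equal(which(cur$pr == 1), c(3L, 10L))
})

test_that("reversal curves are k-nested, scale-invariant and n_min-guarded", {
  set.seed(8)
  theta <- cumsum(rnorm(4000, 0.5, 0.3))
  v <- velocity_from_angles(theta)
  cur <- reversal_probability(v, k = c(2, 4, 8), tau_grid = 1:6)
  # A_k nested: pr non-increasing in k at fixed tau
  wide <- split(cur$pr, cur$tau)
  for (p in wide) expect_true(all(diff(p) <= 1e-12))

  # angles ignore speed: scaling the raw velocity leaves pr unchanged
  raw <- tremorlink:::new_velocity_series(
    v$t, 3.7 * v$vx, 3.7 * v$vy, v$valid, "raw", 1)
  cur2 <- reversal_probability(raw, k = c(2, 4, 8), tau_grid = 1:6)
  expect_equal(cur2$pr, cur$pr)

  # too few pairs -> missing probabilities
  small <- velocity_from_angles(runif(30, 0, 2 * pi))
  cur3 <- reversal_probability(small, k = 2, tau_grid = 1:2, n_min = 100)
  expect_true(all(is.na(cur3$pr)))
  expect_error(reversal_peak(cur3), "no non-missing")
  expect_error(reversal_probability(v, k = 1, tau_grid = 1), "k")
  expect_error(reversal_probability(v, k = 2, tau_grid = 0.5), "multiple")
})

test_that("reversal peak takes the argmax with ties to the smallest lag", {
  mk <- function(pr, tau = seq_along(pr)) {
    structure(data.frame(k = 4, tau = tau, pr = pr, n_pairs = 1000),
              class = c("reversal_curve", "data.frame"))
  }
  expect_equal(reversal_peak(mk(c(0.1, 0.5, 0.9, 0.4)))$tau_max, 3)
  expect_equal(reversal_peak(mk(c(0.1, 0.5, 0.9, 0.9)))$tau_max, 3)
})

test_that("period intervals convert to frequency intervals", {
  expect_equal(period_to_frequency(c(6, 8)), c(125, 1000 / 6))
  expect_equal(period_to_frequency(c(5, 7)), c(1000 / 7, 200))
  expect_equal(period_to_frequency(c(10, 10)), c(100, 100))
  expect_error(period_to_frequency(c(0, 5)), "0 <")
})
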