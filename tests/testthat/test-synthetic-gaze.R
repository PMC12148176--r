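# The synthetic gaze generator: profiles, recordings, trials.

test_that("profile sampling respects the band, the link and the seed", {
  cfg <- simulation_config()
  # degenerate band pins the draw; identity link carries it to the CFFT
  p <- sample_profiles(1, cfg, link_params = list(slope = 1, intercept = 0,
                                                  noise_sd = 0),
                       tremor_band = c(150, 150), seed = 5)[[1]]
  expect_equal(p$tremor_freq, 150)
  expect_equal(p$cfft, 150)

  # draws stay inside the configured band
  profs <- sample_profiles(200, cfg, tremor_band = c(70, 150), seed = 2)
  tf <- vapply(profs, function(x) x$tremor_freq, numeric(1))
  expect_true(all(tf >= 70 & tf <= 150))

  # uniform band mean: within 3 standard errors of (70+150)/2
  profs <- sample_profiles(1000, cfg, tremor_band = c(70, 150), seed = 3)
  tf <- vapply(profs, function(x) x$tremor_freq, numeric(1))
  se <- (80 / sqrt(12)) / sqrt(1000)
  expect_lt(abs(mean(tf) - 110), 3 * se)

  # reproducible under a fixed seed
  a <- sample_profiles(5, cfg, seed = 11)
  b <- sample_profiles(5, cfg, seed = 11)
  expect_identical(a, b)

  expect_error(sample_profiles(0, cfg), "positive count")
  expect_error(sample_profiles(3, cfg, tremor_band = c(150, 70)), "band")
})

test_that("recordings are reproducible and labels partition the samples", {
  prof <- participant_profile("P1", tremor_freq = 100, cfft = 55)
  cfg <- simulation_config(duration = 5)
  a <- simulate_recording(prof, cfg, seed = 4)
  b <- simulate_recording(prof, cfg, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$label %in% c("FIX", "SACC", "BLINK")))
  expect_equal(nrow(a), 5000)
  expect_equal(diff(a$time_ms), rep(1, 4999))
  # positions missing exactly on blink samples
  expect_true(all(is.finite(a$x[a$label != "BLINK"])))
  expect_true(all(is.na(a$x[a$label == "BLINK"])))
  # fixation occupies the majority of the recording under defaults
  expect_gt(mean(a$label == "FIX"), 0.5)
})

test_that("noise-free tremor is exactly periodic within fixations", {
  # 125 Hz -> 8 ms period, an integer number of 1 ms samples
  prof <- participant_profile("P1", tremor_freq = 125, tremor_amp = 0.02,
                              drift_diffusion = 0, cfft = 60)
  cfg <- simulation_config(duration = 2, microsaccade_rate = 0, noise_sd = 0,
                           blink_rate = 0, tremor_coherence = Inf)
  rec <- simulate_recording(prof, cfg, seed = 9)
  runs <- tremorlink:::true_runs(rec$label == "FIX")
  r <- runs[which.max(runs[, "end"] - runs[, "start"]), ]
  x <- rec$x[r["start"]:r["end"]]
  expect_equal(x[-(1:8)], x[seq_len(length(x) - 8)], tolerance = 1e-12)

  # turning every fixational process off leaves piecewise-constant positions
  prof0 <- participant_profile("P1", tremor_freq = 125, tremor_amp = 0,
                               drift_diffusion = 0, cfft = 60)
  rec0 <- simulate_recording(prof0, cfg, seed = 9)
  x0 <- rec0$x[r["start"]:r["end"]]
  expect_equal(diff(x0), rep(0, length(x0) - 1))
})

test_that("fixational spectrum peaks at the generated tremor frequency", {
  rec <- tone_recording(150, duration = 4)
  v <- fixational_velocity(rec)
  sp <- power_spectrum(v, "vx")
  peak <- sp$freq[which.max(sp$power)]
  expect_lt(abs(peak - 150), 1)  # within a couple of grid bins
})

test_that("drift displacement variance grows linearly in lag", {
  prof <- participant_profile("P1", tremor_freq = 100, tremor_amp = 0,
                              drift_diffusion = 0.01, cfft = 60)
  cfg <- simulation_config(duration = 60, fixation_mean_duration = 1e6,
                           saccade_duration = 10, microsaccade_rate = 0,
                           noise_sd = 0, blink_rate = 0)
  rec <- simulate_recording(prof, cfg, seed = 21)
  var_at <- function(L) {
    idx <- seq(1, nrow(rec) - L, by = L)  # non-overlapping increments
    var(rec$x[idx + L] - rec$x[idx])
  }
  ratio <- var_at(200) / var_at(50)
  expect_gt(ratio, 2.6)   # 4 +/- Monte-Carlo slack
  expect_lt(ratio, 5.8)
  # absolute level: Var over L ms = D * L / 1000
  expect_equal(var_at(100), 0.01 * 100 / 1000, tolerance = 0.25)
})

test_that("trial simulation follows the three-option response model", {
  cfg <- simulation_config()
  # 3 frequencies x 3 trials
  prof <- participant_profile("P1", tremor_freq = 100, cfft = 60)
  tr <- simulate_trials(prof, cfg, seed = 1)
  expect_equal(nrow(tr), 9)
  expect_equal(as.vector(table(tr$flicker_freq)), c(3, 3, 3))
  expect_identical(simulate_trials(prof, cfg, seed = 1), tr)

  # saturated detection: every response correct
  sat <- participant_profile("P1", tremor_freq = 100, cfft = 1e6)
  tr <- simulate_trials(sat, cfg, seed = 2)
  expect_true(all(tr$answer == tr$true_side))

  # flat psychometric curve: per-trial correctness 1/3 + (2/3)(1/2) = 2/3
  flat <- participant_profile("P1", tremor_freq = 100, cfft = 60,
                              detection_slope = 0)
  big <- simulation_config(trials_per_frequency = 700)
  tr <- simulate_trials(flat, big, seed = 3)
  phat <- mean(tr$answer == tr$true_side)
  se <- sqrt((2 / 3) * (1 / 3) / nrow(tr))
  expect_lt(abs(phat - 2 / 3), 3 * se)
})
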