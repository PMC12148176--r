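# Independent oracles and shared fixture builders.

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled ranks to the first sample. Independent of wilcox.test.
enum_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Exact binomial tail by enumerating all 3^n equally likely outcome words
# when each trial has 1 success option out of 3.
enum_binom_tail_third <- function(n, min_successes) {
  grids <- rep(list(1:3), n)
  words <- do.call(expand.grid, grids)
  succ <- rowSums(words == 1)
  mean(succ >= min_successes)
}

# A noiseless, fully deterministic single-fixation recording carrying a
# pure circular tremor tone; handy for spectral/kinematic oracles.
tone_recording <- function(freq, duration = 4, amp = 0.01, seed = 1) {
  prof <- participant_profile("tone", tremor_freq = freq, tremor_amp = amp,
                              drift_diffusion = 0, cfft = 60)
  cfg <- simulation_config(
    duration = duration, fixation_mean_duration = duration * 2000,
    saccade_duration = 10, microsaccade_rate = 0, noise_sd = 0,
    blink_rate = 0, tremor_coherence = Inf
  )
  simulate_recording(prof, cfg, seed = seed)
}

# Hand-built velocity series (unit speed, prescribed direction angles).
velocity_from_angles <- function(theta, dt = 1) {
  tremorlink:::new_velocity_series(
    t = seq_along(theta) - 1, vx = cos(theta), vy = sin(theta),
    valid = rep(TRUE, length(theta)), variant = "unit", dt = dt
  )
}
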