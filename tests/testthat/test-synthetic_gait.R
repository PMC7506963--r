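test_that("config validation rejects impossible acquisition setups", {
  expect_error(gait_sim_config(duration_s = -1), "duration_s")
  expect_error(gait_sim_config(10, fs_emg = 1000, fs_angle = 120),
               "integer multiple")
  expect_error(gait_sim_config(10, delay_s = 0.3), "delay_s")
})

test_that("simulated recording has the configured shapes and ground truth", {
  cfg <- gait_sim_config(duration_s = 10, delay_s = 0.1, seed = 5)
  rec <- simulate_recording(cfg)
  expect_equal(ncol(rec$emg$samples), 10 * 1200)
  expect_equal(nrow(rec$emg$samples), 8)
  expect_equal(length(rec$angle$values), 10 * 120)
  expect_identical(rec$emg$channel_names, DEFAULT_MUSCLES)
  expect_equal(rec$truth_delay_s, 0.1)
  expect_true(all(rec$truth_envelopes >= 0))
  # angle template: smooth periodic knee-flexion curve, roughly 0-70 degrees
  expect_gt(min(rec$angle$values), -5)
  expect_lt(max(rec$angle$values), 75)
  expect_gt(diff(range(rec$angle$values)), 40)
})

test_that("identical config and seed give bitwise-identical recordings", {
  cfg <- gait_sim_config(duration_s = 5, seed = 42)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$emg$samples, r2$emg$samples)
  expect_identical(r1$angle$values, r2$angle$values)
  r3 <- simulate_recording(gait_sim_config(duration_s = 5, seed = 43))
  expect_false(identical(r1$emg$samples, r3$emg$samples))
})

test_that("constant-envelope degenerate mode yields stationary band-limited noise", {
  cfg <- gait_sim_config(duration_s = 10, noise_sd = 0, interference_amp = 0,
                         envelope = "constant", seed = 9)
  rec <- simulate_recording(cfg)
  x <- rec$emg$samples[1, ]
  # stationary variance: per-second variances all close to the global one
  vsec <- apply(matrix(x, nrow = 1200), 2, var)
  expect_true(all(abs(vsec - 1) < 0.35))
  expect_equal(var(x), 1, tolerance = 0.05)
  # band-limited: negligible power below 10 Hz and above 500 Hz
  p <- Mod(fft(x))^2
  freqs <- (seq_along(p) - 1) * 1200 / length(p)
  inband <- freqs >= 10 & freqs <= 500
  half <- freqs <= 600
  expect_gt(sum(p[inband & half]) / sum(p[half]), 0.99)
})

test_that("power spectrum shows a 50 Hz line that the notch removes", {
  cfg <- gait_sim_config(duration_s = 10, interference_amp = 0.5, seed = 2)
  rec <- simulate_recording(cfg)
  x <- rec$emg$samples[1, ]
  p <- Mod(fft(x))^2
  freqs <- (seq_along(p) - 1) * 1200 / length(p)
  band <- function(v, lo, hi) max(v[freqs >= lo & freqs <= hi])
  peak50 <- band(p, 49.5, 50.5)
  # local maximum: the 50 Hz bin dominates its neighbourhood
  expect_gt(peak50, band(p, 45, 48))
  expect_gt(peak50, band(p, 52, 55))
  xn <- notch_50hz(rec$emg)$samples[1, ]
  pn <- Mod(fft(xn))^2
  peak50_after <- max(pn[freqs >= 49.5 & freqs <= 50.5])
  expect_gt(10 * log10(peak50 / peak50_after), 20)
})

test_that("brute-force cross-correlation recovers the simulated delay", {
  for (d in c(0.05, 0.1, 0.2)) {
    cfg <- gait_sim_config(duration_s = 30, delay_s = d, seed = 7)
    rec <- simulate_recording(cfg)
    env <- rectified_envelope(rec$emg$samples[1, ], 1200, 120)
    lag <- oracle_best_lag(env, rec$angle$values, max_lag = 60)
    # the envelope leads the angle by the configured delay, to one sample
    expect_lte(abs(lag - d * 120), 1)
  }
})

test_that("recording round-trips through the CSV + sidecar writer", {
  cfg <- gait_sim_config(duration_s = 2, seed = 3)
  rec <- simulate_recording(cfg)
  dir <- withr::local_tempdir()
  write_recording(rec$emg, rec$angle, dir, "trial",
                  meta = list(delay_s = rec$truth_delay_s, seed = 3))
  back <- read_recording(dir, "trial")
  expect_equal(back$emg$samples, rec$emg$samples, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$angle$values, rec$angle$values, tolerance = 1e-6)
  expect_equal(back$meta$fs_emg, 1200)
  expect_equal(back$meta$delay_s, 0.2)
  expect_identical(back$emg$channel_names, DEFAULT_MUSCLES)
})
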