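test_that("shift-point arithmetic follows the ceil and rate-ratio rules", {
  ap <- compute_shift_points(0.2, 120, 1200)
  expect_equal(ap$l, 24L)
  expect_equal(ap$k, 240L)
  ap0 <- compute_shift_points(0, 120, 1200)
  expect_equal(ap0$l, 0L)
  expect_equal(ap0$k, 0L)
  ap3 <- compute_shift_points(0.021, 120, 1200)  # ceil(2.52) = 3
  expect_equal(ap3$l, 3L)
  expect_equal(ap3$k, 30L)
  expect_error(compute_shift_points(0.01, 120, 1250), "not an integer")
  expect_error(compute_shift_points(0.2, 1200, 120), "fs_angle")
})

test_that("window RMS matches the definition on simple signals", {
  cfg <- window_config(20)
  expect_equal(rms_windows(rep(3, 100), cfg), rep(3, 5))
  expect_equal(rms_windows(rep(-2, 40), cfg), rep(2, 2))
  cfg2 <- window_config(2)
  expect_equal(rms_windows(rep(c(3, 4), 10), cfg2),
               rep(sqrt((9 + 16) / 2), 10))
  expect_error(rms_windows(1:5, window_config(10)), "shorter")
})

test_that("window RMS equals the double-loop oracle on random signals", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(c(2, 5, 20), 1)
    len <- sample(50:500, 1)
    offset <- sample(0:3, 1) * n
    if (len - offset < n) next
    x <- rnorm(len)
    expect_equal(rms_windows(x, window_config(n), offset),
                 oracle_rms_windows(x, n, offset), tolerance = 1e-12)
  }
})

test_that("an offset of one window shifts the feature series by one step", {
  x <- as.numeric(1:200)  # ramp: every window RMS is distinct
  cfg <- window_config(20)
  f0 <- rms_windows(x, cfg, offset_k = 0)
  f1 <- rms_windows(x, cfg, offset_k = 20)
  expect_equal(f1, f0[-1])
})

test_that("feature smoothing keeps DC and removes fast vibration", {
  expect_equal(smooth_feature(rep(4.2, 120)), rep(4.2, 120), tolerance = 1e-6)
  expect_equal(smooth_feature(numeric(120)), numeric(120))
  # 25 Hz component at the 60 Hz feature rate is strongly attenuated
  tt <- seq(0, 2 - 1 / 60, by = 1 / 60)
  lp_gain <- {
    lp <- signal::butter(2, 5 / 30, type = "low")
    h <- sum(lp$b * exp(-1i * 2 * pi * 25 / 60 * (seq_along(lp$b) - 1))) /
      sum(lp$a * exp(-1i * 2 * pi * 25 / 60 * (seq_along(lp$a) - 1)))
    Mod(h)^2  # zero-phase application squares the response
  }
  expect_lt(lp_gain, 0.1)
  y <- smooth_feature(sin(2 * pi * 25 * tt))
  expect_lt(sd(y[30:90]), 0.1 * sd(sin(2 * pi * 25 * tt)))
  expect_error(smooth_feature(1:50, fs_feature = 8), "Nyquist")
})

test_that("angle subsampling averages pairwise windows with the lag rule", {
  expect_equal(subsample_angle(c(1, 3, 5, 7)), c(2, 6))
  expect_equal(subsample_angle(rep(7, 10)), rep(7, 5))
  expect_equal(subsample_angle(c(0, 1, 2, 3, 4, 5), lag_l = 2), c(2.5, 4.5))
  expect_error(subsample_angle(c(1, 2), lag_l = 1), "few")
})

test_that("aligned feature set has interleaved RRTAF columns and matched rows", {
  afs <- make_small_features(seed = 11, duration_s = 20)
  expect_equal(ncol(afs$X), 16)
  expect_equal(colnames(afs$X)[1:4],
               c("RF_rms", "RF_rmstaf", "BF_rms", "BF_rmstaf"))
  expect_equal(nrow(afs$X), length(afs$y))
  # trimming rule: floor((n_emg - k)/N) = duration*60 - 12 limits T
  expect_equal(nrow(afs$X), 20 * 60 - 12)
  expect_equal(afs$fs_feature, 60)
  rms8 <- concurrent_only(afs)
  expect_equal(colnames(rms8$X), paste0(DEFAULT_MUSCLES, "_rms"))
})

test_that("alignment length conservation holds across the delta_t grid", {
  for (dt in c(0, 0.05, 0.1, 0.2)) {
    afs <- make_small_features(seed = 4, duration_s = 10, delta_t = dt)
    expect_equal(nrow(afs$X), length(afs$y))
  }
})

test_that("zero advance collapses concurrent and time-advanced columns", {
  afs <- make_small_features(seed = 6, duration_s = 10, delta_t = 0)
  expect_identical(afs$X[, "RF_rms"], afs$X[, "RF_rmstaf"])
  expect_identical(afs$X[, "TA_rms"], afs$X[, "TA_rmstaf"])
})

test_that("with matched advance the time-advanced feature tracks the lagged angle best", {
  sim <- gait_sim_config(duration_s = 30, delay_s = 0.2, seed = 7)
  rec <- simulate_recording(sim)
  emg_c <- preprocess_emg(rec$emg)
  ap <- compute_shift_points(0.2, 120, 1200)
  afs <- build_aligned_features(emg_c, rec$angle, window_config(), ap)
  y_unlagged <- subsample_angle(rec$angle, 0)[seq_len(nrow(afs$X))]
  adv <- afs$X[, "RF_rmstaf"]
  expect_gt(abs(cor(adv, afs$y)), abs(cor(adv, y_unlagged)))
})

test_that("min-max normalization maps the training extremes to [-1, 1] and inverts", {
  afs <- make_small_features(seed = 12, duration_s = 10)
  norm <- fit_normalization(afs$X, afs$y)
  Xn <- apply_normalization(afs$X, norm)
  expect_equal(unname(apply(Xn, 2, min)), rep(-1, 16))
  expect_equal(unname(apply(Xn, 2, max)), rep(1, 16))
  yn <- apply_normalization(afs$y, norm, target = TRUE)
  expect_equal(range(yn), c(-1, 1))
  # midpoint maps to 0
  mid <- (norm$y_min + norm$y_max) / 2
  expect_equal(apply_normalization(mid, norm, target = TRUE), 0)
  # round trip
  expect_equal(invert_normalization(yn, norm), afs$y, tolerance = 1e-12)
  # values beyond the training extremes extrapolate, unclipped
  expect_gt(apply_normalization(norm$y_max + 1, norm, target = TRUE), 1)
  # degenerate column rejected
  Xd <- afs$X; Xd[, 3] <- 1
  expect_error(fit_normalization(Xd, afs$y), "degenerate")
  # column layout enforced
  Xp <- Xn[, c(2, 1, 3:16)]
  expect_error(apply_normalization(Xp, norm), "columns")
})

test_that("smoothing preserves the ordering of column extremes after normalization", {
  afs <- make_small_features(seed = 13, duration_s = 10)
  norm <- fit_normalization(afs$X, afs$y)
  Xn <- apply_normalization(afs$X, norm)
  for (j in c(1, 8, 16)) {
    expect_equal(which.max(Xn[, j]), which.max(afs$X[, j]))
    expect_equal(which.min(Xn[, j]), which.min(afs$X[, j]))
  }
})

test_that("feature sets round-trip through CSV + sidecar", {
  afs <- make_small_features(seed = 14, duration_s = 5)
  path <- file.path(withr::local_tempdir(), "features.csv")
  write_feature_set(afs, path)
  back <- read_feature_set(path)
  expect_equal(back$X, afs$X, tolerance = 1e-6)
  expect_equal(back$y, afs$y, tolerance = 1e-6)
  expect_equal(back$ap$l, afs$ap$l)
  expect_equal(back$fs_feature, 60)
})
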