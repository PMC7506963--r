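# Independent brute-force oracles, kept deliberately naive (double loops,
# direct formula transcription) so they share no code with the implementation.

oracle_rms_windows <- function(x, n, offset) {
  n_win <- (length(x) - offset) %/% n
  out <- numeric(n_win)
  for (h in seq_len(n_win)) {
    s <- 0
    for (i in ((h - 1) * n + offset + 1):(h * n + offset)) s <- s + x[i]^2
    out[h] <- sqrt(s / n)
  }
  out
}

oracle_rmse <- function(est, act) {
  s <- 0
  for (i in seq_along(est)) s <- s + (est[i] - act[i])^2
  sqrt(s / length(est))
}

oracle_rho <- function(est, act) {
  n <- length(est)
  me <- sum(est) / n; ma <- sum(act) / n
  num <- 0; de <- 0; da <- 0
  for (i in seq_len(n)) {
    num <- num + (act[i] - ma) * (est[i] - me)
    de <- de + (est[i] - me)^2
    da <- da + (act[i] - ma)^2
  }
  (num / n) / sqrt((de / n) * (da / n))
}

# scalar-by-scalar transcription of the gated cell equations
oracle_lstm_cell <- function(x, h_prev, c_prev, w) {
  H <- length(h_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  f <- i <- g <- o <- cn <- hn <- numeric(H)
  for (r in seq_len(H)) {
    zf <- sum(w$W_f[r, ] * h_prev) + sum(w$U_f[r, ] * x) + w$b_f[r]
    zi <- sum(w$W_i[r, ] * h_prev) + sum(w$U_i[r, ] * x) + w$b_i[r]
    zc <- sum(w$W_c[r, ] * h_prev) + sum(w$U_c[r, ] * x) + w$b_c[r]
    zo <- sum(w$W_o[r, ] * h_prev) + sum(w$U_o[r, ] * x) + w$b_o[r]
    f[r] <- sig(zf); i[r] <- sig(zi); g[r] <- tanh(zc); o[r] <- sig(zo)
    cn[r] <- f[r] * c_prev[r] + i[r] * g[r]
    hn[r] <- o[r] * tanh(cn[r])
  }
  list(h = hn, c = cn, f = f, i = i, o = o, g = g)
}

# scalar transcription of the printed three-layer network equation
oracle_bpnn <- function(x, w) {
  H <- nrow(w$W_in)
  a <- numeric(H)
  for (r in seq_len(H)) {
    z <- sum(w$W_in[r, ] * x) + w$b_in[r]
    a[r] <- 2 / (1 + exp(-2 * z)) - 1
  }
  zo <- sum(w$W_out[1, ] * a)
  1 / (1 + exp(-zo)) + w$b_out
}

random_lstm_weights <- function(H, I) {
  m <- function(nr, nc) matrix(rnorm(nr * nc), nr, nc)
  list(U_f = m(H, I), U_i = m(H, I), U_c = m(H, I), U_o = m(H, I),
       W_f = m(H, H), W_i = m(H, H), W_c = m(H, H), W_o = m(H, H),
       b_f = rnorm(H), b_i = rnorm(H), b_c = rnorm(H), b_o = rnorm(H),
       w_y = m(1, H), b_y = rnorm(1))
}

# lag (in samples of the common rate) maximizing the cross-correlation of x
# against y shifted by that lag; positive means x leads y
oracle_best_lag <- function(x, y, max_lag) {
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(s) {
    if (s >= 0) stats::cor(x[1:(length(x) - s)], y[(1 + s):length(y)])
    else stats::cor(x[(1 - s):length(x)], y[1:(length(y) + s)])
  }, numeric(1))
  lags[which.max(cc)]
}

# smoothed rectified sEMG envelope decimated to the angle rate
rectified_envelope <- function(emg_ch, fs_emg, fs_angle, cutoff = 3) {
  lp <- signal::butter(2, cutoff / (fs_emg / 2), type = "low")
  e <- signal::filtfilt(lp, abs(emg_ch))
  e[seq(1, length(e), by = fs_emg / fs_angle)]
}

# shared small synthetic feature set for model tests (cheap: 20 s)
make_small_features <- function(seed = 11, duration_s = 20, delta_t = 0.2,
                                delay_s = 0.2) {
  sim <- gait_sim_config(duration_s = duration_s, delay_s = delay_s,
                         seed = seed)
  rec <- simulate_recording(sim)
  emg_c <- preprocess_emg(rec$emg)
  ap <- compute_shift_points(delta_t, rec$angle$fs_angle, rec$emg$fs_emg)
  build_aligned_features(emg_c, rec$angle, window_config(), ap)
}

# scaled-down training recipe for short (60 s) synthetic recordings
scaled_lstm_config <- function(input_size, seed) {
  lstm_config(input_size = input_size, hidden_size = 48, seq_len = 100,
              learning_rate = 0.005, epochs = 30, batch_size = 7,
              dropout_p = 0.2, seed = seed)
}

run_scaled_lstm <- function(seed, features = c("rrtaf", "rms"),
                            duration_s = 60) {
  features <- match.arg(features)
  sim <- gait_sim_config(duration_s = duration_s, delay_s = 0.2, seed = seed)
  rec <- simulate_recording(sim)
  emg_c <- preprocess_emg(rec$emg)
  ap <- compute_shift_points(0.2, rec$angle$fs_angle, rec$emg$fs_emg)
  afs <- build_aligned_features(emg_c, rec$angle, window_config(), ap)
  if (features == "rms") afs <- concurrent_only(afs)
  n <- nrow(afs$X); ntr <- floor(0.8 * n)
  norm <- fit_normalization(afs$X[1:ntr, ], afs$y[1:ntr])
  Xtr <- apply_normalization(afs$X[1:ntr, ], norm)
  ytr <- apply_normalization(afs$y[1:ntr], norm, target = TRUE)
  Xte <- apply_normalization(afs$X[(ntr + 1):n, ], norm)
  m <- train_lstm(Xtr, ytr, scaled_lstm_config(ncol(afs$X), seed))
  yhat <- invert_normalization(predict_lstm(m, Xte), norm)
  evaluate_prediction(yhat, afs$y[(ntr + 1):n])
}
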