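# --- LSTM cell -------------------------------------------------------------

test_that("zero-weight cell reduces to the sigmoid/tanh fixed values", {
  H <- 3; I <- 4
  w <- list(U_f = matrix(0, H, I), U_i = matrix(0, H, I),
            U_c = matrix(0, H, I), U_o = matrix(0, H, I),
            W_f = matrix(0, H, H), W_i = matrix(0, H, H),
            W_c = matrix(0, H, H), W_o = matrix(0, H, H),
            b_f = numeric(H), b_i = numeric(H), b_c = numeric(H),
            b_o = numeric(H))
  c_prev <- c(1, -2, 0.5)
  st <- lstm_cell_step(rnorm(I), numeric(H), c_prev, w)
  expect_equal(as.numeric(st$f), rep(0.5, H))
  expect_equal(as.numeric(st$i), rep(0.5, H))
  expect_equal(as.numeric(st$o), rep(0.5, H))
  expect_equal(as.numeric(st$g), rep(0, H))
  expect_equal(as.numeric(st$c), 0.5 * c_prev)
  expect_equal(as.numeric(st$h), 0.5 * tanh(0.5 * c_prev))
})

test_that("cell matches the scalar oracle on 100 random instances", {
  set.seed(202)
  for (rep in 1:100) {
    H <- sample(1:4, 1); I <- sample(1:5, 1)
    w <- random_lstm_weights(H, I)
    x <- rnorm(I); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- lstm_cell_step(x, h0, c0, w)
    want <- oracle_lstm_cell(x, h0, c0, w)
    for (nm in c("h", "c", "f", "i", "o", "g")) {
      expect_equal(as.numeric(got[[nm]]), want[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("gate activations stay in their ranges for random inputs", {
  set.seed(203)
  for (rep in 1:50) {
    w <- random_lstm_weights(3, 3)
    st <- lstm_cell_step(rnorm(3), rnorm(3), rnorm(3), w)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(st$g > -1 & st$g < 1))
  }
  # extreme inputs saturate but never overshoot the closed bounds
  w <- random_lstm_weights(3, 3)
  st <- lstm_cell_step(rnorm(3) * 100, rnorm(3) * 100, rnorm(3), w)
  expect_true(all(st$f >= 0 & st$f <= 1))
  expect_true(all(st$i >= 0 & st$i <= 1))
  expect_true(all(st$o >= 0 & st$o <= 1))
  expect_true(all(st$g >= -1 & st$g <= 1))
  expect_true(all(is.finite(st$h)))
})

test_that("a saturated-closed input gate empties the cell state", {
  w <- random_lstm_weights(2, 2)
  w$b_i <- c(-1e3, -1e3)   # input gate -> 0
  w$b_f <- c(-1e3, -1e3)   # forget gate -> 0
  st <- lstm_cell_step(rnorm(2), rnorm(2), c(0, 0), w)
  expect_equal(as.numeric(st$c), c(0, 0), tolerance = 1e-12)
})

test_that("cell rejects mismatched shapes", {
  w <- random_lstm_weights(3, 4)
  expect_error(lstm_cell_step(rnorm(2), rnorm(3), rnorm(3), w), "shape")
  expect_error(lstm_cell_step(rnorm(4), rnorm(2), rnorm(2), w), "shape")
})

# --- LSTM training ---------------------------------------------------------

test_that("training on a constant target converges and is seed-reproducible", {
  set.seed(7)
  X <- matrix(rnorm(400 * 4, sd = 0.3), 400, 4)
  y <- rep(0.3, 400)
  cfg <- lstm_config(input_size = 4, hidden_size = 8, seq_len = 50,
                     learning_rate = 0.01, epochs = 30, batch_size = 4,
                     dropout_p = 0, seed = 99)
  m1 <- train_lstm(X, y, cfg)
  m2 <- train_lstm(X, y, cfg)
  expect_identical(m1$loss, m2$loss)
  expect_identical(m1$weights, m2$weights)
  # smoothed loss decreases monotonically (tiny slack for optimizer wobble
  # once the loss reaches its floor)
  sm <- stats::filter(m1$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 5e-4))
  expect_lt(sm[length(sm)], 0.05 * sm[1])
  pred <- predict_lstm(m1, X)
  expect_lt(max(abs(pred[20:400] - 0.3)), 0.05)
})

test_that("zero training epochs leaves the model at its initialization", {
  X <- matrix(rnorm(200 * 4), 200, 4)
  cfg <- lstm_config(input_size = 4, hidden_size = 6, seq_len = 50,
                     epochs = 0, seed = 5)
  m <- train_lstm(X, rnorm(200), cfg)
  expect_length(m$loss, 0)
  w0 <- with_seed_weights <- local({
    set.seed(5)
    rrtaf:::init_lstm_weights(4L, 6L)
  })
  expect_identical(m$weights, w0)
})

test_that("prediction is stateful, contract-checked, and handles empty input", {
  set.seed(31)
  X <- matrix(rnorm(300 * 4), 300, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  cfg <- lstm_config(input_size = 4, hidden_size = 6, seq_len = 50,
                     epochs = 2, seed = 1)
  m <- train_lstm(X, rnorm(300), cfg)
  # constant input: the state iteration converges to a fixed point
  xc <- matrix(0.4, 200, 4, dimnames = list(NULL, paste0("f", 1:4)))
  out <- predict_lstm(m, xc)
  expect_lt(abs(out[200] - out[199]), 1e-8)
  # permuted columns violate the trained layout
  Xp <- X[, c(2, 1, 3, 4)]
  expect_error(predict_lstm(m, Xp), "columns")
  expect_identical(predict_lstm(m, X[0, , drop = FALSE]), numeric(0))
})

# --- BPNN ------------------------------------------------------------------

test_that("zero-weight network evaluates the printed output form", {
  w <- list(W_in = matrix(0, 3, 4), b_in = numeric(3),
            W_out = matrix(0, 1, 3), b_out = 0.25)
  # hidden tansig(0) = 0; output sigma(0) + b_out = 0.75
  expect_equal(bpnn_forward(rnorm(4), w), 0.5 + 0.25)
  expect_equal(bpnn_forward(rnorm(4), w, "linear"), 0.25)
})

test_that("forward pass matches the scalar oracle on 100 random nets", {
  set.seed(204)
  for (rep in 1:100) {
    H <- sample(1:5, 1); I <- sample(1:6, 1)
    w <- list(W_in = matrix(rnorm(H * I), H, I), b_in = rnorm(H),
              W_out = matrix(rnorm(H), 1, H), b_out = rnorm(1))
    x <- rnorm(I)
    expect_equal(bpnn_forward(x, w), oracle_bpnn(x, w), tolerance = 1e-12)
  }
})

test_that("tansig saturation keeps outputs finite for wild inputs", {
  w <- list(W_in = matrix(rnorm(8), 2, 4), b_in = rnorm(2),
            W_out = matrix(rnorm(2), 1, 2), b_out = 0)
  out <- bpnn_forward(c(1e6, -1e6, 50, -50), w)
  expect_true(is.finite(out))
})

test_that("momentum training drives MSE below the learning goal on a toy mapping", {
  set.seed(55)
  X <- matrix(runif(300 * 3, -1, 1), 300, 3)
  # smooth target inside the logistic+bias output range
  y <- 0.35 * tanh(X[, 1] + 0.5 * X[, 2]) + 0.1 * X[, 3]
  cfg <- bpnn_config(n_input = 3, n_hidden = 8, learning_rate = 0.1,
                     goal_mse = 0.01, max_epochs = 20000, momentum = 0.9,
                     seed = 8)
  m <- train_bpnn(X, y, cfg)
  expect_lt(m$loss[m$epochs_run], 0.01)
  expect_lt(m$epochs_run, 20000)
  # early stop happened at the goal, and momentum beat plain gradient descent
  cfg0 <- cfg; cfg0$momentum <- 0
  m0 <- train_bpnn(X, y, cfg0)
  expect_lte(m$epochs_run, m0$epochs_run)
})

test_that("training is reproducible and prediction enforces the layout", {
  set.seed(56)
  X <- matrix(runif(100 * 3, -1, 1), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 0.3 * X[, 1]
  cfg <- bpnn_config(n_input = 3, n_hidden = 4, max_epochs = 200, seed = 2)
  m1 <- train_bpnn(X, y, cfg)
  m2 <- train_bpnn(X, y, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_error(predict_bpnn(m1, X[, c(2, 1, 3)]), "columns")
})

# --- hidden-unit selection -------------------------------------------------

test_that("sizing formulas give 5..14 and 4 for a 16-input single-output net", {
  cand_raw <- hidden_unit_candidates(n = 16, m = 1, widen_to = NULL)
  expect_equal(cand_raw, as.integer(c(4, 5:14)))
  cand <- hidden_unit_candidates()
  expect_equal(cand, 4:26)
  expect_true(18 %in% cand)
})

test_that("selection returns the validation-MSE minimizer, ties to fewer units", {
  set.seed(77)
  X <- matrix(runif(240 * 3, -1, 1), 240, 3)
  y <- 0.3 * tanh(X[, 1]) - 0.2 * X[, 2]
  tr <- 1:180; va <- 181:240
  cfg <- bpnn_config(n_input = 3, max_epochs = 300, seed = 4)
  sel <- select_hidden_units(X[tr, ], y[tr], X[va, ], y[va],
                             candidates = c(2, 6, 10), cfg = cfg)
  expect_equal(sel$n_hidden, as.integer(names(which.min(sel$mse))))
  single <- select_hidden_units(X[tr, ], y[tr], X[va, ], y[va],
                                candidates = 7, cfg = cfg)
  expect_equal(single$n_hidden, 7L)
  expect_error(select_hidden_units(X[tr, ], y[tr], X[va, ], y[va],
                                   candidates = integer(0)), "empty")
})
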