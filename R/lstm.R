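#' LSTM training configuration
#'
#' A single recurrent LSTM layer unrolled over `seq_len` time steps, followed
#' by a dropout-regularized linear readout to one output (the normalized knee
#' angle). Defaults follow the study recipe: 16 inputs (the RRTAF feature
#' set), 200 hidden units, unroll length 100, Adam with learning rate 0.0005,
#' 200 epochs, mini-batches of 50 sequence windows and dropout 0.5 at the
#' readout. The unroll length is what gives the network its depth in time; a
#' `stacked_layers` option (default 1) exists for sensitivity checks but is
#' not part of the standard recipe.
#'
#' @param input_size number of feature columns (default 16).
#' @param hidden_size LSTM cell count (default 200).
#' @param seq_len unroll/sequence-window length in feature steps (default 100).
#' @param learning_rate Adam step size (default 0.0005).
#' @param epochs training rounds (default 200).
#' @param batch_size sequence windows per mini-batch (default 50).
#' @param dropout_p dropout probability at the readout during training
#'   (default 0.5).
#' @param stacked_layers number of stacked recurrent layers (default 1).
#' @param seed integer RNG seed governing initialization, window shuffling
#'   and dropout masks.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(input_size = 16, hidden_size = 200, seq_len = 100,
                        learning_rate = 5e-4, epochs = 200, batch_size = 50,
                        dropout_p = 0.5, stacked_layers = 1, seed = 1L) {
  for (nm in c("input_size", "hidden_size", "seq_len", "learning_rate",
               "batch_size", "stacked_layers")) {
    check_scalar(get(nm), nm)
  }
  check_scalar(epochs, "epochs", positive = FALSE)
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("`dropout_p` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(input_size = as.integer(input_size),
         hidden_size = as.integer(hidden_size),
         seq_len = as.integer(seq_len), learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         dropout_p = dropout_p, stacked_layers = as.integer(stacked_layers),
         seed = as.integer(seed)),
    class = "lstm_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# uniform +-1/sqrt(fan_in) initialization for one layer of gates + readout
init_lstm_weights <- function(input_size, hidden_size) {
  u <- function(nr, nc, fan_in) {
    matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
  }
  H <- hidden_size; I <- input_size
  list(
    U_f = u(H, I, I), U_i = u(H, I, I), U_c = u(H, I, I), U_o = u(H, I, I),
    W_f = u(H, H, H), W_i = u(H, H, H), W_c = u(H, H, H), W_o = u(H, H, H),
    b_f = numeric(H), b_i = numeric(H), b_c = numeric(H), b_o = numeric(H),
    w_y = u(1, H, H), b_y = 0
  )
}

#' One LSTM cell step
#'
#' Gated update of the cell state: forget gate `f = sigma(W_f h + U_f x + b_f)`,
#' input gate `i` and output gate `o` likewise, candidate
#' `g = tanh(W_c h + U_c x + b_c)`, then `c = f * c_prev + i * g` and
#' `h = o * tanh(c)` (elementwise products throughout).
#'
#' @param x_t input vector (length `input_size`) or matrix
#'   `[input_size x batch]`.
#' @param h_prev,c_prev previous hidden / cell state, shapes matching `x_t`'s
#'   batch dimension.
#' @param w weight list as produced by the trainer (`U_*` `[hidden x input]`,
#'   `W_*` `[hidden x hidden]`, `b_*` `[hidden]`).
#' @return A list with `h`, `c` and the gate activations `f`, `i`, `o` and
#'   candidate `g`; gates lie in (0,1), the candidate in (-1,1).
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, w) {
  if (is.vector(x_t)) x_t <- matrix(x_t, ncol = 1)
  if (is.vector(h_prev)) h_prev <- matrix(h_prev, ncol = 1)
  if (is.vector(c_prev)) c_prev <- matrix(c_prev, ncol = 1)
  if (nrow(x_t) != ncol(w$U_f) || nrow(h_prev) != nrow(w$U_f) ||
      !identical(dim(h_prev), dim(c_prev))) {
    stop("shape mismatch between input, state and weights", call. = FALSE)
  }
  f <- sigmoid(w$W_f %*% h_prev + w$U_f %*% x_t + w$b_f)
  i <- sigmoid(w$W_i %*% h_prev + w$U_i %*% x_t + w$b_i)
  g <- tanh(w$W_c %*% h_prev + w$U_c %*% x_t + w$b_c)
  o <- sigmoid(w$W_o %*% h_prev + w$U_o %*% x_t + w$b_o)
  c_new <- f * c_prev + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, f = f, i = i, o = o, g = g)
}

# forward pass over a [seq_len] window batch; X is [seq_len][input x B].
# Returns caches needed for BPTT.
lstm_forward_window <- function(Xs, w, dropout_masks = NULL) {
  H <- nrow(w$W_f)
  B <- ncol(Xs[[1]])
  Tn <- length(Xs)
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  cache <- vector("list", Tn)
  yhat <- matrix(0, Tn, B)
  for (t in seq_len(Tn)) {
    st <- lstm_cell_step(Xs[[t]], h, cc, w)
    hd <- st$h
    if (!is.null(dropout_masks)) hd <- hd * dropout_masks[[t]]
    yhat[t, ] <- as.numeric(w$w_y %*% hd + w$b_y)
    cache[[t]] <- list(st = st, h_prev = h, c_prev = cc, hd = hd)
    h <- st$h; cc <- st$c
  }
  list(yhat = yhat, cache = cache)
}

# BPTT through one window batch; Y is [seq_len x B] of targets.
# Returns gradient list matching the weight list; loss is mean squared error
# over all (t, b).
lstm_backward_window <- function(Xs, Y, w, fw, dropout_masks = NULL) {
  H <- nrow(w$W_f); B <- ncol(Xs[[1]]); Tn <- length(Xs)
  g <- lapply(w, function(p) if (is.matrix(p)) p * 0 else p * 0)
  n_tot <- Tn * B
  dh_next <- matrix(0, H, B)
  dc_next <- matrix(0, H, B)
  for (t in rev(seq_len(Tn))) {
    cc <- fw$cache[[t]]
    st <- cc$st
    dy <- matrix(2 * (fw$yhat[t, ] - Y[t, ]) / n_tot, 1, B)
    g$w_y <- g$w_y + dy %*% t(cc$hd)
    g$b_y <- g$b_y + sum(dy)
    dhd <- t(w$w_y) %*% dy
    if (!is.null(dropout_masks)) dhd <- dhd * dropout_masks[[t]]
    dh <- dhd + dh_next
    tc <- tanh(st$c)
    do <- dh * tc
    dz_o <- do * st$o * (1 - st$o)
    dc <- dh * st$o * (1 - tc^2) + dc_next
    df <- dc * cc$c_prev
    dz_f <- df * st$f * (1 - st$f)
    di <- dc * st$g
    dz_i <- di * st$i * (1 - st$i)
    dg <- dc * st$i
    dz_c <- dg * (1 - st$g^2)
    x_t <- Xs[[t]]
    g$U_f <- g$U_f + dz_f %*% t(x_t); g$W_f <- g$W_f + dz_f %*% t(cc$h_prev)
    g$U_i <- g$U_i + dz_i %*% t(x_t); g$W_i <- g$W_i + dz_i %*% t(cc$h_prev)
    g$U_c <- g$U_c + dz_c %*% t(x_t); g$W_c <- g$W_c + dz_c %*% t(cc$h_prev)
    g$U_o <- g$U_o + dz_o %*% t(x_t); g$W_o <- g$W_o + dz_o %*% t(cc$h_prev)
    g$b_f <- g$b_f + rowSums(dz_f); g$b_i <- g$b_i + rowSums(dz_i)
    g$b_c <- g$b_c + rowSums(dz_c); g$b_o <- g$b_o + rowSums(dz_o)
    dh_next <- t(w$W_f) %*% dz_f + t(w$W_i) %*% dz_i +
      t(w$W_c) %*% dz_c + t(w$W_o) %*% dz_o
    dc_next <- dc * st$f
  }
  g
}

#' Train the LSTM angle regressor
#'
#' Cuts the (normalized) training stream into non-overlapping windows of
#' `seq_len` steps in temporal order, shuffles the windows each epoch with the
#' seeded RNG, and minimizes the mean-squared error of the per-step readout
#' with Adam. The hidden state is reset at each window; dropout masks are
#' redrawn per step during training only. Given the same data and config
#' (including seed) the loss trajectory is identical run to run.
#'
#' @param X normalized feature matrix `[T x input_size]` (column names are
#'   remembered and enforced at prediction time).
#' @param y normalized target vector of length `T`.
#' @param cfg an [lstm_config()].
#' @return A list of class `lstm_model`: `weights`, `cfg`, `feature_names`
#'   and `loss` (training MSE per epoch).
#' @export
train_lstm <- function(X, y, cfg = lstm_config()) {
  stopifnot(inherits(cfg, "lstm_config"))
  X <- as.matrix(X)
  if (ncol(X) != cfg$input_size) {
    stop(sprintf("X has %d columns but cfg$input_size is %d",
                 ncol(X), cfg$input_size), call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  Tn <- cfg$seq_len
  n_win <- nrow(X) %/% Tn
  if (n_win < 1) stop("fewer training steps than one sequence window",
                      call. = FALSE)
  if (cfg$stacked_layers != 1L) {
    stop("only a single recurrent layer is implemented; `stacked_layers` is ",
         "reserved for sensitivity checks", call. = FALSE)
  }

  with_seed(cfg$seed, {
    w <- init_lstm_weights(cfg$input_size, cfg$hidden_size)
    adam_m <- lapply(w, function(p) p * 0)
    adam_v <- lapply(w, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0
    loss <- numeric(cfg$epochs)

    # pre-cut windows: list of index vectors
    windows <- lapply(seq_len(n_win), function(j) ((j - 1) * Tn + 1):(j * Tn))

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_win)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_sse <- 0; ep_n <- 0
      for (bt in batches) {
        B <- length(bt)
        Xs <- lapply(seq_len(Tn), function(t) {
          t(X[vapply(bt, function(j) windows[[j]][t], 1L), , drop = FALSE])
        })
        Y <- vapply(seq_len(Tn),
                    function(t) y[vapply(bt, function(j) windows[[j]][t], 1L)],
                    numeric(B))
        Y <- matrix(t(Y), nrow = Tn)  # [Tn x B]
        masks <- NULL
        if (cfg$dropout_p > 0) {
          keep <- 1 - cfg$dropout_p
          masks <- lapply(seq_len(Tn), function(t) {
            matrix(stats::rbinom(cfg$hidden_size * B, 1, keep) / keep,
                   cfg$hidden_size, B)
          })
        }
        fw <- lstm_forward_window(Xs, w, masks)
        grad <- lstm_backward_window(Xs, Y, w, fw, masks)
        step <- step + 1
        for (nm in names(w)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grad[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grad[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - b1^step)
          vhat <- adam_v[[nm]] / (1 - b2^step)
          w[[nm]] <- w[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        ep_sse <- ep_sse + sum((fw$yhat - Y)^2)
        ep_n <- ep_n + length(Y)
      }
      loss[ep] <- ep_sse / ep_n
    }

    structure(
      list(weights = w, cfg = cfg, feature_names = colnames(X), loss = loss),
      class = "lstm_model"
    )
  })
}

#' Predict normalized angles from a feature sequence
#'
#' Unrolls the trained cell statefully over the whole sequence in temporal
#' order (no window cuts, no dropout), emitting one normalized angle per step.
#'
#' @param model an [train_lstm()] result.
#' @param X feature matrix `[T x input_size]`; if both the model and `X`
#'   carry column names they must match exactly.
#' @return Numeric vector of length `T` (empty input gives an empty vector).
#' @export
predict_lstm <- function(model, X) {
  stopifnot(inherits(model, "lstm_model"))
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != model$cfg$input_size) {
    stop("feature column count does not match the trained model", call. = FALSE)
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names)) {
    stop("feature columns do not match the layout the model was trained on",
         call. = FALSE)
  }
  w <- model$weights
  H <- nrow(w$W_f)
  h <- matrix(0, H, 1); cc <- matrix(0, H, 1)
  out <- numeric(nrow(X))
  for (t in seq_len(nrow(X))) {
    st <- lstm_cell_step(X[t, ], h, cc, w)
    out[t] <- as.numeric(w$w_y %*% st$h + w$b_y)
    h <- st$h; cc <- st$c
  }
  out
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf(
    "<lstm_model> %d -> %d hidden, seq_len %d, %d epoch(s) trained%s\n",
    x$cfg$input_size, x$cfg$hidden_size, x$cfg$seq_len, length(x$loss),
    if (length(x$loss)) sprintf(", final MSE %.4g", x$loss[length(x$loss)])
    else ""
  ))
  invisible(x)
}
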