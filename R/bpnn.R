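#' BPNN training configuration
#'
#' A three-layer feed-forward network (16 inputs, one tansig hidden layer,
#' one output node) trained by full-batch gradient descent with momentum.
#' Defaults follow the study settings: learning goal (MSE on normalized
#' targets) 0.01, learning rate 0.1, at most 50,000 epochs; the momentum
#' coefficient, unspecified there, defaults to the conventional 0.9. The
#' output node evaluates the logistic form of the printed network equation
#' (`sigma(W_out a_hidden) + b_out`); a `"linear"` option gives the plain
#' affine readout conventional for regression.
#'
#' @param n_input input node count (default 16).
#' @param n_hidden hidden node count (default 18, the selected optimum).
#' @param n_output output node count (fixed 1).
#' @param learning_rate gradient step size (default 0.1).
#' @param goal_mse stop once training MSE falls below this (default 0.01).
#' @param max_epochs epoch cap (default 50000).
#' @param momentum momentum coefficient in [0,1) (default 0.9).
#' @param output_activation `"logistic"` (the printed form, default) or
#'   `"linear"`.
#' @param seed integer RNG seed for weight initialization.
#' @return A list of class `bpnn_config`.
#' @export
bpnn_config <- function(n_input = 16, n_hidden = 18, n_output = 1,
                        learning_rate = 0.1, goal_mse = 0.01,
                        max_epochs = 50000, momentum = 0.9,
                        output_activation = c("logistic", "linear"),
                        seed = 1L) {
  output_activation <- match.arg(output_activation)
  for (nm in c("n_input", "n_hidden", "learning_rate", "goal_mse",
               "max_epochs")) check_scalar(get(nm), nm)
  if (n_output != 1) stop("a single output node is supported", call. = FALSE)
  if (momentum < 0 || momentum >= 1) {
    stop("`momentum` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
         n_output = 1L, learning_rate = learning_rate, goal_mse = goal_mse,
         max_epochs = as.integer(max_epochs), momentum = momentum,
         output_activation = output_activation, seed = as.integer(seed)),
    class = "bpnn_config"
  )
}

# tansig: 2/(1+exp(-2z)) - 1 == tanh(z), written in its defining form
tansig <- function(z) 2 / (1 + exp(-2 * z)) - 1

#' BPNN forward pass
#'
#' Hidden layer: `a = tansig(W_in x + b_in)` with
#' `tansig(z) = 2/(1+exp(-2z)) - 1`. Output (default, the printed logistic
#' form): `theta = 1/(1 + exp(-W_out a)) + b_out`; with
#' `output_activation = "linear"`, `theta = W_out a + b_out`.
#'
#' @param x input vector of length `n_input`, or matrix
#'   `[n_input x n_samples]`.
#' @param w weight list: `W_in` `[n_hidden x n_input]`, `b_in` `[n_hidden]`,
#'   `W_out` `[1 x n_hidden]`, `b_out` scalar.
#' @param output_activation `"logistic"` or `"linear"`.
#' @return Numeric vector of angle estimates, one per input column.
#' @export
bpnn_forward <- function(x, w, output_activation = c("logistic", "linear")) {
  output_activation <- match.arg(output_activation)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != ncol(w$W_in)) stop("input size mismatch", call. = FALSE)
  a <- tansig(w$W_in %*% x + w$b_in)
  z <- as.numeric(w$W_out %*% a)
  if (output_activation == "logistic") sigmoid(z) + w$b_out else z + w$b_out
}

#' Train the BPNN angle regressor
#'
#' Full-batch gradient descent with classical momentum
#' (`v <- momentum * v - lr * grad; w <- w + v`) on the mean squared error of
#' normalized targets, stopping at `goal_mse` or `max_epochs`, whichever
#' comes first.
#'
#' @param X feature matrix `[T x n_input]` (normalized).
#' @param y target vector (normalized).
#' @param cfg a [bpnn_config()].
#' @return A list of class `bpnn_model`: `weights`, `cfg`, `feature_names`,
#'   `loss` (MSE per epoch) and `epochs_run`.
#' @export
train_bpnn <- function(X, y, cfg = bpnn_config()) {
  stopifnot(inherits(cfg, "bpnn_config"))
  X <- as.matrix(X)
  if (ncol(X) != cfg$n_input) stop("X column count != n_input", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  Xt <- t(X)  # [n_input x T]
  n <- length(y)
  logistic_out <- cfg$output_activation == "logistic"

  with_seed(cfg$seed, {
    u <- function(nr, nc, fan) matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
    w <- list(W_in = u(cfg$n_hidden, cfg$n_input, cfg$n_input),
              b_in = numeric(cfg$n_hidden),
              W_out = u(1, cfg$n_hidden, cfg$n_hidden),
              b_out = 0)
    v <- lapply(w, function(p) p * 0)
    loss <- numeric(0)
    for (ep in seq_len(cfg$max_epochs)) {
      a <- tansig(w$W_in %*% Xt + w$b_in)
      z <- as.numeric(w$W_out %*% a)
      yhat <- if (logistic_out) sigmoid(z) + w$b_out else z + w$b_out
      err <- yhat - y
      mse <- mean(err^2)
      loss <- c(loss, mse)
      if (mse <= cfg$goal_mse) break
      dyhat <- 2 * err / n
      dz <- if (logistic_out) dyhat * sigmoid(z) * (1 - sigmoid(z)) else dyhat
      dz <- matrix(dz, 1, n)
      grad <- list(
        W_in = NULL, b_in = NULL,
        W_out = dz %*% t(a),
        b_out = sum(dyhat)
      )
      da <- t(w$W_out) %*% dz
      dzin <- da * (1 - a^2)
      grad$W_in <- dzin %*% X
      grad$b_in <- rowSums(dzin)
      for (nm in names(w)) {
        v[[nm]] <- cfg$momentum * v[[nm]] - cfg$learning_rate * grad[[nm]]
        w[[nm]] <- w[[nm]] + v[[nm]]
      }
    }
    structure(
      list(weights = w, cfg = cfg, feature_names = colnames(X), loss = loss,
           epochs_run = length(loss)),
      class = "bpnn_model"
    )
  })
}

#' Predict with a trained BPNN
#'
#' @param model a [train_bpnn()] result.
#' @param X feature matrix `[T x n_input]`; column names, when present on
#'   both sides, must match the training layout.
#' @return Numeric vector of normalized angle estimates.
#' @export
predict_bpnn <- function(model, X) {
  stopifnot(inherits(model, "bpnn_model"))
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  if (!is.null(model$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names)) {
    stop("feature columns do not match the layout the model was trained on",
         call. = FALSE)
  }
  bpnn_forward(t(X), model$weights, model$cfg$output_activation)
}

#' @export
print.bpnn_model <- function(x, ...) {
  cat(sprintf(
    "<bpnn_model> %d-%d-1 (%s output), %d epoch(s), final MSE %.4g\n",
    x$cfg$n_input, x$cfg$n_hidden, x$cfg$output_activation, x$epochs_run,
    if (x$epochs_run) x$loss[x$epochs_run] else NA_real_
  ))
  invisible(x)
}

#' Candidate hidden-layer sizes from the empirical sizing formulas
#'
#' Two standard rules propose hidden-unit counts for `n` inputs and `m`
#' outputs: `n1 = floor(sqrt(n + m)) + a` for a constant `a` in 1..10, and
#' `n1 = log2(n)`. For 16 inputs and 1 output these give 5..14 and 4. The
#' default candidate set widens this union to 4..26, because empirically
#' selected optima (18 in the reference setting) can fall outside the
#' formula range.
#'
#' @param n input unit count (default 16).
#' @param m output unit count (default 1).
#' @param a constants for the square-root rule (default 1:10).
#' @param widen_to upper bound the candidate set is extended to
#'   (default 26); use `NULL` for the raw formula union.
#' @return Sorted integer vector of candidate hidden sizes.
#' @export
hidden_unit_candidates <- function(n = 16, m = 1, a = 1:10, widen_to = 26) {
  sqrt_rule <- floor(sqrt(n + m)) + a
  log_rule <- floor(log2(n))
  cand <- sort(unique(c(sqrt_rule, log_rule)))
  if (!is.null(widen_to)) cand <- seq(min(cand), max(widen_to, max(cand)))
  as.integer(cand)
}

#' Select the BPNN hidden-layer size by validation MSE
#'
#' Trains one BPNN per candidate on the training split and evaluates the mean
#' squared error on the validation split; returns the candidate with the
#' minimum MSE, breaking ties toward fewer units.
#'
#' @param X_train,y_train training split (normalized).
#' @param X_val,y_val validation split (normalized).
#' @param candidates integer vector of hidden sizes
#'   (default [hidden_unit_candidates()]).
#' @param cfg template [bpnn_config()]; `n_hidden` is overridden per
#'   candidate.
#' @return A list: `n_hidden` (selected), `mse` (named per-candidate
#'   validation MSE).
#' @export
select_hidden_units <- function(X_train, y_train, X_val, y_val,
                                candidates = hidden_unit_candidates(),
                                cfg = bpnn_config()) {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  mse <- vapply(candidates, function(h) {
    cfg_h <- cfg
    cfg_h$n_hidden <- as.integer(h)
    m <- train_bpnn(X_train, y_train, cfg_h)
    mean((predict_bpnn(m, X_val) - y_val)^2)
  }, numeric(1))
  names(mse) <- candidates
  best <- candidates[which.min(mse)]  # which.min takes the first (fewest units)
  list(n_hidden = as.integer(best), mse = mse)
}
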