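#' Sliding-window configuration for RMS feature extraction
#'
#' The RMS feature uses a continuous split window: width and increment are
#' equal, so windows tile the signal without overlap. With the default width
#' of 20 samples at 1200 Hz the feature rate is 60 Hz.
#'
#' @param width_N window width in sEMG samples (default 20).
#' @param increment_M window increment; must equal `width_N`.
#' @return A list of class `window_config`.
#' @export
window_config <- function(width_N = 20, increment_M = width_N) {
  check_scalar(width_N, "width_N")
  if (width_N < 1 || width_N != round(width_N)) {
    stop("`width_N` must be a positive integer", call. = FALSE)
  }
  if (increment_M != width_N) {
    stop("continuous split window requires increment_M == width_N",
         call. = FALSE)
  }
  structure(list(width_N = as.integer(width_N),
                 increment_M = as.integer(width_N)),
            class = "window_config")
}

#' Shift-point arithmetic for the time-advanced feature
#'
#' Muscle electrical activity precedes the resulting joint motion by an
#' electromechanical delay of roughly 20-200 ms. To pair sEMG with the angle
#' it *produces*, the angle sequence is lagged by `l` samples and the
#' concurrent sEMG stream by `k` samples, where
#' `l = ceil(delta_t * fs_angle)` and `k = l * fs_emg / fs_angle`.
#' The un-shifted sEMG stream then leads the lagged angle by `delta_t` and
#' supplies the time-advanced feature.
#'
#' @param delta_t advance time in seconds (>= 0; study default 0.2, sensible
#'   range 0.02-0.2).
#' @param fs_angle angle sampling rate in Hz.
#' @param fs_emg sEMG sampling rate in Hz (>= `fs_angle`).
#' @return A list of class `alignment_params` with fields `delta_t`,
#'   `fs_angle`, `fs_emg`, `l` (angle samples) and `k` (sEMG samples).
#' @export
compute_shift_points <- function(delta_t, fs_angle, fs_emg) {
  check_scalar(delta_t, "delta_t", positive = FALSE)
  if (delta_t < 0) stop("`delta_t` must be >= 0", call. = FALSE)
  check_scalar(fs_angle, "fs_angle")
  check_scalar(fs_emg, "fs_emg")
  if (fs_angle > fs_emg) stop("`fs_angle` must be <= `fs_emg`", call. = FALSE)
  l <- ceiling(delta_t * fs_angle)
  k <- l * fs_emg / fs_angle
  if (abs(k - round(k)) > 1e-9) {
    stop("shift k = l * fs_emg / fs_angle is not an integer", call. = FALSE)
  }
  structure(list(delta_t = delta_t, fs_angle = fs_angle, fs_emg = fs_emg,
                 l = as.integer(l), k = as.integer(round(k))),
            class = "alignment_params")
}

#' Non-overlapping window RMS of one signal
#'
#' Window `h` covers samples `(h-1)*N + offset_k + 1` through
#' `h*N + offset_k` (1-based, inclusive); the output value is the root mean
#' square of those samples. With `offset_k = 0` the series starts at the raw
#' signal origin and acts as the time-advanced feature relative to a lagged
#' angle; with `offset_k = k` it is the concurrent feature.
#'
#' @param x numeric signal vector.
#' @param cfg a [window_config()].
#' @param offset_k shift in samples (>= 0) applied before windowing.
#' @return Numeric vector of length `floor((length(x) - offset_k) / N)`.
#' @export
rms_windows <- function(x, cfg = window_config(), offset_k = 0) {
  stopifnot(inherits(cfg, "window_config"))
  n <- cfg$width_N
  usable <- length(x) - offset_k
  if (usable < n) stop("signal shorter than one window after the offset",
                       call. = FALSE)
  n_win <- usable %/% n
  xs <- x[(offset_k + 1):(offset_k + n_win * n)]^2
  sqrt(colMeans(matrix(xs, nrow = n)))
}

#' Smooth a feature series with a 5 Hz low-pass
#'
#' Raw window-RMS curves vibrate acutely; a second-order Butterworth low-pass
#' with a 5 Hz cut-off (zero-phase by default, to preserve the alignment the
#' shift arithmetic establishes) gives a smooth activation profile while
#' keeping everything at gait frequencies (< ~3 Hz) intact.
#'
#' @param f numeric feature series at rate `fs_feature`.
#' @param fs_feature feature sampling rate in Hz (default 60 = 1200/20).
#' @param cutoff_hz low-pass cut-off (default 5); must be below Nyquist.
#' @param zero_phase logical, forward-backward application (default TRUE).
#' @return Smoothed series, same length.
#' @export
smooth_feature <- function(f, fs_feature = 60, cutoff_hz = 5,
                           zero_phase = TRUE) {
  check_scalar(fs_feature, "fs_feature")
  if (cutoff_hz >= fs_feature / 2) {
    stop("cut-off must be below the feature-rate Nyquist frequency",
         call. = FALSE)
  }
  lp <- signal::butter(2, cutoff_hz / (fs_feature / 2), type = "low")
  if (zero_phase) zero_phase_apply(lp$b, lp$a, f)
  else as.numeric(signal::filter(lp, f))
}

#' Subsample (and optionally lag) the angle series to the feature rate
#'
#' Pairwise averaging halves the angle rate (120 -> 60 Hz, the feature rate).
#' Output value `h` is the mean of angle samples `2*(h-1) + lag_l + 1` through
#' `2*h + lag_l` (1-based), so `lag_l > 0` produces the lagged angle sequence
#' that the time-advanced sEMG features lead.
#'
#' @param angle an [angle_series] or plain numeric vector.
#' @param lag_l lag in angle samples (>= 0), typically `l` from
#'   [compute_shift_points()].
#' @return Numeric vector of length `floor((n - lag_l) / 2)`.
#' @export
subsample_angle <- function(angle, lag_l = 0) {
  v <- if (inherits(angle, "angle_series")) angle$values else as.numeric(angle)
  if (lag_l < 0 || lag_l != round(lag_l)) {
    stop("`lag_l` must be a nonnegative integer", call. = FALSE)
  }
  usable <- length(v) - lag_l
  if (usable < 2) stop("too few angle samples after the lag", call. = FALSE)
  n_out <- usable %/% 2
  vs <- v[(lag_l + 1):(lag_l + 2 * n_out)]
  colMeans(matrix(vs, nrow = 2))
}

#' Build the aligned 16-column RRTAF feature matrix and angle target
#'
#' For each muscle the concurrent RMS series (sEMG lagged by `k` samples)
#' and the time-advanced RMS series (un-lagged sEMG, leading the target by
#' `delta_t`) are extracted with non-overlapping windows, smoothed at 5 Hz,
#' and paired with the lagged, pairwise-subsampled angle. All series are
#' right-trimmed to their common length so row `t` of `X` is aligned with
#' `y[t]`. Columns are interleaved per muscle, concurrent before
#' time-advanced: `RF_rms, RF_rmstaf, BF_rms, BF_rmstaf, ...` -- with eight
#' muscles, the 16 model inputs.
#'
#' @param emg a preprocessed [emg_recording].
#' @param angle the synchronized [angle_series].
#' @param cfg a [window_config()].
#' @param ap an [compute_shift_points()] result consistent with the two
#'   sampling rates.
#' @param smooth logical; apply the 5 Hz feature smoothing (default TRUE).
#' @return A list of class `aligned_feature_set`: `X` (`[T x 2*n_muscles]`
#'   matrix with named columns), `y` (length-`T` angle target, degrees),
#'   `feature_names`, `fs_feature`, `ap`, `cfg`.
#' @export
build_aligned_features <- function(emg, angle, cfg = window_config(),
                                   ap, smooth = TRUE) {
  stopifnot(inherits(emg, "emg_recording"), inherits(angle, "angle_series"),
            inherits(cfg, "window_config"), inherits(ap, "alignment_params"))
  if (abs(ap$fs_emg - emg$fs_emg) > 1e-9 ||
      abs(ap$fs_angle - angle$fs_angle) > 1e-9) {
    stop("alignment params inconsistent with the recording rates",
         call. = FALSE)
  }
  dur_emg <- ncol(emg$samples) / emg$fs_emg
  dur_ang <- length(angle$values) / angle$fs_angle
  if (abs(dur_emg - dur_ang) > 0.5) {
    stop("sEMG and angle durations differ by more than 0.5 s", call. = FALSE)
  }
  fs_feature <- emg$fs_emg / cfg$width_N
  n_mus <- nrow(emg$samples)

  y <- subsample_angle(angle, lag_l = ap$l)
  feats <- vector("list", 2 * n_mus)
  nms <- character(2 * n_mus)
  for (m in seq_len(n_mus)) {
    conc <- rms_windows(emg$samples[m, ], cfg, offset_k = ap$k)
    adv <- rms_windows(emg$samples[m, ], cfg, offset_k = 0)
    if (smooth) {
      conc <- smooth_feature(conc, fs_feature)
      adv <- smooth_feature(adv, fs_feature)
    }
    feats[[2 * m - 1]] <- conc
    feats[[2 * m]] <- adv
    nms[2 * m - 1] <- paste0(emg$channel_names[m], "_rms")
    nms[2 * m] <- paste0(emg$channel_names[m], "_rmstaf")
  }
  T_common <- min(vapply(feats, length, 1L), length(y))
  X <- vapply(feats, function(f) f[seq_len(T_common)], numeric(T_common))
  colnames(X) <- nms
  structure(
    list(X = X, y = y[seq_len(T_common)], feature_names = nms,
         fs_feature = fs_feature, ap = ap, cfg = cfg),
    class = "aligned_feature_set"
  )
}

#' @export
print.aligned_feature_set <- function(x, ...) {
  cat(sprintf(
    "<aligned_feature_set> %d steps x %d features @ %g Hz (delta_t = %g s)\n",
    nrow(x$X), ncol(x$X), x$fs_feature, x$ap$delta_t
  ))
  invisible(x)
}

#' Select only the concurrent-RMS columns of a feature set
#'
#' Drops the time-advanced (`*_rmstaf`) columns, producing the 8-column
#' RMS-only input used as the baseline feature set in method comparisons.
#'
#' @param afs an [build_aligned_features()] result.
#' @return A new `aligned_feature_set` with half the columns.
#' @export
concurrent_only <- function(afs) {
  stopifnot(inherits(afs, "aligned_feature_set"))
  keep <- grep("_rms$", colnames(afs$X))
  afs$X <- afs$X[, keep, drop = FALSE]
  afs$feature_names <- colnames(afs$X)
  afs
}

#' Fit leakage-safe min-max normalization parameters
#'
#' Learns per-column minima/maxima of the feature matrix and of the target on
#' *training data only*, mapping them onto `[-1, 1]`:
#' `y = y_min + (y_max - y_min) * (x - x_min) / (x_max - x_min)`.
#' Test data must be transformed with these same parameters and may therefore
#' fall outside `[-1, 1]`; values are deliberately not clipped so the mapping
#' stays invertible.
#'
#' @param X training feature matrix.
#' @param y training target vector.
#' @param range target interval, default `c(-1, 1)`.
#' @return A list of class `normalization_params`.
#' @export
fit_normalization <- function(X, y, range = c(-1, 1)) {
  x_min <- apply(X, 2, min)
  x_max <- apply(X, 2, max)
  if (any(x_max - x_min <= 0)) {
    stop("degenerate (constant) feature column: cannot min-max normalize",
         call. = FALSE)
  }
  if (max(y) - min(y) <= 0) stop("degenerate target", call. = FALSE)
  structure(
    list(x_min = x_min, x_max = x_max, y_min = min(y), y_max = max(y),
         lo = range[1], hi = range[2], feature_names = colnames(X)),
    class = "normalization_params"
  )
}

minmax_map <- function(v, vmin, vmax, lo, hi) {
  lo + (hi - lo) * (v - vmin) / (vmax - vmin)
}

#' Apply (or invert) min-max normalization
#'
#' @param data a feature matrix (columns matching the fitted parameters) or,
#'   with `target = TRUE`, a target vector.
#' @param params a [fit_normalization()] result.
#' @param target logical; normalize the angle target rather than features.
#' @return Transformed data of the same shape.
#' @export
apply_normalization <- function(data, params, target = FALSE) {
  stopifnot(inherits(params, "normalization_params"))
  if (target) {
    return(minmax_map(data, params$y_min, params$y_max, params$lo, params$hi))
  }
  if (!is.null(colnames(data)) &&
      !identical(colnames(data), params$feature_names)) {
    stop("feature columns do not match the fitted normalization parameters",
         call. = FALSE)
  }
  out <- sweep(data, 2, params$x_min)
  out <- sweep(out, 2, params$x_max - params$x_min, "/")
  params$lo + (params$hi - params$lo) * out
}

#' @rdname apply_normalization
#' @param y_norm normalized target values to map back to degrees.
#' @export
invert_normalization <- function(y_norm, params) {
  stopifnot(inherits(params, "normalization_params"))
  params$y_min + (params$y_max - params$y_min) *
    (y_norm - params$lo) / (params$hi - params$lo)
}

#' Write / read an aligned feature set as CSV
#'
#' The matrix is stored with one column per feature plus a final
#' `angle_deg` target column; alignment metadata goes to a JSON sidecar.
#'
#' @param afs an `aligned_feature_set`.
#' @param path CSV path; the sidecar is `<path>.meta.json`.
#' @return `write_feature_set`: invisibly, `path`. `read_feature_set`: the
#'   reconstructed `aligned_feature_set`.
#' @export
write_feature_set <- function(afs, path) {
  stopifnot(inherits(afs, "aligned_feature_set"))
  df <- as.data.frame(afs$X)
  df$angle_deg <- afs$y
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs_feature = afs$fs_feature, delta_t = afs$ap$delta_t,
         fs_angle = afs$ap$fs_angle, fs_emg = afs$ap$fs_emg,
         width_N = afs$cfg$width_N),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  y <- df$angle_deg
  X <- as.matrix(df[setdiff(names(df), "angle_deg")])
  structure(
    list(X = X, y = y, feature_names = colnames(X),
         fs_feature = meta$fs_feature,
         ap = compute_shift_points(meta$delta_t, meta$fs_angle, meta$fs_emg),
         cfg = window_config(meta$width_N)),
    class = "aligned_feature_set"
  )
}
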