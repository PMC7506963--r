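#' Multichannel sEMG recording
#'
#' Container for raw or filtered surface-EMG samples. Channels are rows so a
#' recording is a `[n_channels x n_samples]` matrix in volts (or any linear
#' unit), with a sampling rate and per-channel muscle labels.
#'
#' @param samples numeric matrix `[n_channels x n_samples]`; a vector is
#'   treated as a single channel.
#' @param fs_emg sampling rate in Hz.
#' @param channel_names character vector of channel labels; defaults to the
#'   eight recorded lower-limb muscles ([DEFAULT_MUSCLES]) when the channel
#'   count matches, otherwise `ch1, ch2, ...`.
#' @return An object of class `emg_recording` with elements `samples`,
#'   `fs_emg`, `channel_names`.
#' @export
emg_recording <- function(samples, fs_emg, channel_names = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix [channels x samples]", call. = FALSE)
  }
  if (any(!is.finite(samples))) stop("sEMG samples contain NaN/Inf", call. = FALSE)
  check_scalar(fs_emg, "fs_emg")
  nc <- nrow(samples)
  if (is.null(channel_names)) {
    channel_names <- if (nc == length(DEFAULT_MUSCLES)) DEFAULT_MUSCLES else paste0("ch", seq_len(nc))
  }
  if (length(channel_names) != nc) {
    stop("length(channel_names) must equal nrow(samples)", call. = FALSE)
  }
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, fs_emg = fs_emg, channel_names = channel_names),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n  channels: %s\n",
    nrow(x$samples), ncol(x$samples), x$fs_emg, ncol(x$samples) / x$fs_emg,
    paste(x$channel_names, collapse = ", ")
  ))
  invisible(x)
}

#' Joint-angle series
#'
#' Scalar knee-joint angle samples in degrees at the motion-capture rate.
#'
#' @param values numeric vector of angles in degrees.
#' @param fs_angle sampling rate in Hz.
#' @return An object of class `angle_series` with elements `values`, `fs_angle`.
#' @export
angle_series <- function(values, fs_angle) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("`values` must be finite numeric", call. = FALSE)
  }
  check_scalar(fs_angle, "fs_angle")
  structure(list(values = as.numeric(values), fs_angle = fs_angle),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf(
    "<angle_series> %d samples @ %g Hz (%.2f s), range [%.1f, %.1f] deg\n",
    length(x$values), x$fs_angle, length(x$values) / x$fs_angle,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Write a synchronized sEMG + angle recording as delimited text
#'
#' Writes three files into `dir`: `<prefix>_emg.csv` (one column per muscle,
#' header row), `<prefix>_angle.csv` (single `angle_deg` column) and
#' `<prefix>_meta.json` (sampling rates plus any extra metadata such as the
#' simulator's ground-truth delay and seed).
#'
#' @param emg an [emg_recording].
#' @param angle an [angle_series].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default `"recording"`.
#' @param meta named list of extra metadata for the sidecar.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_recording <- function(emg, angle, dir, prefix = "recording", meta = list()) {
  stopifnot(inherits(emg, "emg_recording"), inherits(angle, "angle_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    emg = file.path(dir, paste0(prefix, "_emg.csv")),
    angle = file.path(dir, paste0(prefix, "_angle.csv")),
    meta = file.path(dir, paste0(prefix, "_meta.json"))
  )
  emg_df <- as.data.frame(t(emg$samples))
  names(emg_df) <- emg$channel_names
  utils::write.csv(emg_df, paths[["emg"]], row.names = FALSE)
  utils::write.csv(data.frame(angle_deg = angle$values), paths[["angle"]],
                   row.names = FALSE)
  meta_all <- c(list(fs_emg = emg$fs_emg, fs_angle = angle$fs_angle,
                     channel_names = emg$channel_names), meta)
  jsonlite::write_json(meta_all, paths[["meta"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back a recording written by [write_recording()]
#'
#' @param dir directory holding the three files.
#' @param prefix file-name prefix used at write time.
#' @return A list with elements `emg` ([emg_recording]), `angle`
#'   ([angle_series]) and `meta` (the parsed sidecar).
#' @export
read_recording <- function(dir, prefix = "recording") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  emg_df <- utils::read.csv(file.path(dir, paste0(prefix, "_emg.csv")),
                            check.names = FALSE)
  ang_df <- utils::read.csv(file.path(dir, paste0(prefix, "_angle.csv")))
  emg <- emg_recording(t(as.matrix(emg_df)), meta$fs_emg,
                       channel_names = names(emg_df))
  angle <- angle_series(ang_df$angle_deg, meta$fs_angle)
  list(emg = emg, angle = angle, meta = meta)
}

# run code with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
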