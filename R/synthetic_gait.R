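#' Configuration for the synthetic gait/sEMG simulator
#'
#' The simulator emulates treadmill walking at a steady cadence: a smooth
#' periodic knee-flexion trajectory sampled at the motion-capture rate, and
#' eight sEMG channels whose activation envelopes *lead* the angle by a known
#' electromechanical delay. It exists so that every downstream stage
#' (filtering, feature alignment, regression, evaluation) can be exercised
#' against a known ground truth.
#'
#' Defaults mirror a typical slow-walk acquisition: 1.2 s stride period
#' (about 1.0 m/s), sEMG at 1200 Hz, angle at 120 Hz, electromechanical delay
#' 0.2 s. They are stand-ins for real gait, not measurements of it.
#'
#' @param duration_s recording length in seconds (> 0).
#' @param stride_period_s gait-cycle period in seconds.
#' @param fs_emg sEMG sampling rate in Hz; must be an integer multiple of
#'   `fs_angle`.
#' @param fs_angle angle sampling rate in Hz.
#' @param delay_s ground-truth electromechanical lead of muscle activation
#'   over the angle, in seconds, within `[0, 0.25]`.
#' @param n_muscles number of sEMG channels (default 8).
#' @param interference_amp amplitude of an additive 50 Hz power-line
#'   component, relative to the unit-variance carrier.
#' @param noise_sd standard deviation of additive Gaussian measurement noise.
#' @param seed integer RNG seed; the one seeded generator drives all draws in
#'   a fixed order (per-muscle carrier noise first, then per-muscle
#'   measurement noise), so recordings are bitwise reproducible.
#' @param angle_coefs optional numeric vector `c(a0, c1, s1, c2, s2, c3, s3)`
#'   overriding the default 3-harmonic knee-flexion template (degrees):
#'   `theta(phi) = a0 + sum_j c_j*cos(j*phi) + s_j*sin(j*phi)`.
#' @param envelope `"gait"` (activation driven by the delayed angle, the
#'   default) or `"constant"` (all envelopes fixed at 1 -- a degenerate mode
#'   in which each channel reduces to its band-limited carrier, useful for
#'   testing stationarity).
#' @return A validated list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(duration_s,
                            stride_period_s = 1.2,
                            fs_emg = 1200,
                            fs_angle = 120,
                            delay_s = 0.2,
                            n_muscles = 8,
                            interference_amp = 0.1,
                            noise_sd = 0.05,
                            seed = 1L,
                            angle_coefs = NULL,
                            envelope = c("gait", "constant")) {
  envelope <- match.arg(envelope)
  check_scalar(duration_s, "duration_s")
  check_scalar(stride_period_s, "stride_period_s")
  check_scalar(fs_emg, "fs_emg")
  check_scalar(fs_angle, "fs_angle")
  check_scalar(delay_s, "delay_s", positive = FALSE)
  if (delay_s < 0 || delay_s > 0.25) {
    stop("`delay_s` must lie in [0, 0.25] seconds", call. = FALSE)
  }
  ratio <- fs_emg / fs_angle
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("`fs_emg` must be an integer multiple of `fs_angle`", call. = FALSE)
  }
  if (n_muscles < 1) stop("`n_muscles` must be >= 1", call. = FALSE)
  if (is.null(angle_coefs)) {
    # biphasic knee-flexion template: small stance-phase flexion wave plus a
    # dominant swing-phase peak, spanning roughly 0-70 degrees
    angle_coefs <- c(38, -9.6, 7.2, -19.2, 12, -4.8, 0)
  }
  if (length(angle_coefs) != 7) {
    stop("`angle_coefs` must have 7 elements: a0, c1, s1, c2, s2, c3, s3",
         call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, stride_period_s = stride_period_s,
         fs_emg = fs_emg, fs_angle = fs_angle, delay_s = delay_s,
         n_muscles = as.integer(n_muscles),
         interference_amp = interference_amp, noise_sd = noise_sd,
         seed = as.integer(seed), angle_coefs = angle_coefs,
         envelope = envelope),
    class = "gait_sim_config"
  )
}

# 3-harmonic angle template evaluated at stride phase phi (radians)
gait_angle_template <- function(phi, coefs) {
  coefs[1] +
    coefs[2] * cos(phi) + coefs[3] * sin(phi) +
    coefs[4] * cos(2 * phi) + coefs[5] * sin(2 * phi) +
    coefs[6] * cos(3 * phi) + coefs[7] * sin(3 * phi)
}

# analytic d(theta)/d(phi) of the template
gait_angle_template_deriv <- function(phi, coefs) {
  -coefs[2] * sin(phi) + coefs[3] * cos(phi) +
    2 * (-coefs[4] * sin(2 * phi) + coefs[5] * cos(2 * phi)) +
    3 * (-coefs[6] * sin(3 * phi) + coefs[7] * cos(3 * phi))
}

# nonnegative activation envelopes at fs_emg: each muscle mixes the
# standardized delayed angle and its derivative with a muscle-specific phase
# (psi_m), then half-wave rectifies, so activation leads the angle by delay_s
gait_envelopes <- function(config) {
  t_emg <- seq(0, config$duration_s - 1 / config$fs_emg, by = 1 / config$fs_emg)
  if (identical(config$envelope, "constant")) {
    return(matrix(1, nrow = config$n_muscles, ncol = length(t_emg)))
  }
  phi <- 2 * pi * (t_emg + config$delay_s) / config$stride_period_s
  th <- gait_angle_template(phi, config$angle_coefs)
  dth <- gait_angle_template_deriv(phi, config$angle_coefs) *
    (2 * pi / config$stride_period_s)
  zdiv <- function(v, s) if (s > 0) v / s else v * 0
  th_z <- zdiv(th - mean(th), stats::sd(th))
  dth_z <- zdiv(dth, stats::sd(dth))
  psi <- 2 * pi * (seq_len(config$n_muscles) - 1) / config$n_muscles
  env <- vapply(psi, function(p) pmax(cos(p) * th_z + sin(p) * dth_z, 0),
                numeric(length(t_emg)))
  t(env)  # [n_muscles x n_samples]
}

#' Simulate a synchronized sEMG + knee-angle recording
#'
#' Generates the angle trajectory at `fs_angle` and, per muscle, an amplitude
#' envelope at `fs_emg` that leads the angle by `delay_s`. Each sEMG channel
#' is the envelope multiplied by a band-limited (10-500 Hz) unit-variance
#' Gaussian carrier, plus an optional 50 Hz interference tone and white
#' measurement noise. Identical `config` (including `seed`) gives bitwise
#' identical output.
#'
#' @param config a [gait_sim_config()].
#' @return A list of class `synthetic_recording` with elements
#'   `emg` ([emg_recording]), `angle` ([angle_series]), `truth_delay_s`
#'   (exact delay used) and `truth_envelopes` (`[n_muscles x n_emg_samples]`,
#'   nonnegative).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  n_emg <- round(config$duration_s * config$fs_emg)
  n_ang <- round(config$duration_s * config$fs_angle)
  if (n_emg < 4 * config$fs_emg / 500 + 24) {
    stop("duration too short for the carrier band-pass warm-up", call. = FALSE)
  }

  t_emg <- seq(0, by = 1 / config$fs_emg, length.out = n_emg)
  t_ang <- seq(0, by = 1 / config$fs_angle, length.out = n_ang)

  phi_ang <- 2 * pi * t_ang / config$stride_period_s
  angle <- angle_series(gait_angle_template(phi_ang, config$angle_coefs),
                        config$fs_angle)

  env <- gait_envelopes(config)

  bp <- signal::butter(4, c(10, 500) / (config$fs_emg / 2), type = "pass")
  emg <- with_seed(config$seed, {
    carriers <- matrix(0, nrow = config$n_muscles, ncol = n_emg)
    for (m in seq_len(config$n_muscles)) {
      w <- stats::rnorm(n_emg)
      cw <- zero_phase_apply(bp$b, bp$a, w)
      carriers[m, ] <- cw / stats::sd(cw)
    }
    noise <- matrix(0, nrow = config$n_muscles, ncol = n_emg)
    if (config$noise_sd > 0) {
      for (m in seq_len(config$n_muscles)) {
        noise[m, ] <- stats::rnorm(n_emg, sd = config$noise_sd)
      }
    }
    interference <- config$interference_amp * sin(2 * pi * 50 * t_emg)
    env * carriers + rep(1, config$n_muscles) %o% interference + noise
  })

  muscles <- if (config$n_muscles == length(DEFAULT_MUSCLES)) {
    DEFAULT_MUSCLES
  } else {
    paste0("m", seq_len(config$n_muscles))
  }

  structure(
    list(emg = emg_recording(emg, config$fs_emg, channel_names = muscles),
         angle = angle,
         truth_delay_s = config$delay_s,
         truth_envelopes = env,
         config = config),
    class = "synthetic_recording"
  )
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %.1f s, delay %.3f s\n",
    x$config$duration_s, x$truth_delay_s
  ))
  print(x$emg)
  print(x$angle)
  invisible(x)
}
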