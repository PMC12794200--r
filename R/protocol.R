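#' Experimental protocol configuration
#'
#' Describes the bimanual circular-tracking session structure: each trial is
#' 1 s preparation, 6 s movement (one full clockwise rotation of the target
#' along a 20 cm diameter circle) and 2 s rest; 20 sessions of 10 trials give
#' 200 trials per subject. EEG is 32 channels at 256 Hz; the overhead camera
#' samples hand position at an unstable 400-600 Hz.
#'
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session.
#' @param prep_s,move_s,rest_s trial phase durations in seconds.
#' @param inter_session_rest_s rest between sessions in seconds (metadata
#'   only; sessions are simulated independently).
#' @param rotation_period_s seconds per full target rotation.
#' @param radius_cm circle radius in cm.
#' @param direction `"clockwise"` or `"counterclockwise"`.
#' @param eeg_rate_hz EEG sampling rate.
#' @param n_channels number of EEG channels (32-channel montage supported).
#' @param camera_rate_range_hz length-2 numeric, low/high instantaneous
#'   camera sampling rate.
#' @param camera_dropout_rate expected number of momentary tracking losses per
#'   trial (Poisson); losses are rare in the emulated recordings.
#' @return a `protocol_config` list.
#' @export
#' @examples
#' p <- protocol_config()
#' p$n_sessions * p$trials_per_session # 200 trials
protocol_config <- function(n_sessions = 20,
                            trials_per_session = 10,
                            prep_s = 1,
                            move_s = 6,
                            rest_s = 2,
                            inter_session_rest_s = 30,
                            rotation_period_s = 6,
                            radius_cm = 10,
                            direction = c("clockwise", "counterclockwise"),
                            eeg_rate_hz = 256,
                            n_channels = 32,
                            camera_rate_range_hz = c(400, 600),
                            camera_dropout_rate = 0.05) {
  direction <- match.arg(direction)
  assert_scalar_num(n_sessions, "n_sessions", lower = 1)
  assert_scalar_num(trials_per_session, "trials_per_session", lower = 1)
  for (nm in c("prep_s", "move_s", "rest_s", "rotation_period_s",
               "radius_cm", "eeg_rate_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      stop(sprintf("`%s` must be a positive number", nm), call. = FALSE)
    }
  }
  assert_scalar_num(inter_session_rest_s, "inter_session_rest_s", lower = 0)
  assert_scalar_num(camera_dropout_rate, "camera_dropout_rate", lower = 0)
  if (length(camera_rate_range_hz) != 2 ||
      camera_rate_range_hz[1] <= 0 ||
      camera_rate_range_hz[2] < camera_rate_range_hz[1]) {
    stop("`camera_rate_range_hz` must be an increasing positive pair",
         call. = FALSE)
  }
  if (n_channels != 32) {
    stop("only the 32-channel 10-10 montage is supported", call. = FALSE)
  }
  structure(list(
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    prep_s = prep_s, move_s = move_s, rest_s = rest_s,
    inter_session_rest_s = inter_session_rest_s,
    rotation_period_s = rotation_period_s,
    radius_cm = radius_cm,
    direction = direction,
    eeg_rate_hz = eeg_rate_hz,
    n_channels = as.integer(n_channels),
    camera_rate_range_hz = as.numeric(camera_rate_range_hz),
    camera_dropout_rate = camera_dropout_rate
  ), class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    "<protocol_config> %d sessions x %d trials; %g+%g+%g s per trial; %s rotation, r = %g cm; EEG %g Hz x %d ch; camera %g-%g Hz\n",
    x$n_sessions, x$trials_per_session, x$prep_s, x$move_s, x$rest_s,
    x$direction, x$radius_cm, x$eeg_rate_hz, x$n_channels,
    x$camera_rate_range_hz[1], x$camera_rate_range_hz[2]))
  invisible(x)
}

trial_duration_s <- function(protocol) {
  protocol$prep_s + protocol$move_s + protocol$rest_s
}

#' EEG signal-encoding configuration for the synthetic paradigm
#'
#' Controls the statistical structure written into synthetic EEG: the
#' angle-locked low-frequency components over motor channels (what the
#' decoders recover), alpha/beta oscillations with event-related
#' desynchronization during movement, a pre-movement slow negativity (MRCP),
#' ocular blink artifacts over frontal channels, spatially correlated pink
#' background activity and 50 Hz line noise.
#'
#' @param angle_gain amplitude (uV) of the cos/sin angle-locked components.
#' @param channel_topography 32 x 2 matrix of per-channel weights for the
#'   cosine and sine components; defaults to Gaussian bumps over C3 (cos) and
#'   C4 (sin).
#' @param erd_depth fractional alpha/beta amplitude reduction during movement,
#'   in `[0, 1]`.
#' @param alpha_amplitude,beta_amplitude resting oscillation amplitudes (uV).
#' @param mrcp_amplitude peak pre-movement slow negativity (uV) at central
#'   channels.
#' @param blink_rate_hz expected blink rate (subjects suppress blinks, so the
#'   default is low).
#' @param blink_amplitude_uv peak frontal blink deflection (uV).
#' @param line_noise_uv 50 Hz sinusoid amplitude (uV).
#' @param background_scale pink background RMS scale (uV).
#' @param seed integer seed for this encoding's randomness.
#' @return an `encoding_config` list.
#' @export
#' @examples
#' encoding_config(angle_gain = 25, background_scale = 5)
encoding_config <- function(angle_gain = 5,
                            channel_topography = NULL,
                            erd_depth = 0.3,
                            alpha_amplitude = 8,
                            beta_amplitude = 4,
                            mrcp_amplitude = 8,
                            blink_rate_hz = 0.1,
                            blink_amplitude_uv = 80,
                            line_noise_uv = 2,
                            background_scale = 20,
                            seed = 1L) {
  assert_scalar_num(angle_gain, "angle_gain", lower = 0)
  assert_scalar_num(erd_depth, "erd_depth", lower = 0, upper = 1)
  for (nm in c("alpha_amplitude", "beta_amplitude", "mrcp_amplitude",
               "blink_rate_hz", "blink_amplitude_uv", "line_noise_uv",
               "background_scale")) {
    assert_scalar_num(get(nm), nm, lower = 0)
  }
  if (is.null(channel_topography)) {
    channel_topography <- cbind(cos = channel_bump("C3") + 0.4 * channel_bump("Cz"),
                                sin = channel_bump("C4") + 0.4 * channel_bump("Cz"))
  }
  channel_topography <- as.matrix(channel_topography)
  if (nrow(channel_topography) != 32 || ncol(channel_topography) != 2) {
    stop("`channel_topography` must be a 32 x 2 matrix", call. = FALSE)
  }
  structure(list(
    angle_gain = angle_gain,
    channel_topography = channel_topography,
    erd_depth = erd_depth,
    alpha_amplitude = alpha_amplitude,
    beta_amplitude = beta_amplitude,
    mrcp_amplitude = mrcp_amplitude,
    blink_rate_hz = blink_rate_hz,
    blink_amplitude_uv = blink_amplitude_uv,
    line_noise_uv = line_noise_uv,
    background_scale = background_scale,
    seed = as.integer(seed)
  ), class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat(sprintf(
    "<encoding_config> angle gain %g uV; ERD depth %g; MRCP %g uV; blinks %g Hz; line %g uV; background %g uV; seed %d\n",
    x$angle_gain, x$erd_depth, x$mrcp_amplitude, x$blink_rate_hz,
    x$line_noise_uv, x$background_scale, x$seed))
  invisible(x)
}
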