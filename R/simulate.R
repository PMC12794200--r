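#' Simulate one trial's hand-tracking trajectory
#'
#' Generates the overhead-camera record of hand position for a single trial of
#' the circular-tracking task. The target starts at the rightmost point of the
#' circle and completes one full clockwise rotation at constant speed during
#' the movement period; the hand follows it through a first-order tracking lag
#' with additive smooth motor noise. Timestamps are irregular: inter-sample
#' intervals are drawn uniformly from the reciprocal of the configured camera
#' rate range, and rare momentary tracking losses are injected as far-off
#' outlier positions (to be repaired downstream).
#'
#' In the `[0, 2*pi)` angle representation, clockwise motion is generated as
#' `theta(t) = (2*pi - omega * t) %% (2*pi)` so the wrap sits at the trial's
#' start/end point and the interior of the rotation is continuous.
#'
#' @param protocol a [protocol_config()].
#' @param motor_noise_sd standard deviation (cm) of the smooth motor noise.
#' @param lag_s first-order tracking lag time constant in seconds (0 = the
#'   hand sits exactly on the target).
#' @param seed integer seed.
#' @return a tibble with columns `time` (s, strictly increasing, irregular),
#'   `x` and `y` (cm, relative to the circle center).
#' @export
#' @examples
#' tr <- simulate_trajectory(protocol_config(camera_dropout_rate = 0),
#'                           motor_noise_sd = 0, lag_s = 0, seed = 1)
#' range(sqrt(tr$x^2 + tr$y^2)) # exactly on the 10 cm circle
simulate_trajectory <- function(protocol = protocol_config(),
                                motor_noise_sd = 0.3,
                                lag_s = 0.1,
                                seed = 1L) {
  stopifnot(inherits(protocol, "protocol_config"))
  assert_scalar_num(motor_noise_sd, "motor_noise_sd", lower = 0)
  assert_scalar_num(lag_s, "lag_s", lower = 0)
  dur <- trial_duration_s(protocol)
  r <- protocol$radius_cm
  omega <- 2 * pi / protocol$rotation_period_s

  out <- withr::with_seed(as.integer(seed), {
    lo <- protocol$camera_rate_range_hz[1]
    hi <- protocol$camera_rate_range_hz[2]
    n_max <- ceiling(dur * hi) + 10
    dts <- runif(n_max, 1 / hi, 1 / lo)
    tt <- cumsum(c(0, dts))
    tt <- tt[tt <= dur]
    n <- length(tt)

    theta_t <- target_angle(tt, protocol)
    tx <- r * cos(theta_t)
    ty <- r * sin(theta_t)

    if (lag_s > 0) {
      hx <- numeric(n); hy <- numeric(n)
      hx[1] <- tx[1]; hy[1] <- ty[1]
      for (i in 2:n) {
        a <- 1 - exp(-(tt[i] - tt[i - 1]) / lag_s)
        hx[i] <- hx[i - 1] + a * (tx[i] - hx[i - 1])
        hy[i] <- hy[i - 1] + a * (ty[i] - hy[i - 1])
      }
    } else {
      hx <- tx; hy <- ty
    }

    if (motor_noise_sd > 0) {
      hx <- hx + smooth_noise(n, motor_noise_sd)
      hy <- hy + smooth_noise(n, motor_noise_sd)
    }

    n_drop <- rpois(1, protocol$camera_dropout_rate)
    if (n_drop > 0) {
      for (d in seq_len(n_drop)) {
        len <- sample(3:6, 1)
        start <- sample(seq_len(max(1, n - len)), 1)
        ang <- runif(1, 0, 2 * pi)
        off <- 50 * c(cos(ang), sin(ang))
        idx <- start:(start + len - 1)
        hx[idx] <- hx[idx] + off[1]
        hy[idx] <- hy[idx] + off[2]
      }
    }
    tibble::tibble(time = tt, x = hx, y = hy)
  })
  out
}

# target polar angle over the trial timeline; start/rest at the rightmost
# point (angle 0)
target_angle <- function(tt, protocol) {
  t0 <- protocol$prep_s
  t1 <- protocol$prep_s + protocol$move_s
  omega <- 2 * pi / protocol$rotation_period_s
  theta <- numeric(length(tt))
  moving <- tt >= t0 & tt < t1
  if (protocol$direction == "clockwise") {
    theta[moving] <- (2 * pi - omega * (tt[moving] - t0)) %% (2 * pi)
  } else {
    theta[moving] <- (omega * (tt[moving] - t0)) %% (2 * pi)
  }
  theta
}

# zero-mean smooth (moving-average filtered) gaussian noise with target sd
smooth_noise <- function(n, sd_target, k = 25) {
  w <- rnorm(n + k)
  s <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 1))
  s <- s[!is.na(s)][seq_len(n)]
  s <- s - mean(s)
  if (pop_sd(s) > 0) s <- s * (sd_target / pop_sd(s))
  s
}

#' Simulate one trial's EEG from its kinematics
#'
#' Builds a 32-channel EEG record at the protocol sampling rate containing
#' the signal structure the decoding analysis assumes: spatially correlated
#' pink background activity, angle-locked low-frequency components
#' (`angle_gain * [cos theta(t), sin theta(t)]` projected through the
#' configured channel topography, active only during movement), alpha and
#' beta oscillations whose envelope drops by `erd_depth` during movement
#' (ERD), a slow negative ramp beginning 1 s before movement onset at central
#' channels (MRCP), randomly timed frontal blink deflections, and a 50 Hz
#' line-noise sinusoid. Trigger samples mark preparation onset, movement
#' onset and movement offset.
#'
#' @param trace kinematics tibble from [simulate_trajectory()], covering the
#'   full trial timeline.
#' @param protocol a [protocol_config()].
#' @param encoding an [encoding_config()].
#' @param trial_id,session_id identifiers stored in the recording.
#' @param seed integer seed; defaults to the encoding seed.
#' @return a `trial_recording`: list with elements `eeg` (32 x samples matrix,
#'   uV, channel rownames), `rate`, `triggers` (1-based sample indices
#'   `prep_onset`, `move_onset`, `move_offset`), `kinematics`, `trial_id`,
#'   `session_id`.
#' @export
simulate_eeg <- function(trace, protocol = protocol_config(),
                         encoding = encoding_config(),
                         trial_id = 1L, session_id = 1L,
                         seed = encoding$seed) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(encoding, "encoding_config"))
  dur <- trial_duration_s(protocol)
  if (max(trace$time) < dur - 0.05 || min(trace$time) > 0.05) {
    stop("kinematics trace does not cover the full trial timeline",
         call. = FALSE)
  }
  fs <- protocol$eeg_rate_hz
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  nch <- protocol$n_channels
  mont <- montage_positions()

  eeg <- withr::with_seed(as.integer(seed), {
    x <- pink_background(nch, n, fs, encoding$background_scale, mont)

    t_m0 <- protocol$prep_s
    t_m1 <- protocol$prep_s + protocol$move_s
    movewin <- move_window(tt, t_m0, t_m1, ramp_s = 0.1)

    if (encoding$angle_gain > 0) {
      hx <- approx(trace$time, trace$x, xout = tt, rule = 2)$y
      hy <- approx(trace$time, trace$y, xout = tt, rule = 2)$y
      th <- to_polar(hx, hy)
      comp <- rbind(cos(th), sin(th)) * rep(movewin, each = 2)
      x <- x + encoding$angle_gain * (encoding$channel_topography %*% comp)
    }

    osc_topo_l <- channel_bump("C3", 0.5)
    osc_topo_r <- channel_bump("C4", 0.5)
    erd_env <- 1 - encoding$erd_depth * movewin
    for (band in list(c(10, encoding$alpha_amplitude),
                      c(20, encoding$beta_amplitude))) {
      if (band[2] > 0) {
        for (topo in list(osc_topo_l, osc_topo_r)) {
          env <- 0.5 + abs(smooth_noise(n, 1, k = round(fs / 2)))
          src <- band[2] * env * erd_env * sin(2 * pi * band[1] * tt + runif(1, 0, 2 * pi))
          x <- x + outer(topo, src)
        }
      }
    }

    if (encoding$mrcp_amplitude > 0) {
      ramp <- mrcp_shape(tt, t_m0, t_m1)
      topo <- channel_bump("Cz", 0.6)
      x <- x - encoding$mrcp_amplitude * outer(topo, ramp)
    }

    if (encoding$blink_rate_hz > 0) {
      n_b <- rpois(1, encoding$blink_rate_hz * dur)
      if (n_b > 0) {
        topo <- channel_bump("Fp1", 0.45) + channel_bump("Fp2", 0.45)
        topo <- topo / max(topo)
        blink_len <- round(0.35 * fs)
        wave <- encoding$blink_amplitude_uv *
          (0.5 - 0.5 * cos(2 * pi * seq_len(blink_len) / (blink_len + 1)))
        for (bt in runif(n_b, 0, dur - 0.4)) {
          i0 <- round(bt * fs) + 1
          idx <- i0:(i0 + blink_len - 1)
          x[, idx] <- x[, idx] + outer(topo, wave)
        }
      }
    }

    if (encoding$line_noise_uv > 0) {
      gain <- runif(nch, 0.8, 1.2)
      x <- x + outer(gain, encoding$line_noise_uv *
                       sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi)))
    }
    x
  })
  rownames(eeg) <- mont$channel

  structure(list(
    eeg = eeg,
    rate = fs,
    triggers = list(
      prep_onset = 1L,
      move_onset = as.integer(round(protocol$prep_s * fs)) + 1L,
      move_offset = as.integer(round((protocol$prep_s + protocol$move_s) * fs)) + 1L
    ),
    kinematics = trace,
    trial_id = as.integer(trial_id),
    session_id = as.integer(session_id)
  ), class = "trial_recording")
}

# smooth 0/1 movement indicator with raised-cosine ramps inside the window,
# exactly zero outside it
move_window <- function(tt, t0, t1, ramp_s = 0.1) {
  w <- numeric(length(tt))
  inside <- tt >= t0 & tt < t1
  w[inside] <- 1
  up <- tt >= t0 & tt < t0 + ramp_s
  w[up] <- 0.5 - 0.5 * cos(pi * (tt[up] - t0) / ramp_s)
  down <- tt >= t1 - ramp_s & tt < t1
  w[down] <- 0.5 - 0.5 * cos(pi * (t1 - tt[down]) / ramp_s)
  w
}

# slow negativity: linear ramp over the second before movement onset, hold
# during movement, 1 s linear recovery after offset
mrcp_shape <- function(tt, t_m0, t_m1) {
  s <- numeric(length(tt))
  pre <- tt >= t_m0 - 1 & tt < t_m0
  s[pre] <- (tt[pre] - (t_m0 - 1))
  s[tt >= t_m0 & tt < t_m1] <- 1
  post <- tt >= t_m1 & tt < t_m1 + 1
  s[post] <- 1 - (tt[post] - t_m1)
  s
}

# spatially correlated pink noise: per-channel 1/f-amplitude-shaped white
# noise mixed through a distance-based matrix for realistic inter-channel
# correlation
pink_background <- function(nch, n, fs, scale, mont) {
  if (scale <= 0) return(matrix(0, nch, n))
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  amp <- 1 / pmax(f, 0.5)
  amp[1] <- 0 # no DC
  w <- matrix(rnorm(nch * n), nch, n)
  for (c in seq_len(nch)) {
    z <- fft(w[c, ])
    half <- seq_along(amp)
    shaped <- z
    shaped[half] <- z[half] * amp
    if (n %% 2 == 0) {
      shaped[(n / 2 + 2):n] <- Conj(shaped[seq(n / 2, 2)])
    } else {
      shaped[((n + 1) / 2 + 1):n] <- Conj(shaped[seq((n + 1) / 2, 2)])
    }
    w[c, ] <- Re(fft(shaped, inverse = TRUE)) / n
  }
  pos <- as.matrix(mont[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  mix <- exp(-d^2 / (2 * 0.6^2))
  mix <- mix / sqrt(rowSums(mix^2))
  x <- mix %*% w
  x * (scale / mean(apply(x, 1, pop_sd)))
}

#' Simulate a full subject dataset
#'
#' Generates `n_sessions x trials_per_session` trials (200 under the default
#' protocol), with per-trial seeds derived deterministically from the
#' encoding's master seed via [derive_seed()], so the same configuration
#' always reproduces an identical dataset.
#'
#' @param protocol a [protocol_config()].
#' @param encoding an [encoding_config()]; its `seed` is the master seed.
#' @param motor_noise_sd,lag_s trajectory parameters, see
#'   [simulate_trajectory()].
#' @return a list of `trial_recording` objects with attributes `protocol` and
#'   `encoding`.
#' @export
#' @examples
#' trials <- simulate_subject(protocol_config(n_sessions = 2,
#'                                            trials_per_session = 3),
#'                            encoding_config(seed = 7))
#' length(trials) # 6
simulate_subject <- function(protocol = protocol_config(),
                             encoding = encoding_config(),
                             motor_noise_sd = 0.3, lag_s = 0.1) {
  trials <- vector("list", protocol$n_sessions * protocol$trials_per_session)
  k <- 0L
  for (s in seq_len(protocol$n_sessions)) {
    for (tr in seq_len(protocol$trials_per_session)) {
      k <- k + 1L
      tr_seed <- derive_seed(encoding$seed, 2L * k)
      eeg_seed <- derive_seed(encoding$seed, 2L * k + 1L)
      trace <- simulate_trajectory(protocol, motor_noise_sd, lag_s,
                                   seed = tr_seed)
      trials[[k]] <- simulate_eeg(trace, protocol, encoding,
                                  trial_id = k, session_id = s,
                                  seed = eeg_seed)
    }
  }
  attr(trials, "protocol") <- protocol
  attr(trials, "encoding") <- encoding
  class(trials) <- "subject_recordings"
  trials
}

#' Assemble per-trial recordings into continuous session recordings
#'
#' Concatenates the trials of each session into one continuous EEG matrix
#' (sessions run trials back to back) and re-expresses triggers as absolute
#' sample indices, the form the preprocessing chain (notably per-session ICA)
#' operates on.
#'
#' @param trials a `subject_recordings` list from [simulate_subject()].
#' @return a list of `session_recording` objects: `eeg`, `rate`, `triggers`
#'   (tibble with `trial_id` and the three trigger sample columns), and the
#'   per-trial `kinematics`.
#' @export
sessions_from_trials <- function(trials) {
  stopifnot(length(trials) > 0)
  sess_ids <- vapply(trials, function(x) x$session_id, integer(1))
  lapply(unique(sess_ids), function(sid) {
    tr <- trials[sess_ids == sid]
    ns <- vapply(tr, function(x) ncol(x$eeg), integer(1))
    off <- cumsum(c(0L, head(ns, -1)))
    trig <- tibble::tibble(
      trial_id = vapply(tr, function(x) x$trial_id, integer(1)),
      prep_onset = vapply(tr, function(x) x$triggers$prep_onset, integer(1)) + off,
      move_onset = vapply(tr, function(x) x$triggers$move_onset, integer(1)) + off,
      move_offset = vapply(tr, function(x) x$triggers$move_offset, integer(1)) + off
    )
    structure(list(
      eeg = do.call(cbind, lapply(tr, function(x) x$eeg)),
      rate = tr[[1]]$rate,
      triggers = trig,
      kinematics = lapply(tr, function(x) x$kinematics),
      session_id = sid
    ), class = "session_recording")
  })
}

#' Write a subject dataset to plain-text files
#'
#' One EEG CSV per session (channels as columns), one kinematics CSV per trial
#' (`time,x,y`), a triggers CSV per session, and a JSON sidecar recording the
#' protocol and encoding configuration including all seeds.
#'
#' @param trials a `subject_recordings` list.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- sessions_from_trials(trials)
  for (s in sessions) {
    write.csv(t(s$eeg), file.path(dir, sprintf("session%02d_eeg.csv", s$session_id)),
              row.names = FALSE)
    write.csv(s$triggers, file.path(dir, sprintf("session%02d_triggers.csv",
                                                 s$session_id)),
              row.names = FALSE)
  }
  for (tr in trials) {
    write.csv(tr$kinematics,
              file.path(dir, sprintf("trial%03d_kinematics.csv", tr$trial_id)),
              row.names = FALSE)
  }
  enc <- attr(trials, "encoding")
  proto <- attr(trials, "protocol")
  sidecar <- list(
    protocol = unclass(proto),
    encoding = c(unclass(enc)[setdiff(names(enc), "channel_topography")],
                 list(channel_topography = as.data.frame(enc$channel_topography)))
  )
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
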