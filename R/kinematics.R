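#' Cartesian-to-polar angle conversion on `[0, 2*pi)`
#'
#' Converts hand positions (relative to the circle center) to polar angles,
#' constrained to `[0, 2*pi)` rather than `(-pi, pi]` so that the continuous
#' rotation has no discontinuity in the interior of a trial. The quadrant
#' branches are:
#' \itemize{
#'   \item `arctan(y/x)` for `x > 0, y > 0`
#'   \item `pi + arctan(y/x)` for `x < 0, y != 0` (and, by continuity of this
#'     branch, `pi` for `x < 0, y = 0`)
#'   \item `2*pi + arctan(y/x)` for `x > 0, y < 0`
#'   \item special cases: `0` if `x >= 0, y = 0`; `0.5*pi` if `x = 0, y > 0`;
#'     `1.5*pi` if `x = 0, y < 0`.
#' }
#'
#' @param x,y numeric vectors of equal length (cm, centered coordinates).
#' @return numeric vector of angles in radians, all in `[0, 2*pi)`; never
#'   exactly `2*pi`.
#' @export
#' @examples
#' to_polar(c(1, 0, -1, 0), c(0, 1, 0, -1)) / pi # 0, 0.5, 1, 1.5
to_polar <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x == 0 & y == 0)) {
    stop("polar angle undefined at the origin (x = 0, y = 0)", call. = FALSE)
  }
  theta <- numeric(length(x))
  q1 <- x > 0 & y > 0
  theta[q1] <- atan(y[q1] / x[q1])
  q2 <- x < 0 # includes y = 0: pi + arctan(0) = pi
  theta[q2] <- pi + atan(y[q2] / x[q2])
  q4 <- x > 0 & y < 0
  theta[q4] <- 2 * pi + atan(y[q4] / x[q4])
  theta[x >= 0 & y == 0] <- 0
  theta[x == 0 & y > 0] <- 0.5 * pi
  theta[x == 0 & y < 0] <- 1.5 * pi
  # guard against rounding to the open upper bound
  theta[theta >= 2 * pi] <- 0
  theta
}

#' Resample an irregular kinematics trace to a uniform rate
#'
#' The camera's frame rate fluctuates between 400 and 600 Hz, so positions are
#' linearly interpolated onto a uniform grid (1 kHz by default) spanning the
#' input range.
#'
#' @param trace tibble with `time`, `x`, `y` (strictly increasing `time`).
#' @param target_rate output sampling rate in Hz.
#' @return a tibble with uniform `time` and interpolated `x`, `y`.
#' @export
resample_uniform <- function(trace, target_rate = 1000) {
  if (nrow(trace) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(trace$time) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  tt <- seq(trace$time[1], trace$time[nrow(trace)], by = 1 / target_rate)
  tibble::tibble(
    time = tt,
    x = approx(trace$time, trace$x, xout = tt)$y,
    y = approx(trace$time, trace$y, xout = tt)$y
  )
}

#' Repair momentary tracking losses in a kinematics trace
#'
#' A sample whose distance to both temporal neighbors exceeds
#' `jump_threshold` is replaced by the mean of the preceding and following
#' points (boundary samples are compared to, and replaced by, their single
#' neighbor). The rule is applied iteratively so that short runs of outliers
#' are peeled from both ends; runs still present after `max_run` passes are
#' flagged in the repair report and bridged linearly.
#'
#' @param trace tibble with `time`, `x`, `y`.
#' @param jump_threshold neighbor-distance threshold in cm.
#' @param max_run maximum outlier run length repaired by neighbor averaging.
#' @return the repaired tibble; attribute `repair_report` lists
#'   `n_replaced` and `n_bridged`.
#' @export
repair_outliers <- function(trace, jump_threshold = 3, max_run = 10) {
  x <- trace$x
  y <- trace$y
  n <- length(x)
  n_replaced <- 0L
  for (pass in seq_len(max_run)) {
    bad <- find_jump_outliers(x, y, jump_threshold)
    if (!any(bad)) break
    idx <- which(bad)
    xr <- x; yr <- y
    for (i in idx) {
      lo <- if (i > 1) i - 1L else i + 1L
      hi <- if (i < n) i + 1L else i - 1L
      xr[i] <- (x[lo] + x[hi]) / 2
      yr[i] <- (y[lo] + y[hi]) / 2
    }
    x <- xr; y <- yr
    n_replaced <- n_replaced + length(idx)
  }
  # bridge anything that survived (long dropout runs)
  bad <- find_jump_outliers(x, y, jump_threshold)
  n_bridged <- 0L
  if (any(bad)) {
    good <- which(!bad)
    if (length(good) >= 2) {
      x[bad] <- approx(good, x[good], xout = which(bad), rule = 2)$y
      y[bad] <- approx(good, y[good], xout = which(bad), rule = 2)$y
      n_bridged <- sum(bad)
    }
  }
  out <- tibble::tibble(time = trace$time, x = x, y = y)
  attr(out, "repair_report") <- list(n_replaced = n_replaced,
                                     n_bridged = n_bridged)
  out
}

# outlier = farther than threshold from every temporal neighbor it has
find_jump_outliers <- function(x, y, threshold) {
  n <- length(x)
  d_prev <- c(Inf, sqrt(diff(x)^2 + diff(y)^2))
  d_next <- c(sqrt(diff(x)^2 + diff(y)^2), Inf)
  far_prev <- d_prev > threshold
  far_next <- d_next > threshold
  bad <- far_prev & far_next
  bad[1] <- far_next[1]
  bad[n] <- far_prev[n]
  bad
}

#' Least-squares circle fit
#'
#' Estimates the circle center (and radius) from tracked positions, standing
#' in for the unrecorded screen/camera calibration. Uses the algebraic
#' (Kasa) least-squares fit.
#'
#' @param x,y numeric position vectors (cm).
#' @return list with `center` (length-2) and `radius`.
#' @export
fit_circle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  list(center = c(sol[1], sol[2]),
       radius = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

#' Convert a centered uniform trace to a polar-angle series
#'
#' @param trace uniform tibble with `time`, `x`, `y`.
#' @param center length-2 circle center to subtract; `NULL` fits one with
#'   [fit_circle()].
#' @return tibble with `time`, `theta` (radians in `[0, 2*pi)`).
#' @export
polar_trace <- function(trace, center = NULL) {
  if (is.null(center)) center <- fit_circle(trace$x, trace$y)$center
  tibble::tibble(time = trace$time,
                 theta = to_polar(trace$x - center[1], trace$y - center[2]))
}

# wrap-safe decimation of an angle series: low-pass the cos/sin embedding
# (anti-alias FIR), decimate, and convert back through the polar branches
decimate_angle <- function(theta, in_rate, out_rate) {
  stopifnot(in_rate %% out_rate == 0)
  factor <- in_rate / out_rate
  cutoff <- 0.4 * out_rate
  b <- signal::fir1(120, cutoff / (in_rate / 2))
  cs <- fir_filtfilt(cos(theta), b)
  sn <- fir_filtfilt(sin(theta), b)
  keep <- seq(1, length(theta), by = factor)
  to_polar(cs[keep], sn[keep])
}

#' Cut a polar-angle trace into the per-trial analysis epoch
#'
#' Synchronizes the angle series with the EEG triggers and extracts the
#' analysis epoch: the last 0.5 s of preparation, the whole movement period
#' and the first 0.5 s of rest, then downsamples to 100 Hz (wrap-safe
#' cos/sin decimation with anti-alias filtering). Under the default protocol
#' each epoch has 700 samples.
#'
#' @param theta_trace tibble with uniform `time` and `theta` (from
#'   [polar_trace()]).
#' @param move_onset_s,move_offset_s movement onset/offset in trace time
#'   (seconds), from the recorded triggers.
#' @param pad_s seconds kept before onset and after offset.
#' @param out_rate label sampling rate in Hz.
#' @param trial_id identifier used in error messages and the result.
#' @return an `angle_epoch`: list with `theta` (radians at `out_rate`),
#'   `rate`, `trial_id`.
#' @export
synchronize_and_epoch <- function(theta_trace, move_onset_s, move_offset_s,
                                  pad_s = 0.5, out_rate = 100,
                                  trial_id = 1L) {
  tt <- theta_trace$time
  in_rate <- round(1 / median(diff(tt)))
  t0 <- move_onset_s - pad_s
  t1 <- move_offset_s + pad_s
  i0 <- round((t0 - tt[1]) * in_rate) + 1
  n_in <- round((t1 - t0) * in_rate)
  if (i0 < 1 || i0 + n_in - 1 > length(tt)) {
    stop(sprintf("trial %s: analysis epoch [%g, %g] s exceeds the angle trace bounds",
                 trial_id, t0, t1), call. = FALSE)
  }
  th <- theta_trace$theta[i0:(i0 + n_in - 1)]
  structure(list(
    theta = decimate_angle(th, in_rate, out_rate),
    rate = out_rate,
    trial_id = as.integer(trial_id)
  ), class = "angle_epoch")
}

#' Angle labels for every trial of a subject
#'
#' Runs the full kinematics chain per trial: uniform 1 kHz resampling,
#' outlier repair, session-level circle-center fit, polar conversion and
#' epoching at 100 Hz.
#'
#' @param trials a `subject_recordings` list from [simulate_subject()].
#' @param jump_threshold outlier repair threshold (cm).
#' @return list of `angle_epoch` objects, one per trial, in trial order.
#' @export
compute_angle_epochs <- function(trials, jump_threshold = 3) {
  sess_ids <- vapply(trials, function(x) x$session_id, integer(1))
  epochs <- vector("list", length(trials))
  for (sid in unique(sess_ids)) {
    idx <- which(sess_ids == sid)
    uniform <- lapply(idx, function(i) {
      repair_outliers(resample_uniform(trials[[i]]$kinematics, 1000),
                      jump_threshold)
    })
    ctr <- fit_circle(unlist(lapply(uniform, `[[`, "x")),
                      unlist(lapply(uniform, `[[`, "y")))$center
    for (j in seq_along(idx)) {
      i <- idx[j]
      trig <- trials[[i]]$triggers
      fs <- trials[[i]]$rate
      epochs[[i]] <- synchronize_and_epoch(
        polar_trace(uniform[[j]], ctr),
        move_onset_s = (trig$move_onset - 1) / fs,
        move_offset_s = (trig$move_offset - 1) / fs,
        trial_id = trials[[i]]$trial_id
      )
    }
  }
  epochs
}
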