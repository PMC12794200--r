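#' Preprocessing configuration
#'
#' Collects every parameter of the EEG cleaning chain. The pipeline order is
#' fixed: notch, zero-phase FIR band-pass, bad-channel interpolation, common
#' average reference, per-session ICA ocular removal (fit on a 1 Hz
#' high-passed copy, applied to the broadband data), then epoching with
#' baseline correction and downsampling to 100 Hz.
#'
#' @param notch_hz line frequency for the notch filter.
#' @param bandpass pass band in Hz.
#' @param ica_fit_highpass_hz high-pass cutoff for the ICA fitting copy.
#' @param ocular_score_threshold components scoring at or above this are
#'   removed (see [score_ocular_components()]).
#' @param max_removed_components cap on removed components per session.
#' @param baseline_window seconds relative to movement onset, default
#'   `c(-1, 0)`.
#' @param epoch_window analysis epoch in seconds relative to movement onset,
#'   default `c(-0.5, 6.5)`.
#' @param out_rate epoch sampling rate after downsampling (Hz).
#' @param bad_z robust z-score threshold on log channel variance.
#' @param bad_corr flag channels whose best absolute correlation with any
#'   other channel falls below this.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(notch_hz = 50,
                              bandpass = c(0.1, 30),
                              ica_fit_highpass_hz = 1,
                              ocular_score_threshold = 0.85,
                              max_removed_components = 3,
                              baseline_window = c(-1, 0),
                              epoch_window = c(-0.5, 6.5),
                              out_rate = 100,
                              bad_z = 5,
                              bad_corr = 0.2) {
  stopifnot(bandpass[1] < bandpass[2], max_removed_components >= 0)
  structure(list(
    notch_hz = notch_hz, bandpass = bandpass,
    ica_fit_highpass_hz = ica_fit_highpass_hz,
    ocular_score_threshold = ocular_score_threshold,
    max_removed_components = as.integer(max_removed_components),
    baseline_window = baseline_window,
    epoch_window = epoch_window,
    out_rate = out_rate,
    bad_z = bad_z, bad_corr = bad_corr
  ), class = "preprocess_config")
}

#' Automated bad-channel detection
#'
#' Flags channels whose robust z-score of log-variance exceeds `z_thresh`
#' (dead or saturated channels) or whose best absolute correlation with any
#' other channel falls below `corr_thresh` (disconnected channels). This is
#' an automated, reproducible proxy for visual channel inspection.
#'
#' @param eeg channels x samples matrix.
#' @param z_thresh robust z threshold on log variance.
#' @param corr_thresh minimum best-neighbor absolute correlation.
#' @return integer vector of flagged channel indices (possibly empty).
#' @export
detect_bad_channels <- function(eeg, z_thresh = 5, corr_thresh = 0.2) {
  stopifnot(is.matrix(eeg), nrow(eeg) >= 2)
  v <- apply(eeg, 1, var)
  flat <- v <= .Machine$double.eps
  lv <- log(pmax(v, .Machine$double.xmin))
  med <- median(lv)
  madv <- median(abs(lv - med)) * 1.4826
  z <- if (madv > 0) (lv - med) / madv else rep(0, length(lv))
  by_var <- abs(z) > z_thresh
  ok <- !flat
  by_corr <- rep(FALSE, nrow(eeg))
  if (sum(ok) >= 2) {
    cc <- abs(cor(t(eeg[ok, , drop = FALSE])))
    diag(cc) <- 0
    best <- apply(cc, 1, max)
    by_corr[which(ok)[best < corr_thresh]] <- TRUE
  }
  sort(unique(which(flat | by_var | by_corr)))
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces flagged channels with spherical-spline estimates from the
#' remaining electrodes (Perrin-style thin-plate spline on the unit sphere,
#' order m = 4, 50 Legendre terms, ridge 1e-5). If the spline system is
#' numerically singular the affected channel falls back to inverse-distance
#' weighting, which is noted in the attached log.
#'
#' @param eeg channels x samples matrix (32 rows, montage order).
#' @param bad integer indices of channels to replace.
#' @param montage tibble of electrode positions, default [montage_1010_32()].
#' @return the matrix with bad rows replaced; attribute `interp_log`.
#' @export
interpolate_channels <- function(eeg, bad, montage = montage_1010_32()) {
  if (length(bad) == 0) return(eeg)
  if (length(bad) > 0.25 * nrow(eeg)) {
    stop("more than 25% of channels flagged bad; interpolation unreliable",
         call. = FALSE)
  }
  pos <- as.matrix(montage[, c("x", "y", "z")])
  good <- setdiff(seq_len(nrow(eeg)), bad)
  fallback <- character(0)
  Gg <- spline_g(pos[good, , drop = FALSE] %*% t(pos[good, , drop = FALSE]))
  A <- rbind(cbind(Gg + diag(1e-5, length(good)), 1), c(rep(1, length(good)), 0))
  rhs <- rbind(eeg[good, , drop = FALSE], 0)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (!is.null(sol)) {
    gb <- spline_g(pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE]))
    eeg[bad, ] <- cbind(gb, 1) %*% sol
  } else {
    for (b in bad) {
      d <- acos(pmin(1, pmax(-1, pos[good, , drop = FALSE] %*% pos[b, ])))
      w <- 1 / pmax(d, 1e-3)^2
      eeg[b, ] <- (w / sum(w)) %*% eeg[good, , drop = FALSE]
      fallback <- c(fallback, montage$channel[b])
    }
  }
  attr(eeg, "interp_log") <- list(interpolated = montage$channel[bad],
                                  idw_fallback = fallback)
  eeg
}

# spherical-spline kernel g(cos angle) with order m = 4
spline_g <- function(cosang, m = 4, n_terms = 50) {
  cosang <- pmin(pmax(cosang, -1), 1) # keep dims: matrix first
  g <- matrix(0, nrow(cosang), ncol(cosang))
  p_nm1 <- matrix(1, nrow(cosang), ncol(cosang)) # P_0
  p_n <- cosang                                  # P_1
  for (n in seq_len(n_terms)) {
    g <- g + ((2 * n + 1) / (n^m * (n + 1)^m)) * p_n
    p_np1 <- ((2 * n + 1) * cosang * p_n - n * p_nm1) / (n + 1)
    p_nm1 <- p_n
    p_n <- p_np1
  }
  g / (4 * pi)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every channel, so the
#' across-channel mean is zero at each sample.
#'
#' @param eeg channels x samples matrix (at least 2 channels).
#' @return re-referenced matrix.
#' @export
common_average_reference <- function(eeg) {
  if (!is.matrix(eeg) || nrow(eeg) < 2) {
    stop("common average reference needs at least 2 channels", call. = FALSE)
  }
  sweep(eeg, 2, colMeans(eeg))
}

#' Score independent components for ocularity
#'
#' Deterministic stand-in for a trained component classifier: each
#' component's score is the product of (a) its frontal topography
#' concentration (mean absolute mixing weight over Fp/AF/F electrodes
#' relative to all electrodes, halved and saturated at 1) and (b) the
#' fraction of its source power below 4 Hz. Blink components concentrate
#' weight frontally and power at low frequency, scoring near 1; diffuse
#' background components score well below the default 0.85 threshold.
#'
#' @param mixing channels x components mixing matrix.
#' @param sources components x samples source matrix.
#' @param rate sampling rate in Hz.
#' @param montage electrode table, default [montage_1010_32()].
#' @return numeric score per component, in `[0, 1]`.
#' @export
score_ocular_components <- function(mixing, sources, rate,
                                    montage = montage_1010_32()) {
  fr <- montage$channel %in% frontal_channels()
  n <- ncol(sources)
  f <- seq(0, rate / 2, length.out = floor(n / 2) + 1)
  vapply(seq_len(ncol(mixing)), function(j) {
    a <- abs(mixing[, j])
    conc <- mean(a[fr]) / max(mean(a), .Machine$double.eps)
    pw <- Mod(fft(sources[j, ] - mean(sources[j, ])))^2
    pw <- pw[seq_along(f)]
    lowfrac <- sum(pw[f < 4]) / max(sum(pw), .Machine$double.eps)
    min(1, conc / 2) * lowfrac
  }, numeric(1))
}

#' Choose which components to remove given their ocular scores
#'
#' Components scoring at or above `threshold` are selected in descending
#' score order, capped at `max_removed` (3 by default, balancing artifact
#' removal against neural-signal preservation).
#'
#' @param scores numeric ocular scores from [score_ocular_components()].
#' @param threshold removal threshold.
#' @param max_removed cap on removed components.
#' @return integer indices of components to remove, best-scoring first.
#' @export
select_ocular_components <- function(scores, threshold, max_removed) {
  cand <- which(scores >= threshold)
  cand <- cand[order(scores[cand], decreasing = TRUE)]
  head(cand, max_removed)
}

#' Remove ocular components by dual-filter ICA
#'
#' ICA performs best on high-passed data, but the decoders need the
#' low-frequency content, so the unmixing is estimated on a 1 Hz high-passed
#' copy of the session and then applied to the unfiltered signal. Components
#' scoring at or above the ocular threshold are removed in descending score
#' order, at most `max_removed_components` of them (cap 3 by default).
#'
#' @param eeg channels x samples continuous session matrix (after CAR).
#' @param rate sampling rate in Hz.
#' @param config a [preprocess_config()].
#' @param seed seed for the ICA initialization.
#' @return list with `eeg` (cleaned), `removed` (component indices),
#'   `scores`, `n_components`.
#' @export
ica_remove_ocular <- function(eeg, rate, config = preprocess_config(),
                              seed = 1L) {
  nch <- nrow(eeg)
  mu <- rowMeans(eeg)
  xb <- eeg - mu
  xf <- highpass_zero_phase(xb, rate, config$ica_fit_highpass_hz)
  xf <- xf - rowMeans(xf)
  nc <- qr(xf)$rank
  nc <- min(nc, nch - 1L) # CAR removes one degree of freedom
  fit <- NULL
  for (attempt in 0:1) {
    set.seed(as.integer(seed) + attempt)
    fit <- tryCatch(
      ica::icafast(t(xf), nc = nc, center = TRUE, maxit = 200, tol = 1e-6),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(sum(fit$W))) break
    fit <- NULL
  }
  if (is.null(fit)) stop("ICA failed to converge after retry", call. = FALSE)
  # icafast fits sources = t(W %*% x); mixing M maps sources back to channels
  U <- fit$W                           # nc x channels (unmixing)
  A <- fit$M                           # channels x nc (mixing)
  S <- U %*% xb                        # broadband sources
  scores <- score_ocular_components(A, S, rate)
  removed <- select_ocular_components(scores, config$ocular_score_threshold,
                                      config$max_removed_components)
  clean <- xb
  if (length(removed) > 0) {
    clean <- clean - A[, removed, drop = FALSE] %*% S[removed, , drop = FALSE]
  }
  list(eeg = clean + mu, removed = removed, scores = scores,
       n_components = nc)
}

#' Epoch a session and baseline-correct each trial
#'
#' Cuts the analysis epoch (`epoch_window`, default -0.5 s to +6.5 s around
#' movement onset), subtracts the per-channel mean of the baseline window
#' (-1 to 0 s before movement onset, taken from the continuous data), and
#' downsamples to `out_rate` by polyphase resampling. Under the defaults the
#' result is 32 x 700 per trial.
#'
#' @param eeg channels x samples continuous session matrix.
#' @param rate sampling rate in Hz.
#' @param triggers tibble with `trial_id` and `move_onset` sample indices.
#' @param config a [preprocess_config()].
#' @return list of `clean_epoch` objects: `eeg` (channels x 700), `rate`,
#'   `trial_id`.
#' @export
epoch_and_baseline <- function(eeg, rate, triggers,
                               config = preprocess_config()) {
  lapply(seq_len(nrow(triggers)), function(i) {
    m <- triggers$move_onset[i]
    tid <- triggers$trial_id[i]
    b0 <- m + round(config$baseline_window[1] * rate)
    b1 <- m + round(config$baseline_window[2] * rate) - 1
    e0 <- m + round(config$epoch_window[1] * rate)
    e1 <- m + round(config$epoch_window[2] * rate) - 1
    if (b0 < 1 || e0 < 1 || e1 > ncol(eeg)) {
      stop(sprintf("trial %s: epoch or baseline exceeds session bounds", tid),
           call. = FALSE)
    }
    base <- rowMeans(eeg[, b0:b1, drop = FALSE])
    ep <- eeg[, e0:e1, drop = FALSE] - base
    g <- gcd_int(round(config$out_rate), round(rate))
    ep_ds <- resample_rows(ep, round(config$out_rate) / g, round(rate) / g)
    structure(list(eeg = ep_ds, rate = config$out_rate,
                   trial_id = as.integer(tid)),
              class = "clean_epoch")
  })
}

#' Run the full preprocessing chain on a subject's sessions
#'
#' notch -> band-pass -> bad-channel interpolation -> CAR -> per-session ICA
#' -> epoch + baseline + downsample.
#'
#' @param sessions list of `session_recording` objects from
#'   [sessions_from_trials()].
#' @param config a [preprocess_config()].
#' @param seed seed stream for the per-session ICA.
#' @return list with `epochs` (all trials' `clean_epoch`s in order) and
#'   `log` (per-session: bad channels, removed component count, scores).
#' @export
preprocess_subject <- function(sessions, config = preprocess_config(),
                               seed = 1L) {
  epochs <- list()
  logs <- list()
  for (s in sessions) {
    x <- notch_filter(s$eeg, s$rate, config$notch_hz)
    x <- bandpass_zero_phase(x, s$rate, config$bandpass)
    bad <- detect_bad_channels(x, config$bad_z, config$bad_corr)
    x <- interpolate_channels(x, bad)
    x <- common_average_reference(x)
    ica_res <- ica_remove_ocular(x, s$rate, config,
                                 seed = derive_seed(seed, s$session_id))
    eps <- epoch_and_baseline(ica_res$eeg, s$rate, s$triggers, config)
    for (e in eps) {
      e$bad_channels <- bad
      e$removed_components <- length(ica_res$removed)
      epochs[[length(epochs) + 1]] <- e
    }
    logs[[length(logs) + 1]] <- list(
      session_id = s$session_id,
      bad_channels = bad,
      removed_components = ica_res$removed,
      component_scores = ica_res$scores
    )
  }
  list(epochs = epochs, log = logs)
}
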