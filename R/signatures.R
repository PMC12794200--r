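#' Movement-related cortical potential (MRCP) averages
#'
#' Band-passes each epoch to the slow MRCP range (0.1-4 Hz, zero-phase
#' Butterworth applied forward and backward) and returns the across-trial
#' mean voltage with a pointwise 95% t-interval per requested channel. Time
#' is expressed relative to movement onset.
#'
#' @param epochs list of `clean_epoch` objects (channels x samples, common
#'   rate).
#' @param channels channel labels, default C3/Cz/C4.
#' @param band MRCP band in Hz.
#' @param epoch_start_s time of the first epoch sample relative to movement
#'   onset (default -0.5 s, the analysis epoch).
#' @return tibble: `channel`, `time`, `mean`, `ci_lo`, `ci_hi` (uV).
#' @export
compute_mrcp <- function(epochs, channels = c("C3", "Cz", "C4"),
                         band = c(0.1, 4), epoch_start_s = -0.5) {
  stopifnot(length(epochs) >= 2)
  rate <- epochs[[1]]$rate
  labs <- rownames(epochs[[1]]$eeg) %||% montage_1010_32()$channel
  ch_idx <- match(channels, labs)
  if (anyNA(ch_idx)) {
    stop("channel(s) not present: ",
         paste(channels[is.na(ch_idx)], collapse = ", "), call. = FALSE)
  }
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  n <- ncol(epochs[[1]]$eeg)
  tt <- epoch_start_s + (seq_len(n) - 1) / rate
  purrr::map_dfr(seq_along(channels), function(j) {
    m <- vapply(epochs, function(e) {
      as.numeric(signal::filtfilt(bf, e$eeg[ch_idx[j], ]))
    }, numeric(n))
    mu <- rowMeans(m)
    se <- apply(m, 1, sd) / sqrt(ncol(m))
    q <- qt(0.975, ncol(m) - 1)
    tibble::tibble(channel = channels[j], time = tt, mean = mu,
                   ci_lo = mu - q * se, ci_hi = mu + q * se)
  })
}

# complex Morlet wavelet power at one frequency via FFT convolution; the
# signal is reflection-padded so power estimates near the epoch edges (where
# the baseline interval sits) are not biased low
morlet_power <- function(x, rate, freq, cycles) {
  n <- length(x)
  sd_t <- cycles / (2 * pi * freq)
  half <- ceiling(4 * sd_t * rate)
  p <- min(n - 1, half)
  xp <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  tt <- (-half:half) / rate
  w <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sd_t^2))
  w <- w / sum(Mod(w))
  L <- length(w)
  m <- length(xp)
  nf <- nextn(m + L - 1)
  conv <- fft(fft(c(xp, numeric(nf - m))) * fft(c(w, numeric(nf - L))),
              inverse = TRUE) / nf
  d <- (L - 1) / 2
  Mod(conv[(d + p + 1):(d + p + n)])^2
}

#' Event-related spectral perturbation (ERSP)
#'
#' Morlet-wavelet time-frequency power per trial (linearly spaced
#' frequencies, cycles = freq/2 clamped to [3, 10]), averaged across trials
#' and expressed in dB relative to the mean baseline power per frequency.
#' The baseline interval consequently averages to 0 dB per frequency by
#' construction.
#'
#' @param epochs list of `clean_epoch` objects.
#' @param channels channel labels, default C3/Cz/C4.
#' @param freq_range frequency range in Hz.
#' @param n_freqs number of linearly spaced frequencies.
#' @param baseline baseline interval in seconds relative to movement onset;
#'   must lie inside the epoch.
#' @param epoch_start_s time of the first epoch sample relative to movement
#'   onset.
#' @return tibble: `channel`, `freq`, `time`, `power_db`.
#' @export
compute_ersp <- function(epochs, channels = c("C3", "Cz", "C4"),
                         freq_range = c(4, 30), n_freqs = 14,
                         baseline = c(-0.5, 0), epoch_start_s = -0.5) {
  rate <- epochs[[1]]$rate
  labs <- rownames(epochs[[1]]$eeg) %||% montage_1010_32()$channel
  ch_idx <- match(channels, labs)
  if (anyNA(ch_idx)) {
    stop("channel(s) not present: ",
         paste(channels[is.na(ch_idx)], collapse = ", "), call. = FALSE)
  }
  n <- ncol(epochs[[1]]$eeg)
  tt <- epoch_start_s + (seq_len(n) - 1) / rate
  if (baseline[1] < tt[1] - 1e-9 || baseline[2] > tt[n] + 1 / rate + 1e-9) {
    stop("baseline interval lies outside the epoch", call. = FALSE)
  }
  base_idx <- which(tt >= baseline[1] & tt < baseline[2])
  freqs <- seq(freq_range[1], freq_range[2], length.out = n_freqs)
  cycles <- pmin(10, pmax(3, freqs / 2))
  purrr::map_dfr(seq_along(channels), function(j) {
    purrr::map_dfr(seq_along(freqs), function(fi) {
      pw <- rowMeans(vapply(epochs, function(e) {
        morlet_power(e$eeg[ch_idx[j], ], rate, freqs[fi], cycles[fi])
      }, numeric(n)))
      base <- mean(pw[base_idx])
      tibble::tibble(channel = channels[j], freq = freqs[fi], time = tt,
                     power_db = 10 * log10(pw / base))
    })
  })
}

#' Across-trial mean channel voltages at chosen timepoints
#'
#' The numeric substrate of a voltage topography sequence: the across-trial
#' mean voltage of every channel at each requested time.
#'
#' @param epochs list of `clean_epoch` objects.
#' @param timepoints seconds relative to movement onset.
#' @param epoch_start_s time of the first epoch sample relative to movement
#'   onset.
#' @return tibble: `channel`, `time`, `mean_uv` (32 rows per timepoint).
#' @export
channel_voltage_summary <- function(epochs, timepoints,
                                    epoch_start_s = -0.5) {
  rate <- epochs[[1]]$rate
  n <- ncol(epochs[[1]]$eeg)
  labs <- rownames(epochs[[1]]$eeg) %||% montage_1010_32()$channel
  purrr::map_dfr(timepoints, function(tp) {
    i <- round((tp - epoch_start_s) * rate) + 1
    if (i < 1 || i > n) {
      stop(sprintf("timepoint %g s outside the epoch", tp), call. = FALSE)
    }
    v <- rowMeans(vapply(epochs, function(e) e$eeg[, i],
                         numeric(nrow(epochs[[1]]$eeg))))
    tibble::tibble(channel = labs, time = tp, mean_uv = unname(v))
  })
}
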