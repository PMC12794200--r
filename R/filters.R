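#' Zero-phase FIR filtering
#'
#' Applies a linear-phase FIR filter forward and backward (squaring its
#' magnitude response, cancelling its phase) with odd-symmetric reflection
#' padding at the edges. Convolution is FFT-based so very long kernels (the
#' 0.1 Hz band edge needs thousands of taps) stay cheap.
#'
#' @param x numeric signal vector.
#' @param b FIR coefficients (odd length, symmetric).
#' @return filtered vector, same length as `x`.
#' @noRd
fir_filtfilt <- function(x, b) {
  n <- length(x)
  L <- length(b)
  p <- min(n - 1, L)
  pad <- function(v) {
    c(2 * v[1] - rev(v[2:(p + 1)]), v, 2 * v[n] - rev(v[(n - p):(n - 1)]))
  }
  onepass <- function(v) {
    # linear convolution via FFT, trimmed to compensate the group delay
    m <- length(v)
    nf <- nextn(m + L - 1)
    y <- Re(fft(fft(c(v, numeric(nf - m))) * fft(c(b, numeric(nf - L))),
                inverse = TRUE)) / nf
    d <- (L - 1) / 2
    y[(d + 1):(d + m)]
  }
  v <- pad(x)
  v <- onepass(v)
  v <- rev(onepass(rev(v)))
  v[(p + 1):(p + n)]
}

# Hamming-window FIR length from the transition width rule N ~ 3.3 / dF,
# dF in cycles/sample; rounded up to odd
fir_order_hamming <- function(rate, transition_hz) {
  n <- ceiling(3.3 * rate / transition_hz)
  if (n %% 2 == 1) n <- n + 1 # fir1 order must be even for odd length
  n
}

#' Notch filter for power-line interference
#'
#' Zero-phase Hamming-window FIR band-stop around the line frequency
#' (default 50 Hz, stop band +/- 2 Hz).
#'
#' @param eeg channels x samples matrix (or a numeric vector).
#' @param rate sampling rate in Hz.
#' @param notch_hz line frequency.
#' @param width_hz half-width of the stop band.
#' @return filtered data, same shape.
#' @export
notch_filter <- function(eeg, rate, notch_hz = 50, width_hz = 2) {
  if (rate <= 2 * notch_hz) {
    stop("sampling rate must exceed twice the notch frequency", call. = FALSE)
  }
  ord <- fir_order_hamming(rate, width_hz)
  b <- signal::fir1(ord, c(notch_hz - width_hz, notch_hz + width_hz) / (rate / 2),
                    type = "stop")
  apply_rows(eeg, function(v) fir_filtfilt(v, b))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc design applied forward and backward (zero net group
#' delay). The filter order follows the transition width at the low edge
#' (0.1 Hz by default), which dominates the length.
#'
#' @param eeg channels x samples matrix (or numeric vector).
#' @param rate sampling rate in Hz.
#' @param band length-2 numeric, pass band in Hz.
#' @param transition_hz transition width at the low edge.
#' @return filtered data, same shape.
#' @export
bandpass_zero_phase <- function(eeg, rate, band = c(0.1, 30),
                                transition_hz = max(band[1], 0.1)) {
  if (band[1] <= 0 || band[2] <= band[1]) {
    stop("`band` must be increasing and positive", call. = FALSE)
  }
  if (band[2] >= rate / 2) {
    stop("band edge at or above Nyquist", call. = FALSE)
  }
  ord <- fir_order_hamming(rate, transition_hz)
  b <- signal::fir1(ord, band / (rate / 2), type = "pass")
  n <- if (is.matrix(eeg)) ncol(eeg) else length(eeg)
  if (length(b) > n) {
    stop(sprintf(paste0("signal (%d samples) is shorter than the %d-tap ",
                        "filter; widen `transition_hz` or filter longer ",
                        "continuous data"), n, length(b)), call. = FALSE)
  }
  apply_rows(eeg, function(v) fir_filtfilt(v, b))
}

# zero-phase FIR high-pass (used for the ICA fitting copy)
highpass_zero_phase <- function(eeg, rate, cutoff = 1) {
  ord <- fir_order_hamming(rate, cutoff)
  b <- signal::fir1(ord, cutoff / (rate / 2), type = "high")
  apply_rows(eeg, function(v) fir_filtfilt(v, b))
}

apply_rows <- function(x, f) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, f))
    dimnames(out) <- dimnames(x)
    out
  } else {
    f(x)
  }
}

# polyphase resampling of each channel row (anti-alias filtered); used for
# the 256 -> 100 Hz EEG decimation (ratio 25/64)
resample_rows <- function(eeg, p, q) {
  apply_rows(eeg, function(v) as.numeric(signal::resample(v, p, q)))
}
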