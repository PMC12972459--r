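# Zero-phase filtering by frequency-domain gain application.
#
# Multiplying the DFT by a real, nonnegative gain is the exact zero-phase
# analogue of forward-backward IIR filtering: the magnitude response is the
# squared single-pass magnitude, the phase is identically zero, and the
# operator is exactly linear. `gain` receives physical frequency in Hz.
.gain_vector <- function(n, fs, gain) {
  f <- (seq_len(n) - 1) * fs / n
  gain(pmin(f, fs - f)) # fold to [0, fs/2]
}

.apply_gain <- function(x, fs, gain) {
  g <- if (is.function(gain)) .gain_vector(NROW(x), fs, gain) else gain
  if (is.matrix(x)) {
    Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / nrow(x)
  } else {
    Re(fft(fft(x) * g, inverse = TRUE)) / length(x)
  }
}

.apply_gain_rec <- function(recording, gain) {
  cn <- colnames(recording$samples)
  recording$samples <- .apply_gain(recording$samples, recording$fs, gain)
  colnames(recording$samples) <- cn
  recording
}

# squared magnitude of an order-`order` Butterworth low/high-pass, i.e. the
# two-pass (zero-phase) amplitude gain
.butter_gain <- function(f, fc, order, type) {
  ratio <- switch(type,
    low  = f / fc,
    high = fc / pmax(f, 1e-300)
  )
  1 / (1 + ratio^(2 * order))
}

# two-pass amplitude gain of a second-order notch with centre f0 and -3 dB
# bandwidth `bw` (Hz): |H|^2 with |H|^2 = d^2 / (d^2 + (bw*f)^2), d = f^2-f0^2
.notch_gain <- function(f, f0, bw) {
  d2 <- (f^2 - f0^2)^2
  d2 / (d2 + (bw * f)^2)
}

# combined gain of the notch comb over every mains harmonic below Nyquist
.comb_gain <- function(f, base_freq, bandwidth, nyq) {
  g <- rep(1, length(f))
  for (f0 in base_freq * seq_len(floor((nyq - 1e-9) / base_freq))) {
    g <- g * .notch_gain(f, f0, bandwidth)
  }
  g
}

# combined band-limiting gain (high-pass * low-pass)
.band_gain <- function(f, low, high, order) {
  .butter_gain(f, low, order, "high") * .butter_gain(f, high, order, "low")
}

#' Band-limit an sEMG recording
#'
#' Applies a zero-phase Butterworth high-pass (default corner 20 Hz, removing
#' movement artefact and baseline drift) followed by a zero-phase Butterworth
#' low-pass (default corner 500 Hz) to every channel. Each stage has the
#' magnitude response of a 4th-order Butterworth run forward and backward
#' (effective 8th order) and exactly zero phase.
#'
#' @param recording an [semg_recording].
#' @param low high-pass corner frequency (Hz).
#' @param high low-pass corner frequency (Hz).
#' @param order single-pass Butterworth order.
#' @return The filtered [semg_recording], same shape.
#' @export
band_limit <- function(recording, low = 20, high = 500, order = 4) {
  stopifnot(inherits(recording, "semg_recording"))
  if (recording$fs <= 2 * high) {
    .stop("invalid_rate",
          "Sampling rate %g Hz puts the %g Hz low-pass corner at/above Nyquist.",
          recording$fs, high)
  }
  .apply_gain_rec(recording, function(f) .band_gain(f, low, high, order))
}

#' Remove power-line interference with a comb of notches
#'
#' Suppresses the mains component and every harmonic below Nyquist with
#' zero-phase notches of constant 2 Hz bandwidth (quality factor 30 at a
#' 60 Hz fundamental), leaving frequencies 5 Hz or more away essentially
#' untouched (< 1 dB).
#'
#' @param recording an [semg_recording].
#' @param base_freq mains fundamental in Hz (60 in Brazil, where the
#'   perturbation protocol was run; 50 elsewhere).
#' @param bandwidth notch -3 dB bandwidth in Hz, applied to every harmonic.
#' @return The filtered [semg_recording], same shape.
#' @export
remove_line_interference <- function(recording, base_freq = 60,
                                     bandwidth = 2) {
  stopifnot(inherits(recording, "semg_recording"))
  nyq <- recording$fs / 2
  if (base_freq >= nyq) {
    .stop("invalid_rate",
          "Line frequency %g Hz is at/above Nyquist (%g Hz).", base_freq, nyq)
  }
  .apply_gain_rec(recording, function(f) .comb_gain(f, base_freq, bandwidth, nyq))
}

#' Z-score each channel of a recording
#'
#' Normalises every channel over the full recording to mean 0 and population
#' standard deviation 1, so that amplitudes are comparable across channels
#' and subjects and the sample-entropy tolerance is in common units.
#'
#' @param recording an [semg_recording].
#' @return The normalised [semg_recording].
#' @export
zscore_channels <- function(recording) {
  stopifnot(inherits(recording, "semg_recording"))
  recording$samples <- apply(recording$samples, 2, function(x) {
    mu <- mean(x)
    sdp <- sqrt(mean((x - mu)^2))
    if (sdp <= 1e-12 * max(1, abs(mu))) {
      .stop("degenerate_signal", "Channel has zero variance; cannot z-score.")
    }
    (x - mu) / sdp
  })
  recording
}

#' Full sEMG conditioning pipeline
#'
#' Runs, in this fixed order: band-limiting (20-500 Hz), comb removal of the
#' mains component and harmonics, and per-channel z-scoring over the whole
#' recording. The order matters - z-scoring before filtering would normalise
#' against out-of-band power - so it is enforced here rather than left to the
#' caller.
#'
#' @param recording an [semg_recording].
#' @param line_freq mains fundamental in Hz.
#' @param low,high band-limiting corners in Hz.
#' @param .gain precomputed combined gain vector (internal reuse across
#'   same-shaped recordings).
#' @return The conditioned [semg_recording].
#' @export
preprocess_recording <- function(recording, line_freq = 60,
                                 low = 20, high = 500, .gain = NULL) {
  stopifnot(inherits(recording, "semg_recording"))
  nyq <- recording$fs / 2
  if (recording$fs <= 2 * high) {
    .stop("invalid_rate",
          "Sampling rate %g Hz puts the %g Hz low-pass corner at/above Nyquist.",
          recording$fs, high)
  }
  if (line_freq >= nyq) {
    .stop("invalid_rate",
          "Line frequency %g Hz is at/above Nyquist (%g Hz).", line_freq, nyq)
  }
  # band-limit and comb are both diagonal in frequency, so the cascade is
  # applied in a single pass; the result is sample-identical to
  # band_limit() %>% remove_line_interference()
  g <- .gain %||% .preprocess_gain(nrow(recording$samples), recording$fs,
                                   line_freq, low, high)
  .apply_gain_rec(recording, g) %>%
    zscore_channels()
}

.preprocess_gain <- function(n, fs, line_freq, low = 20, high = 500) {
  .gain_vector(n, fs, function(f) {
    .band_gain(f, low, high, 4) * .comb_gain(f, line_freq, 2, fs / 2)
  })
}
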