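#' Root-mean-square amplitude
#'
#' `sqrt(mean(x^2))`: the standard sEMG activation-intensity measure. On a
#' z-scored recording the full-channel RMS is 1 by construction; epoch-level
#' values quantify how active the window is relative to the session.
#'
#' @param x numeric vector of samples.
#' @return Nonnegative scalar.
#' @export
compute_rms <- function(x) {
  if (length(x) == 0) .stop("empty_input", "Cannot compute RMS of an empty segment.")
  sqrt(mean(x^2))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: Hann window, 256-sample segments, 50%
#' overlap. The one-sided density is scaled so that its integral equals the
#' signal power (Parseval).
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param nfft analysis window length in samples.
#' @param overlap fractional overlap between consecutive windows.
#' @param band two-element numeric, the frequency band (Hz) considered by
#'   downstream spectral summaries; defaults to the 20-500 Hz analysis band.
#' @return An object of class `semg_psd`: list with `freq` (Hz), `psd`
#'   (power per Hz), `band`, `df` (grid resolution, Hz).
#' @export
estimate_psd <- function(x, fs, nfft = 256, overlap = 0.5,
                         band = c(20, 500)) {
  n <- length(x)
  if (n < nfft) {
    .stop("short_segment",
          "Segment of %d samples is shorter than one %d-sample analysis window.",
          n, nfft)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / nfft)
  step <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, n - nfft + 1L, by = step)
  scale <- fs * sum(w^2)
  nb <- nfft %/% 2 + 1L
  acc <- numeric(nb)
  for (s in starts) {
    X <- fft(x[s:(s + nfft - 1L)] * w)
    P <- abs(X[seq_len(nb)])^2 / scale
    P[2:(nb - 1L)] <- 2 * P[2:(nb - 1L)] # one-sided: double interior bins
    acc <- acc + P
  }
  structure(
    list(freq = fs * (seq_len(nb) - 1) / nfft, psd = acc / length(starts),
         band = band, df = fs / nfft),
    class = "semg_psd"
  )
}

#' @export
as_tibble.semg_psd <- function(x, ...) tibble(freq = x$freq, psd = x$psd)

#' Median frequency of a power spectrum
#'
#' The smallest frequency at which the cumulative power over the analysis
#' band reaches half of the total band power, i.e. the frequency splitting
#' the band power into two equal halves (up to grid resolution).
#'
#' @param spec an `semg_psd` from [estimate_psd()], or a list with `freq`,
#'   `psd` and optionally `band`.
#' @param band frequency band (Hz) over which the median is taken; defaults
#'   to the band stored in `spec`.
#' @return Median frequency in Hz.
#' @export
compute_mdf <- function(spec, band = NULL) {
  band <- band %||% spec$band %||% range(spec$freq)
  keep <- spec$freq >= band[1] & spec$freq <= band[2]
  f <- spec$freq[keep]
  p <- spec$psd[keep]
  total <- sum(p)
  if (!length(p) || total <= 0) {
    .stop("degenerate_spectrum", "Zero power in the analysis band.")
  }
  f[which(cumsum(p) >= total / 2)[1]]
}

#' Sample entropy
#'
#' `-log(A/B)` where `B` counts pairs of length-`m` templates matching within
#' Chebyshev tolerance `r` (self-matches excluded) and `A` counts the pairs
#' still matching when extended to length `m + 1`. Lower values indicate a
#' more regular, predictable signal. Defaults `m = 1`, `r = 0.1`: the
#' tolerance is in absolute z-units because the pipeline z-scores each
#' channel before feature extraction.
#'
#' @param x numeric vector of samples.
#' @param m template length (samples).
#' @param r matching tolerance, in the units of `x`.
#' @return Nonnegative scalar; `+Inf` with attribute `saturated = TRUE` when
#'   no extended template matches exist.
#' @export
compute_sampen <- function(x, m = 1, r = 0.1) {
  if (length(x) == 0) .stop("empty_input", "Empty segment.")
  if (m < 1) .stop("parameter", "Template length m must be >= 1.")
  if (r <= 0) .stop("parameter", "Tolerance r must be positive.")
  if (length(x) < m + 2) {
    .stop("short_segment",
          "Need at least m + 2 = %d samples, got %d.", m + 2, length(x))
  }
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r)
  if (cnt$B == 0) {
    .stop("undefined_entropy",
          "No length-%d template matches within r = %g; entropy undefined.",
          m, r)
  }
  if (cnt$A == 0) {
    return(structure(Inf, saturated = TRUE))
  }
  -log(cnt$A / cnt$B)
}

#' Higuchi fractal dimension
#'
#' Builds, for each lag `k = 1..kmax`, the `k` decimated curves starting at
#' offsets `1..k`, computes their normalised lengths, and returns the negated
#' slope of `log(mean length)` against `log(k)`. Values near 1 indicate a
#' smooth curve, values near 2 a plane-filling (noise-like) series.
#'
#' @param x numeric vector of samples.
#' @param kmax largest lag; `"auto"` picks `min(64, floor(n / 50))` (so about
#'   8 for 400-sample epochs and 64 for 4000-sample epochs), keeping at least
#'   50 points per decimated curve.
#' @return Scalar dimension estimate; a warning is emitted outside `[1, 2]`.
#' @export
compute_higuchi_fd <- function(x, kmax = "auto") {
  n <- length(x)
  if (identical(kmax, "auto")) kmax <- max(2L, min(64L, n %/% 50L))
  kmax <- as.integer(kmax)
  if (kmax < 2) .stop("parameter", "kmax must be at least 2.")
  if (n < 2 * kmax) {
    .stop("short_segment", "Need at least 2 * kmax = %d samples.", 2 * kmax)
  }
  L <- vapply(seq_len(kmax), function(k) {
    mean(vapply(seq_len(k), function(m) {
      xi <- x[seq(m, n, by = k)]
      nm <- length(xi) - 1L
      sum(abs(diff(xi))) * (n - 1) / (nm * k^2)
    }, numeric(1)))
  }, numeric(1))
  fd <- -unname(coef(lm(log(L) ~ log(seq_len(kmax))))[2])
  if (fd < 1 - 1e-6 || fd > 2 + 1e-6) {
    warn(sprintf("Higuchi dimension %.3f outside [1, 2]; check the input.", fd))
  }
  fd
}

#' Compute features for a table of epoch segments
#'
#' Evaluates the requested features on every segment row produced by
#' [segment_epochs()] and returns them in long format, one row per
#' (segment, feature). `CSD`, `RSD` and `LSD` are the Gaussian-reference
#' shape distances of the amplitude distribution (see [csm_distances()]).
#'
#' @param segments segment tibble from [segment_epochs()] (must carry the
#'   `fs` attribute column added there).
#' @param features character subset of
#'   `c("RMS", "MDF", "SAMPEN", "HFD", "CSD", "RSD", "LSD")`.
#' @param sampen_m,sampen_r sample-entropy parameters.
#' @param kmax Higuchi lag bound, or `"auto"`.
#' @param psd_band spectral analysis band in Hz.
#' @return Long tibble: provenance columns plus `feature` and `value`.
#' @export
extract_features <- function(segments,
                             features = c("RMS", "MDF", "SAMPEN",
                                          "CSD", "RSD", "LSD"),
                             sampen_m = 1, sampen_r = 0.1, kmax = "auto",
                             psd_band = c(20, 500)) {
  if (!nrow(segments)) .stop("empty_input", "No segments supplied.")
  features <- match.arg(features,
                        c("RMS", "MDF", "SAMPEN", "HFD", "CSD", "RSD", "LSD"),
                        several.ok = TRUE)
  shape_wanted <- intersect(c("CSD", "RSD", "LSD"), features)

  ns <- nrow(segments)
  cols <- list()
  if ("RMS" %in% features) {
    cols$RMS <- vapply(segments$samples, compute_rms, numeric(1))
  }
  if ("MDF" %in% features) {
    cols$MDF <- vapply(seq_len(ns), function(i) {
      compute_mdf(estimate_psd(segments$samples[[i]], fs = segments$fs[i],
                               band = psd_band))
    }, numeric(1))
  }
  if ("SAMPEN" %in% features) {
    cols$SAMPEN <- vapply(segments$samples, function(x) {
      as.numeric(compute_sampen(x, m = sampen_m, r = sampen_r))
    }, numeric(1))
  }
  if ("HFD" %in% features) {
    cols$HFD <- vapply(segments$samples, compute_higuchi_fd,
                       numeric(1), kmax = kmax)
  }
  if (length(shape_wanted)) {
    sh <- vapply(segments$samples, .csm_values, numeric(3))
    for (f in shape_wanted) cols[[f]] <- sh[f, ]
  }
  cols <- cols[intersect(c("RMS", "MDF", "SAMPEN", "HFD", "CSD", "RSD", "LSD"),
                         names(cols))]

  segments %>%
    select(dplyr::any_of(c("subject_id", "group", "muscle", "trial", "epoch"))) %>%
    dplyr::bind_cols(as_tibble(cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(names(cols)),
                        names_to = "feature", values_to = "value")
}

#' Assemble and validate the long feature table
#'
#' Wraps [extract_features()] with design bookkeeping: errors on duplicate
#' provenance keys and warns when the (muscle x epoch x trial) design is
#' incomplete (e.g. a dropped trial).
#'
#' @inheritParams extract_features
#' @param n_trials expected number of trials per subject; `NULL` skips the
#'   completeness check.
#' @return Long feature tibble as from [extract_features()].
#' @export
build_feature_table <- function(segments,
                                features = c("RMS", "MDF", "SAMPEN",
                                             "CSD", "RSD", "LSD"),
                                n_trials = NULL, ...) {
  if (!nrow(segments)) .stop("empty_input", "No segments supplied.")
  key <- paste(segments$subject_id, segments$muscle, segments$trial,
               segments$epoch)
  if (anyDuplicated(key)) {
    .stop("duplicate_key", "Duplicate segment provenance: %s",
          key[anyDuplicated(key)])
  }
  tab <- extract_features(segments, features = features, ...)
  if (!is.null(n_trials)) {
    expected <- length(unique(segments$muscle)) *
      length(unique(segments$epoch)) * n_trials * length(features)
    got <- nrow(tab) / length(unique(tab$subject_id))
    if (got < expected) {
      warn(sprintf(
        "Incomplete design: %g records per subject, expected %d.", got, expected))
    }
  }
  tab
}
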