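test_that("band limiting removes DC and stop-band tones but passes the band", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  dc <- band_limit(one_channel(rep(1, length(t))))
  expect_lt(abs(mean(dc$samples)), 0.01)

  s100 <- sin(2 * pi * 100 * t)
  out <- band_limit(one_channel(s100))$samples
  expect_lt(abs(rms_of(out) / rms_of(s100) - 1), 0.05)

  s10 <- sin(2 * pi * 10 * t)
  out10 <- band_limit(one_channel(s10))$samples
  expect_lt(rms_of(out10) / rms_of(s10), 0.25)

  expect_error(band_limit(one_channel(s100, fs = 900)),
               class = "semgadapt_error_invalid_rate")
})

test_that("the notch comb suppresses the mains fundamental and harmonics only", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  gain_at <- function(freq) {
    s <- sin(2 * pi * freq * t)
    rms_of(remove_line_interference(one_channel(s))$samples) / rms_of(s)
  }
  for (freq in c(60, 120, 300, 960)) {
    expect_lt(gain_at(freq), 0.01) # >= 40 dB attenuation
  }
  for (freq in c(55, 65, 955, 965, 100)) {
    expect_gt(20 * log10(gain_at(freq)), -1) # < 1 dB at neighbours
  }
  expect_error(remove_line_interference(one_channel(t, fs = 100),
                                        base_freq = 60),
               class = "semgadapt_error_invalid_rate")
})

test_that("filtering is linear and exactly zero-phase", {
  rec <- toy_recording(n = 4000)
  a <- 3.7
  scaled <- rec
  scaled$samples <- a * scaled$samples
  expect_equal(band_limit(scaled)$samples, a * band_limit(rec)$samples,
               tolerance = 1e-9)
  expect_equal(remove_line_interference(scaled)$samples,
               a * remove_line_interference(rec)$samples, tolerance = 1e-9)

  # cross-correlation between a band-limited input and its filtered output
  # must peak at lag zero
  x <- brickwall_noise(4000, 2000, 30, 400)
  y <- band_limit(one_channel(x))$samples[, 1]
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_identical(cc$lag[which.max(abs(cc$acf)), 1, 1], 0)
  y2 <- remove_line_interference(one_channel(x))$samples[, 1]
  cc2 <- stats::ccf(x, y2, lag.max = 20, plot = FALSE)
  expect_identical(cc2$lag[which.max(abs(cc2$acf)), 1, 1], 0)
})

test_that("z-scoring normalises each channel with the population SD", {
  z <- zscore_channels(one_channel(c(0, 2, 0, 2)))
  expect_equal(as.numeric(z$samples), c(-1, 1, -1, 1))

  rec <- toy_recording(n = 3000)
  z2 <- zscore_channels(rec)
  for (ch in 1:4) {
    x <- z2$samples[, ch]
    expect_lt(abs(mean(x)), 1e-10)
    expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-10)
  }
  expect_error(zscore_channels(one_channel(rep(5, 100))),
               class = "semgadapt_error_degenerate_signal")
})

test_that("epoch segmentation uses half-open onset-locked windows", {
  fs <- 2000
  n <- 16000
  rec <- semg_recording(matrix(seq_len(4 * n), ncol = 4), fs = fs,
                        onsets = 10001L, # sample index of time zero, 1-based
                        muscles = c("TA", "GL", "GM", "SO"),
                        meta = list(subject_id = "S1", group = "control"))
  segs <- segment_epochs(rec)
  expect_equal(nrow(segs), 20) # 4 channels x 5 epochs

  post <- segs[segs$epoch == "Post-stab" & segs$muscle == "TA", ]
  expect_equal(post$n, 4000)
  # 350 ms at 2000 Hz = 700 samples after onset
  expect_equal(post$samples[[1]], rec$samples[10701:14700, "TA"])

  prevol <- segs[segs$epoch == "Pre-vol" & segs$muscle == "TA", ]
  expect_equal(prevol$n, 400)
  expect_equal(prevol$samples[[1]], rec$samples[9501:9900, "TA"])

  expect_equal(sort(unique(segs$n)), c(400, 4000))
  lens <- segs[segs$muscle == "TA", ][["n"]]
  expect_equal(lens[match(epoch_specs()$epoch,
                          segs$epoch[segs$muscle == "TA"])],
               c(4000, 400, 400, 400, 4000))

  # adjacent epochs partition without overlap
  auto <- segs[segs$epoch == "Auto-resp" & segs$muscle == "TA", ]$samples[[1]]
  stab <- segs[segs$epoch == "Stab" & segs$muscle == "TA", ]$samples[[1]]
  expect_equal(stab[1], auto[length(auto)] + 1) # channel values = row index

  rec$onsets <- 1000L
  expect_error(segment_epochs(rec),
               class = "semgadapt_error_truncated_trial")
})

test_that("the conditioning pipeline enforces filter-before-normalise order", {
  rec <- toy_recording(n = 6000)
  rec$samples <- rec$samples + 0.5 * sin(2 * pi * 60 * (1:6000) / 2000)
  piped <- preprocess_recording(rec)
  manual <- rec %>%
    band_limit() %>%
    remove_line_interference() %>%
    zscore_channels()
  expect_equal(piped$samples, manual$samples, tolerance = 1e-9)

  wrong_order <- rec %>%
    zscore_channels() %>%
    band_limit() %>%
    remove_line_interference()
  expect_gt(max(abs(wrong_order$samples - piped$samples)), 1e-3)
})
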