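test_that("RMS matches its closed forms", {
  expect_equal(compute_rms(rep(-3, 17)), 3)
  t <- (0:3999) / 2000
  expect_equal(compute_rms(2.5 * sin(2 * pi * 100 * t)), 2.5 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(compute_rms(c(1, -1, 2, -2)), sqrt(2.5))
  expect_error(compute_rms(numeric(0)), class = "semgadapt_error_empty_input")
})

test_that("Welch PSD conserves power and localises tones", {
  set.seed(11)
  x <- rnorm(4000)
  p <- estimate_psd(x, fs = 2000)
  expect_true(all(p$psd >= 0))
  expect_lt(abs(sum(p$psd) * p$df / var(x) - 1), 0.05)

  t <- (0:3999) / 2000
  tone <- estimate_psd(sin(2 * pi * 100 * t), fs = 2000)
  expect_lt(abs(tone$freq[which.max(tone$psd)] - 100), tone$df)

  # equal-amplitude tones carry near-equal integrated power
  two <- estimate_psd(sin(2 * pi * 80 * t) + sin(2 * pi * 240 * t), fs = 2000)
  peak_power <- function(spec, f0) {
    sum(spec$psd[abs(spec$freq - f0) <= 3 * spec$df]) * spec$df
  }
  expect_lt(abs(peak_power(two, 80) / peak_power(two, 240) - 1), 0.1)

  expect_error(estimate_psd(rnorm(100), fs = 2000),
               class = "semgadapt_error_short_segment")
})

test_that("median frequency follows the smallest-frequency-at-half-power rule", {
  t <- (0:3999) / 2000
  tone <- estimate_psd(sin(2 * pi * 100 * t), fs = 2000)
  expect_lt(abs(compute_mdf(tone) - 100), tone$df)

  # synthetic two-line spectrum: the convention picks the lower line
  two_lines <- structure(
    list(freq = seq(20, 500, by = 4),
         psd = rep(0, 121), band = c(20, 500), df = 4),
    class = "semg_psd"
  )
  two_lines$psd[two_lines$freq == 80] <- 1
  two_lines$psd[two_lines$freq == 240] <- 1
  expect_equal(compute_mdf(two_lines), 80)

  # flat band: Monte Carlo mean near the band midpoint
  set.seed(21)
  md <- replicate(30, compute_mdf(estimate_psd(
    brickwall_noise(8000, 2000, 20, 500), fs = 2000)))
  expect_lt(abs(mean(md) - 260), 10)

  dead <- two_lines
  dead$psd[] <- 0
  expect_error(compute_mdf(dead),
               class = "semgadapt_error_degenerate_spectrum")
})

test_that("sample entropy equals the brute-force definition exactly", {
  expect_equal(compute_sampen(rep(1, 10)), 0)
  x <- rep(c(0, 1), 4)
  b <- brute_sampen(x, 1, 0.1)
  expect_equal(compute_sampen(x), b$value)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    m <- sample(1:3, 1)
    r <- runif(1, 0.05, 0.5)
    oracle <- brute_sampen(x, m, r)
    if (oracle$B == 0) {
      expect_error(compute_sampen(x, m = m, r = r),
                   class = "semgadapt_error_undefined_entropy")
    } else {
      expect_identical(as.numeric(compute_sampen(x, m = m, r = r)),
                       oracle$value)
    }
  }
  x4k <- rnorm(4000)
  expect_equal(compute_sampen(x4k), brute_sampen(x4k)$value, tolerance = 1e-9)

  expect_error(compute_sampen(c(1, 2)), class = "semgadapt_error_short_segment")
  # widely separated values: no templates match at all
  expect_error(compute_sampen(c(0, 10, 20, 30, 40), r = 0.1),
               class = "semgadapt_error_undefined_entropy")
})

test_that("sample entropy invariances and saturation flag behave", {
  set.seed(32)
  x <- rnorm(500)
  expect_identical(compute_sampen(x), compute_sampen(x + 100))
  expect_identical(compute_sampen(x, r = 0.1), compute_sampen(5 * x, r = 0.5))

  # entropy falls as a sinusoid becomes cleaner
  t <- (0:1999) / 2000
  base <- sin(2 * pi * 25 * t)
  vals <- vapply(c(1, 0.5, 0.2, 0.05), function(noise) {
    median(replicate(5, compute_sampen(base + rnorm(2000, 0, noise))))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  # matches at length m but never at m + 1 saturate to +Inf
  sat <- compute_sampen(c(0, 0.05, 1.5, 0, 3, 0.02, -3, 6), m = 1, r = 0.1)
  expect_identical(as.numeric(sat), Inf)
  expect_true(isTRUE(attr(sat, "saturated")))
})

test_that("Higuchi dimension spans smooth to noise-like series", {
  expect_lt(abs(compute_higuchi_fd(seq(0, 1, length.out = 1000)) - 1), 0.05)
  set.seed(41)
  fd <- suppressWarnings(compute_higuchi_fd(rnorm(4000)))
  expect_lt(abs(fd - 2), 0.1)

  x <- cumsum(rnorm(1000))
  for (k in c(5, 10, 20)) {
    expect_equal(compute_higuchi_fd(x, kmax = k), reference_higuchi(x, k),
                 tolerance = 1e-9)
  }
  expect_error(compute_higuchi_fd(rnorm(100), kmax = 1),
               class = "semgadapt_error_parameter")
})

test_that("the feature table covers the full design and guards provenance", {
  cfg <- cohort_config(n_per_group = 1, n_trials = 10, seed = 5,
                       line_amplitude = 0)
  co <- simulate_cohort(cfg)
  rec <- preprocess_recording(co$recordings[[1]])
  segs <- segment_epochs(rec)
  tab <- build_feature_table(segs, n_trials = 10)
  expect_equal(nrow(tab), 4 * 5 * 10 * 6) # 1200 records for a full design
  expect_true(all(tab$value[tab$feature == "RMS"] >= 0))
  expect_true(all(tab$value[tab$feature %in% c("CSD", "RSD", "LSD")] >= 0))

  # a dropped trial leaves 1080 records and warns
  segs9 <- segs[segs$trial != 10, ]
  expect_warning(tab9 <- build_feature_table(segs9, n_trials = 10),
                 "Incomplete")
  expect_equal(nrow(tab9), 4 * 5 * 9 * 6)

  expect_error(build_feature_table(dplyr::bind_rows(segs, segs[1, ])),
               class = "semgadapt_error_duplicate_key")
  expect_error(build_feature_table(segs[0, ]),
               class = "semgadapt_error_empty_input")

  # full-recording RMS of a z-scored channel is 1 by construction
  expect_equal(compute_rms(rec$samples[, "TA"]), 1, tolerance = 1e-9)
})
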