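suppressMessages({
  library(dplyr)
  library(tidyr)
  library(withr)
})

# Independent reference implementations and fixture builders used across the
# suite. These deliberately use the naive textbook constructions so they stay
# independent of the package's optimised code paths.

# O(n^2) sample entropy by direct template enumeration
brute_sampen <- function(x, m = 1, r = 0.1) {
  n_templates <- length(x) - m
  A <- 0
  B <- 0
  for (i in seq_len(n_templates - 1)) {
    for (j in (i + 1):n_templates) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  list(A = A, B = B, value = -log(A / B))
}

# canonical Higuchi curve-length construction, written independently
reference_higuchi <- function(x, kmax) {
  n <- length(x)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      norm <- (n - 1) / (floor((n - m) / k) * k)
      Lm[m] <- sum(abs(diff(x[idx]))) * norm / k
    }
    Lk[k] <- mean(Lm)
  }
  fit <- stats::lm(log(Lk) ~ log(seq_len(kmax)))
  -unname(stats::coef(fit)[2])
}

# white noise ideally band-limited by zeroing DFT bins outside [lo, hi] Hz
brickwall_noise <- function(n, fs, lo, hi) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# numeric constrained least squares for the quantile registration, solved by
# box-constrained quasi-Newton optimisation of the same weighted objective
qp_register <- function(y, P, G) {
  w <- c(diff(y)[1] / 2, (y[-(1:2)] - y[1:(length(y) - 2)]) / 2,
         diff(y)[length(y) - 1] / 2)
  obj <- function(par) sum(w * (par[1] * P + par[2] - G)^2)
  fit <- stats::optim(c(1, 0), obj, method = "L-BFGS-B",
                      lower = c(1e-8, -Inf), upper = c(Inf, Inf),
                      control = list(factr = 1e1))
  list(alpha = fit$par[1], beta = fit$par[2])
}

# single-channel recording wrapper for filter tests
one_channel <- function(x, fs = 2000, onset = 1L, muscle = "TA",
                        meta = list()) {
  semg_recording(matrix(x, ncol = 1), fs = fs, onsets = onset,
                 muscles = muscle, meta = meta)
}

# four-channel noise recording; onset defaults to the midpoint
toy_recording <- function(fs = 2000, n = 12000, onset = n %/% 2,
                          meta = list(subject_id = "S01", group = "control")) {
  set.seed(404)
  semg_recording(matrix(rnorm(4 * n), ncol = 4), fs = fs, onsets = onset,
                 muscles = c("TA", "GL", "GM", "SO"), meta = meta)
}

# exact analytic density objects (bypass the KDE) for closed-form checks
analytic_density <- function(f, lo, hi, n = 4096) {
  grid <- seq(lo, hi, length.out = n)
  structure(list(grid = grid, density = f(grid), bw = NA_real_),
            class = "semg_density")
}

rms_of <- function(x) sqrt(mean(x^2))

# excess kurtosis
exkurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3
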