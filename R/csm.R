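#' Default probability grid for quantile-function comparison
#'
#' 1001 equispaced points on `[0.001, 0.999]`. The nominal tail integration
#' limits 0 and 1 are clipped to 0.001/0.999 because the Gaussian reference
#' quantile function is unbounded at the endpoints.
#'
#' @return Numeric vector of probabilities.
#' @export
default_y_grid <- function() seq(0.001, 0.999, length.out = 1001)

#' Kernel density estimate of an amplitude distribution
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on a
#' regular grid extending three bandwidths past the data range, then
#' renormalised to integrate to one.
#'
#' @param x numeric sample (at least 50 points; shape estimation on smaller
#'   samples is unreliable).
#' @param n_grid number of grid points.
#' @return Object of class `semg_density`: list with `grid`, `density`, `bw`.
#' @export
estimate_density <- function(x, n_grid = 512) {
  if (length(x) < 50) {
    .stop("insufficient_sample",
          "Need at least 50 samples for density shape estimation, got %d.",
          length(x))
  }
  d <- density(x, bw = "nrd0", kernel = "gaussian", n = n_grid, cut = 3)
  dx <- diff(d$x)
  area <- sum((d$y[-1] + d$y[-length(d$y)]) / 2 * dx)
  structure(list(grid = d$x, density = d$y / area, bw = d$bw),
            class = "semg_density")
}

#' @export
as_tibble.semg_density <- function(x, ...) tibble(grid = x$grid, density = x$density)

#' Sample and Gaussian-reference quantile functions
#'
#' Inverts the estimated density's CDF on a probability grid and pairs it
#' with the standard normal quantile function, the reference shape for a
#' z-scored signal with maximally unsynchronised motor-unit contributions.
#'
#' @param dens an `semg_density` from [estimate_density()].
#' @param y probability grid, strictly increasing inside (0, 1).
#' @return Object of class `semg_qpair`: list with `y`, `P_inv`, `G_inv`,
#'   and (after [register_to_gaussian()]) `alpha`, `beta`.
#' @export
quantile_functions <- function(dens, y = default_y_grid()) {
  if (!inherits(dens, "semg_density")) {
    .stop("parameter", "`dens` must come from estimate_density().")
  }
  if (any(y <= 0) || any(y >= 1) || is.unsorted(y, strictly = TRUE)) {
    .stop("domain", "Probability grid must be strictly increasing inside (0, 1).")
  }
  g <- dens$grid
  dx <- diff(g)
  cdf <- c(0, cumsum((dens$density[-1] + dens$density[-length(g)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0) # drop flat tail stretches for inversion
  P_inv <- approx(cdf[keep], g[keep], xout = y, rule = 2)$y
  structure(list(y = y, P_inv = P_inv, G_inv = qnorm(y),
                 alpha = NULL, beta = NULL),
            class = "semg_qpair")
}

# trapezoid weights on a (not necessarily uniform) grid
.trapz_w <- function(y) {
  n <- length(y)
  w <- numeric(n)
  w[1] <- (y[2] - y[1]) / 2
  w[n] <- (y[n] - y[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  w
}

#' Affinely register a sample quantile function to the Gaussian reference
#'
#' Finds `alpha > 0`, `beta` minimising the integrated squared difference
#' `integral((alpha * P_inv(y) + beta - G_inv(y))^2 dy)` over the probability
#' grid (trapezoid quadrature). The registration absorbs location and scale,
#' so the residual discrepancy measured afterwards is pure shape.
#'
#' @param pair an `semg_qpair` from [quantile_functions()].
#' @return The pair with `alpha` and `beta` filled in.
#' @export
register_to_gaussian <- function(pair) {
  if (!inherits(pair, "semg_qpair")) {
    .stop("parameter", "`pair` must come from quantile_functions().")
  }
  if (length(pair$y) < 10) {
    .stop("parameter", "Need at least 10 grid points to register.")
  }
  w <- .trapz_w(pair$y)
  P <- pair$P_inv
  G <- pair$G_inv
  Pm <- sum(w * P) / sum(w)
  Gm <- sum(w * G) / sum(w)
  spp <- sum(w * (P - Pm)^2)
  if (spp <= 1e-14 * max(1, Gm^2)) {
    .stop("registration", "Degenerate (constant) sample quantile function.")
  }
  alpha <- sum(w * (P - Pm) * (G - Gm)) / spp
  if (alpha <= 0) {
    .stop("registration",
          "Orientation-preserving registration impossible (alpha <= 0).")
  }
  pair$alpha <- alpha
  pair$beta <- Gm - alpha * Pm
  pair
}

# integral of the squared registered residual over [a, b], linear
# interpolation at the endpoints, trapezoid inside
.band_integral <- function(y, v, a, b) {
  n <- length(y)
  a <- max(a, y[1])
  b <- min(b, y[n])
  if (b <= a) return(0)
  lerp <- function(p) {
    i <- findInterval(p, y, all.inside = TRUE)
    v[i] + (v[i + 1] - v[i]) * (p - y[i]) / (y[i + 1] - y[i])
  }
  inner <- which(y > a & y < b)
  ys <- c(a, y[inner], b)
  vs <- c(lerp(a), v[inner], lerp(b))
  sum((vs[-1] + vs[-length(vs)]) / 2 * diff(ys))
}

#' Central, left and right shape distances
#'
#' Square roots of the integrals of the squared registered quantile residual
#' `(alpha * P_inv + beta - G_inv)^2` over the central (`y in [0.4, 0.6]`,
#' peakedness), left-tail (`y in [0, 0.25]`) and right-tail
#' (`y in [0.75, 1]`) probability ranges; the tail limits 0 and 1 are
#' clipped to the grid ends. All three are zero for an exactly Gaussian
#' sample distribution and grow as the amplitude PDF departs from
#' Gaussianity (e.g. towards a Laplacian under increased motor-unit
#' synchronisation, which accentuates the tails).
#'
#' @param pair a registered `semg_qpair` (see [register_to_gaussian()]).
#' @return One-row tibble with columns `CSD`, `LSD`, `RSD`.
#' @export
shape_distances <- function(pair) {
  if (!inherits(pair, "semg_qpair")) {
    .stop("parameter", "`pair` must come from quantile_functions().")
  }
  if (is.null(pair$alpha)) {
    .stop("state", "Quantile pair has not been registered; call register_to_gaussian().")
  }
  res2 <- (pair$alpha * pair$P_inv + pair$beta - pair$G_inv)^2
  y <- pair$y
  tibble(
    CSD = sqrt(.band_integral(y, res2, 0.4, 0.6)),
    LSD = sqrt(.band_integral(y, res2, 0, 0.25)),
    RSD = sqrt(.band_integral(y, res2, 0.75, 1))
  )
}

#' Shape distances of a raw sample
#'
#' Convenience chain: [estimate_density()], [quantile_functions()],
#' [register_to_gaussian()], [shape_distances()].
#'
#' @param x numeric sample.
#' @param y probability grid.
#' @return One-row tibble with `CSD`, `LSD`, `RSD`.
#' @export
csm_distances <- function(x, y = default_y_grid()) {
  v <- .csm_values(x, y)
  tibble(CSD = v[["CSD"]], LSD = v[["LSD"]], RSD = v[["RSD"]])
}

# named-vector fast path used by bulk feature extraction
.csm_values <- function(x, y = default_y_grid()) {
  pair <- register_to_gaussian(quantile_functions(estimate_density(x), y))
  res2 <- (pair$alpha * pair$P_inv + pair$beta - pair$G_inv)^2
  c(CSD = sqrt(.band_integral(y, res2, 0.4, 0.6)),
    LSD = sqrt(.band_integral(y, res2, 0, 0.25)),
    RSD = sqrt(.band_integral(y, res2, 0.75, 1)))
}
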