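# all permutations of 1..n as rows (n! x n); used for exact Spearman p
.perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- .perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# two-sided Spearman p-value: exhaustive permutation enumeration for small
# tie-free samples, asymptotic t approximation otherwise
.spearman_test <- function(x, y) {
  rho <- cor(x, y, method = "spearman")
  n <- length(x)
  if (n <= 8 && !anyDuplicated(x) && !anyDuplicated(y)) {
    rx <- rank(x)
    ry <- rank(y)
    pm <- .perms(n)
    d2 <- rowSums((matrix(rx[t(pm)], ncol = n, byrow = TRUE) -
                     matrix(ry, nrow = nrow(pm), ncol = n, byrow = TRUE))^2)
    rho_perm <- 1 - 6 * d2 / (n * (n^2 - 1))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
    )
  }
  list(rho = rho, p = p)
}

#' Screen features for age and BMI confounding
#'
#' Computes, for every (muscle, epoch, feature) cell, the Spearman rank
#' correlation between the subjects' trial-averaged feature values and each
#' cofactor (age in years, BMI in kg/m^2 derived from body mass and height),
#' and flags cells with `p < 0.05` for smooth-model adjustment with
#' [gam_adjust()].
#'
#' @param data long feature tibble carrying per-subject `age`, `body_mass`
#'   and `height` columns (as produced by [cohort_features()]).
#' @param cofactors subset of `c("age", "bmi")`.
#' @param alpha flagging threshold.
#' @return Tibble with columns `muscle`, `epoch`, `feature`, `cofactor`,
#'   `rho`, `p_value`, `flagged`.
#' @export
spearman_screen <- function(data, cofactors = c("age", "bmi"), alpha = 0.05) {
  cofactors <- match.arg(cofactors, several.ok = TRUE)
  subj <- data %>%
    group_by(.data$subject_id, .data$muscle, .data$epoch, .data$feature) %>%
    summarise(value = mean(.data$value),
              age = .data$age[1],
              bmi = .data$body_mass[1] / .data$height[1]^2,
              .groups = "drop")
  if (length(unique(subj$subject_id)) < 5) {
    .stop("design", "Need at least 5 subjects with cofactor values.")
  }
  subj %>%
    tidyr::pivot_longer(dplyr::all_of(cofactors),
                        names_to = "cofactor", values_to = "x") %>%
    group_by(.data$muscle, .data$epoch, .data$feature, .data$cofactor) %>%
    dplyr::group_modify(function(g, key) {
      if (sd(g$x) == 0) {
        .stop("undefined_correlation", "Cofactor is constant across subjects.")
      }
      st <- .spearman_test(g$x, g$value)
      tibble(rho = st$rho, p_value = st$p)
    }) %>%
    ungroup() %>%
    mutate(flagged = .data$p_value < alpha)
}

#' Remove a smooth cofactor effect from a feature
#'
#' Fits a univariate penalised regression spline `Y ~ s(X)` (smoothness by
#' generalised cross-validation) and returns the corrected values
#' `Y_C = Y - f(X)` (the fit residuals). With fewer than 8 distinct cofactor
#' values the smooth is unidentifiable and a linear fit is used instead,
#' with a warning.
#'
#' @param y feature values (one per subject).
#' @param x cofactor values, same length.
#' @return Numeric vector of corrected values, same length as `y`.
#' @export
gam_adjust <- function(y, x) {
  stopifnot(length(y) == length(x))
  nu <- length(unique(x))
  if (nu < 8) {
    warn("Fewer than 8 distinct cofactor values; using a linear correction.")
    return(unname(residuals(lm(y ~ x))))
  }
  k <- min(10L, nu - 1L)
  fit <- mgcv::gam(y ~ s(x, k = k), method = "GCV.Cp")
  unname(residuals(fit))
}

#' Wilcoxon rank-sum screen for sex differences
#'
#' Two-sided rank-sum test comparing male and female subjects'
#' trial-averaged feature values per (muscle, feature) cell within one
#' epoch, used to check that group contrasts are not driven by the sex
#' imbalance of the cohort.
#'
#' @param data long feature tibble with a per-subject `sex` column
#'   (`"M"` / `"F"`).
#' @param epoch epoch name to test within.
#' @return Tibble with columns `muscle`, `feature`, `p_value`.
#' @export
sex_difference_test <- function(data, epoch) {
  d <- data[data$epoch == epoch, ]
  if (!nrow(d)) .stop("empty_input", "No rows for epoch '%s'.", epoch)
  subj <- d %>%
    group_by(.data$subject_id, .data$muscle, .data$feature) %>%
    summarise(value = mean(.data$value), sex = .data$sex[1], .groups = "drop")
  if (length(unique(subj$sex)) < 2) {
    .stop("undefined_test", "Both sexes must be present.")
  }
  subj %>%
    group_by(.data$muscle, .data$feature) %>%
    summarise(p_value = suppressWarnings(
      wilcox.test(value ~ sex, data = dplyr::pick(dplyr::everything()),
                  exact = NULL)$p.value
    ), .groups = "drop")
}
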