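# Laplace quantile function, location 0, scale b (variance 2*b^2)
.qlaplace <- function(p, b) {
  -b * sign(p - 0.5) * log(1 - 2 * abs(p - 0.5))
}

#' Configuration of the synthetic perturbation cohort
#'
#' Describes a two-group cohort (control vs pre/sarcopenic) of repeated
#' forward balance perturbations: 14 subjects per group, 10 trials, four
#' lower-leg channels at 2000 Hz, with group-level generative knobs mapped
#' to the features the analysis extracts. The defaults plant the qualitative
#' group effects reported for the post-perturbation stabilisation window:
#' lower amplitude (scale 0.7), lower complexity (more narrowband carrier
#' energy) and a Laplacian amplitude marginal (heavier tails, the signature
#' of increased motor-unit synchronisation) in the pre/sarcopenic group,
#' plus a flatter adaptation slope over trials.
#'
#' @param n_per_group subjects per group.
#' @param n_trials perturbation trials per subject.
#' @param fs sampling rate (Hz).
#' @param specs epoch table, see [epoch_specs()].
#' @param amplitude_scale named (`control`, `presarc`) multiplicative
#'   amplitude scales (controls RMS).
#' @param trial_slope named per-trial fractional amplitude change
#'   (adaptation; controls the Trial and Group:Trial effects).
#' @param complexity_mix named weight in `[0, 1]` of broadband (vs
#'   narrowband) carrier power; lower values give a more regular signal and
#'   lower sample entropy.
#' @param spectral_center named centre (Hz) of the narrowband carrier
#'   component (controls MDF).
#' @param narrowband_halfwidth half-width (Hz) of the narrowband component.
#' @param carrier_band broadband carrier band (Hz), inside the 20-500 Hz
#'   analysis band.
#' @param marginal named amplitude marginal family per group,
#'   `"gaussian"` or `"laplacian"` (controls the shape distances).
#' @param subject_sd SD of the log-normal per-subject amplitude intercept.
#' @param resid_sd SD of the log-normal per-trial amplitude jitter.
#' @param line_amplitude amplitude of the additive mains sinusoid (z-units
#'   before normalisation).
#' @param line_freq mains frequency (Hz).
#' @param envelope named per-epoch activation levels (dimensionless); the
#'   envelope is piecewise-constant per epoch with 20 ms cosine ramps, a
#'   quiescent pre-onset level, a burst during the automatic response and a
#'   stabilisation plateau afterwards.
#' @param guard_level envelope level outside the defined epochs.
#' @param seed optional RNG seed; a fixed seed makes [simulate_cohort()]
#'   byte-identical.
#' @return A validated list of class `semg_sim_config`.
#' @export
cohort_config <- function(n_per_group = 14, n_trials = 10, fs = 2000,
                          specs = epoch_specs(),
                          amplitude_scale = c(control = 1, presarc = 0.7),
                          trial_slope = c(control = -0.015, presarc = 0.01),
                          complexity_mix = c(control = 0.8, presarc = 0.45),
                          spectral_center = c(control = 110, presarc = 110),
                          narrowband_halfwidth = 25,
                          carrier_band = c(20, 450),
                          marginal = c(control = "gaussian",
                                       presarc = "laplacian"),
                          subject_sd = 0.15, resid_sd = 0.05,
                          line_amplitude = 0.1, line_freq = 60,
                          envelope = c("Pre-prep" = 0.5, "Pre-vol" = 0.7,
                                       "Auto-resp" = 3, "Stab" = 2,
                                       "Post-stab" = 1.2),
                          guard_level = 0.4, seed = NULL) {
  cfg <- list(
    n_per_group = n_per_group, n_trials = n_trials, fs = fs,
    specs = .check_epoch_specs(specs),
    amplitude_scale = amplitude_scale, trial_slope = trial_slope,
    complexity_mix = complexity_mix, spectral_center = spectral_center,
    narrowband_halfwidth = narrowband_halfwidth, carrier_band = carrier_band,
    marginal = marginal, subject_sd = subject_sd, resid_sd = resid_sd,
    line_amplitude = line_amplitude, line_freq = line_freq,
    envelope = envelope, guard_level = guard_level, seed = seed
  )
  groups <- c("control", "presarc")
  for (nm in c("amplitude_scale", "trial_slope", "complexity_mix",
               "spectral_center", "marginal")) {
    if (!all(groups %in% names(cfg[[nm]]))) {
      .stop("config", "`%s` must be named with control and presarc entries.", nm)
    }
  }
  nyq <- fs / 2
  band_lo <- min(carrier_band, spectral_center - narrowband_halfwidth)
  band_hi <- max(carrier_band, spectral_center + narrowband_halfwidth)
  if (band_lo <= 0 || band_hi >= nyq) {
    .stop("config", "Carrier bands must lie strictly inside (0, %g) Hz.", nyq)
  }
  if (n_trials < 2) .stop("config", "Need at least 2 trials.")
  if (subject_sd < 0 || resid_sd < 0) .stop("config", "SDs must be >= 0.")
  if (!all(marginal %in% c("gaussian", "laplacian"))) {
    .stop("config", "Marginal families must be gaussian or laplacian.")
  }
  structure(cfg, class = "semg_sim_config")
}

# per-trial sample geometry: 100 ms guard on each side of the epoch extent
.trial_geometry <- function(config) {
  fs <- config$fs
  n_pre <- round((-min(config$specs$start_ms) + 100) * fs / 1000)
  n_post <- round((max(config$specs$end_ms) + 100) * fs / 1000)
  list(n = n_pre + n_post, onset = n_pre + 1L)
}

# piecewise-constant per-epoch activation envelope with 20 ms cosine ramps
.trial_envelope <- function(config) {
  geom <- .trial_geometry(config)
  t_ms <- (seq_len(geom$n) - geom$onset) * 1000 / config$fs
  env <- rep(config$guard_level, geom$n)
  for (i in seq_len(nrow(config$specs))) {
    sp <- config$specs[i, ]
    env[t_ms >= sp$start_ms & t_ms < sp$end_ms] <-
      config$envelope[[sp$epoch]]
  }
  # smooth with a 20 ms Hann kernel so epoch transitions are not steps
  m <- round(0.02 * config$fs)
  if (m >= 3) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
    w <- w / sum(w)
    env <- as.numeric(stats::filter(c(rep(env[1], m), env, rep(env[geom$n], m)),
                                    w, sides = 2))[(m + 1):(m + geom$n)]
  }
  env
}

#' Simulate one perturbation trial
#'
#' Generates the four-channel signal of a single trial: per channel, white
#' noise shaped in the frequency domain to a mixture of a broadband and a
#' narrowband component (the complexity/spectral knobs), rank-remapped to
#' the configured marginal family, scaled by
#' `group scale * subject intercept * (1 + slope * (trial - 1))` and by the
#' per-epoch activation envelope, with an optional additive mains sinusoid.
#'
#' @param config an `semg_sim_config`.
#' @param group `"control"` or `"presarc"`.
#' @param intercept per-subject multiplicative amplitude intercept.
#' @param trial trial number (1-based).
#' @param envelope precomputed envelope vector (internal reuse); defaults to
#'   the config's envelope.
#' @param gain precomputed carrier amplitude gain vector (internal reuse).
#' @return List with `samples` (time x 4 matrix) and `onset` (sample index
#'   of perturbation onset).
#' @export
simulate_trial_signal <- function(config, group, intercept = 1, trial = 1,
                                  envelope = NULL, gain = NULL) {
  if (!inherits(config, "semg_sim_config")) {
    .stop("config", "`config` must come from cohort_config().")
  }
  geom <- .trial_geometry(config)
  env <- envelope %||% .trial_envelope(config)
  n <- geom$n
  fs <- config$fs
  g <- gain %||% .gain_vector(n, fs, .carrier_gain_fn(config, group))
  # the rank remap evaluates the marginal quantile function on the fixed
  # grid (k - 0.5)/n only, so precompute it once per trial
  qgrid <- .marginal_grid(config$marginal[[group]], n)
  amp <- config$amplitude_scale[[group]] * intercept *
    (1 + config$trial_slope[[group]] * (trial - 1))
  carriers <- .apply_gain(matrix(rnorm(4 * n), n, 4), fs, g)
  jitter <- exp(rnorm(4, 0, config$resid_sd))
  samples <- vapply(seq_len(4), function(ch) {
    rk <- integer(n)
    rk[order(carriers[, ch])] <- seq_len(n)
    amp * jitter[ch] * env * qgrid[rk] # exact marginal, order kept
  }, numeric(n))
  if (config$line_amplitude > 0) {
    tt <- (seq_len(n) - geom$onset) / fs
    samples <- samples + config$line_amplitude *
      sin(outer(2 * pi * config$line_freq * tt, runif(4, 0, 2 * pi), "+"))
  }
  colnames(samples) <- .muscles
  list(samples = samples, onset = geom$onset)
}

.marginal_grid <- function(family, n) {
  p <- (seq_len(n) - 0.5) / n
  if (family == "laplacian") .qlaplace(p, 1 / sqrt(2)) else qnorm(p)
}

# amplitude gain shaping the white-noise carrier: power mixture of a
# broadband and a narrowband (complexity knob) component
.carrier_gain_fn <- function(config, group) {
  w_mix <- config$complexity_mix[[group]]
  centre <- config$spectral_center[[group]]
  hw <- config$narrowband_halfwidth
  cb <- config$carrier_band
  function(f) {
    sqrt(w_mix * .band_gain(f, cb[1], cb[2], 4) +
           (1 - w_mix) * .band_gain(f, centre - hw, centre + hw, 4))
  }
}

# truncated normal by rejection
.rtnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a full perturbation cohort
#'
#' Draws per-group demographics (age, body mass, height from the cohort's
#' reported group means and SDs; sex with the reported 3/11 vs 7/7 male to
#' female imbalance), per-subject log-normal amplitude intercepts, and one
#' concatenated multi-trial recording per subject via
#' [simulate_trial_signal()]. The generative parameters are returned as a
#' ground-truth log for parameter-recovery tests.
#'
#' @param config an `semg_sim_config` from [cohort_config()].
#' @return Object of class `semg_cohort`: list with `recordings` (named list
#'   of [semg_recording]), `subjects` (metadata tibble), `truth` (per-subject
#'   intercepts plus the config), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "semg_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_per_group
  demo <- list(
    control = list(age = c(68.85, 3.50), mass = c(70.90, 13.08),
                   height = c(1.61, 0.07), male_frac = 7 / 14),
    presarc = list(age = c(70.21, 2.80), mass = c(75.04, 12.15),
                   height = c(1.57, 0.09), male_frac = 3 / 14)
  )
  subjects <- purrr::imap(demo, function(d, g) {
    n_m <- round(n * d$male_frac)
    tibble(
      subject_id = sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(n)),
      group = g,
      sex = sample(c(rep("M", n_m), rep("F", n - n_m))),
      age = .rtnorm(n, d$age[1], d$age[2], 60, 85),
      body_mass = .rtnorm(n, d$mass[1], d$mass[2], 40, 120),
      height = .rtnorm(n, d$height[1], d$height[2], 1.35, 1.90),
      intercept = exp(rnorm(n, 0, config$subject_sd))
    )
  }) %>% bind_rows()

  env <- .trial_envelope(config)
  geom <- .trial_geometry(config)
  gains <- lapply(
    setNames(nm = c("control", "presarc")),
    function(g) .gain_vector(geom$n, config$fs, .carrier_gain_fn(config, g))
  )
  recordings <- purrr::pmap(
    subjects, function(subject_id, group, sex, age, body_mass, height,
                       intercept) {
      trials <- lapply(seq_len(config$n_trials), function(tr) {
        simulate_trial_signal(config, group, intercept, tr, envelope = env,
                              gain = gains[[group]])
      })
      semg_recording(
        samples = do.call(rbind, lapply(trials, `[[`, "samples")),
        fs = config$fs,
        onsets = geom$onset + (seq_len(config$n_trials) - 1L) * geom$n,
        muscles = .muscles,
        meta = list(subject_id = subject_id, group = group, sex = sex,
                    age = age, body_mass = body_mass, height = height)
      )
    })
  names(recordings) <- subjects$subject_id
  structure(
    list(recordings = recordings,
         subjects = select(subjects, -"intercept"),
         truth = list(intercepts = select(subjects, "subject_id", "intercept"),
                      config = config),
         config = config),
    class = "semg_cohort"
  )
}

#' @export
print.semg_cohort <- function(x, ...) {
  cat(sprintf("<semg_cohort> %d subjects (%d per group), %d trials each @ %g Hz\n",
              nrow(x$subjects), x$config$n_per_group, x$config$n_trials,
              x$config$fs))
  invisible(x)
}

#' Run the full feature-extraction pipeline on a cohort
#'
#' Conditions each subject's recording ([preprocess_recording()]), cuts the
#' perturbation-locked epochs ([segment_epochs()]), extracts the requested
#' features ([build_feature_table()]) and joins the subject metadata,
#' producing the long table the mixed-model stage consumes.
#'
#' @param cohort an `semg_cohort` (or a list with `recordings` and
#'   `subjects`).
#' @param features feature subset, see [extract_features()].
#' @param epochs optional epoch-name subset to restrict extraction to.
#' @param preprocess set `FALSE` to skip signal conditioning (for raw-signal
#'   diagnostics only).
#' @param ... passed on to [build_feature_table()].
#' @return Long feature tibble with subject metadata columns.
#' @export
cohort_features <- function(cohort,
                            features = c("RMS", "MDF", "SAMPEN",
                                         "CSD", "RSD", "LSD"),
                            epochs = NULL, preprocess = TRUE, ...) {
  specs <- cohort$config$specs %||% epoch_specs()
  line_freq <- cohort$config$line_freq %||% 60
  if (!is.null(epochs)) specs <- specs[specs$epoch %in% epochs, ]
  g <- if (preprocess) {
    r1 <- cohort$recordings[[1]]
    .preprocess_gain(nrow(r1$samples), r1$fs, line_freq)
  }
  tab <- purrr::map(cohort$recordings, function(rec) {
    if (preprocess) rec <- preprocess_recording(rec, line_freq = line_freq,
                                                .gain = g)
    build_feature_table(segment_epochs(rec, specs = specs),
                        features = features, ...)
  }) %>% bind_rows()
  left_join(tab,
            select(cohort$subjects, "subject_id", "sex", "age",
                   "body_mass", "height"),
            by = "subject_id")
}

#' Simulate a feature table directly from the mixed model
#'
#' Draws feature values straight from the Group x Trial random-intercept
#' model (no signal stage): `value = b0 + b_g * presarc + b_t * trial +
#' b_gt * presarc * trial + u_subject + e`. Used for type-I-error and
#' parameter-recovery calibration of the inference stage.
#'
#' @param n_per_group subjects per group.
#' @param n_trials trials per subject.
#' @param beta fixed effects, named `intercept`, `group`, `trial`,
#'   `interaction`.
#' @param subject_sd random-intercept SD.
#' @param resid_sd residual SD.
#' @return Tibble with `subject_id`, `group`, `trial`, `value`.
#' @export
simulate_feature_table <- function(n_per_group = 14, n_trials = 10,
                                   beta = c(intercept = 0, group = 0,
                                            trial = 0, interaction = 0),
                                   subject_sd = 1, resid_sd = 1) {
  subjects <- tibble(
    subject_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = rep(c("control", "presarc"), each = n_per_group),
    u = rnorm(2 * n_per_group, 0, subject_sd)
  )
  tidyr::expand_grid(subjects, trial = seq_len(n_trials)) %>%
    mutate(
      g = as.integer(.data$group == "presarc"),
      value = beta[["intercept"]] + beta[["group"]] * .data$g +
        beta[["trial"]] * .data$trial +
        beta[["interaction"]] * .data$g * .data$trial +
        .data$u + rnorm(n(), 0, resid_sd)
    ) %>%
    select("subject_id", "group", "trial", "value")
}
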