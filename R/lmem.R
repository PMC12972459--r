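# canonical fixed-effect labels for the Group*Trial model
.term_map <- c(
  "(Intercept)" = "Intercept",
  "grouppresarc" = "Group",
  "trial" = "Trial",
  "grouppresarc:trial" = "Group:Trial"
)

.as_group_factor <- function(group) {
  factor(as.character(group), levels = c("control", "presarc"))
}

#' Fit the Group x Trial linear mixed model for one analysis cell
#'
#' Fits `value ~ group * trial + (1 | subject_id)` by REML for one
#' (muscle, epoch, feature) cell: `group` is a two-level factor with
#' `control` as reference, `trial` the integer trial index 1..n, and the
#' random intercept absorbs stable between-subject amplitude differences.
#' Fixed effects are tested with asymptotic Wald z tests
#' (`p = 2 * (1 - pnorm(|estimate / se|))`). The `Group` coefficient is the
#' between-group value difference, `Trial` the per-trial adaptation slope of
#' the reference group, and `Group:Trial` the between-group slope
#' difference (differential motor adaptation).
#'
#' @param data long feature tibble with columns `subject_id`, `group`,
#'   `trial`, `feature`, `value` (and optionally `muscle`, `epoch`).
#' @param muscle,epoch,feature optional cell selectors; rows are filtered to
#'   the selected cell before fitting.
#' @return Object of class `semg_lmem` with the [lme4::lmer()] fit, a tidy
#'   coefficient table, variance components and a convergence flag. Use
#'   [tidy()] / [glance()] to extract them.
#' @export
fit_group_trial_model <- function(data, muscle = NULL, epoch = NULL,
                                  feature = NULL) {
  cell <- list(muscle = muscle, epoch = epoch, feature = feature)
  for (v in names(cell)) {
    if (!is.null(cell[[v]]) && v %in% names(data)) {
      data <- data[data[[v]] == cell[[v]], ]
    }
  }
  if (!nrow(data)) .stop("empty_input", "No rows for the requested cell.")
  data$group <- .as_group_factor(data$group)
  if (anyNA(data$group)) {
    .stop("design", "Group labels must be 'control' or 'presarc'.")
  }
  n_per_group <- tapply(data$subject_id, data$group,
                        function(s) length(unique(s)))
  if (any(is.na(n_per_group)) || any(n_per_group < 2)) {
    .stop("design", "Need at least two subjects in each group.")
  }
  if (max(tapply(data$trial, data$subject_id,
                 function(t) length(unique(t)))) < 2) {
    .stop("design", "Need at least two trials per subject.")
  }
  data$trial <- as.numeric(data$trial)

  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(
      value ~ group * trial + (1 | subject_id),
      data = data, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)
    ))),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # zero-residual (interpolating) data defeats the mixed-model deviance;
    # the fixed effects are then just the least-squares solution
    ls_fit <- lm(value ~ group * trial, data = data)
    cf <- summary(ls_fit)$coefficients
    coefs <- tibble(
      term = unname(.term_map[rownames(cf)]),
      estimate = cf[, 1], std_error = cf[, 2],
      statistic = cf[, 1] / cf[, 2],
      p_value = 2 * pnorm(-abs(cf[, 1] / cf[, 2]))
    )
    out <- list(fit = ls_fit, cell = cell, coefs = coefs,
                subject_var = 0, resid_var = mean(residuals(ls_fit)^2),
                converged = TRUE, nobs = nrow(data))
    return(structure(out, class = "semg_lmem"))
  }

  cf <- coef(summary(fit))
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  z <- est / se
  coefs <- tibble(
    term = unname(.term_map[rownames(cf)]),
    estimate = unname(est), std_error = unname(se),
    statistic = unname(z), p_value = 2 * pnorm(-abs(unname(z)))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  converged <- length(fit@optinfo$conv$lme4) == 0 ||
    is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code >= 0
  if (!converged) coefs$p_value <- NA_real_
  structure(
    list(fit = fit, cell = cell, coefs = coefs,
         subject_var = vc$vcov[vc$grp == "subject_id"],
         resid_var = vc$vcov[vc$grp == "Residual"],
         converged = converged, nobs = nrow(data)),
    class = "semg_lmem"
  )
}

#' @export
print.semg_lmem <- function(x, ...) {
  cell <- purrr::compact(x$cell)
  if (length(cell)) {
    cat("<semg_lmem>", paste(unlist(cell), collapse = " / "), "\n")
  } else {
    cat("<semg_lmem>\n")
  }
  print(x$coefs)
  cat(sprintf("subject var %.4g, residual var %.4g, converged: %s\n",
              x$subject_var, x$resid_var, x$converged))
  invisible(x)
}

#' @rdname fit_group_trial_model
#' @param x an `semg_lmem` object.
#' @param ... unused.
#' @export
tidy.semg_lmem <- function(x, ...) x$coefs

#' @rdname fit_group_trial_model
#' @export
glance.semg_lmem <- function(x, ...) {
  tibble(subject_var = x$subject_var, resid_var = x$resid_var,
         converged = x$converged, nobs = x$nobs)
}

#' Fit the Group x Trial model in every analysis cell
#'
#' Maps [fit_group_trial_model()] over all (muscle, epoch, feature)
#' combinations present in the table and stacks the tidy fixed-effect rows.
#'
#' @param data long feature tibble (see [fit_group_trial_model()]).
#' @return Tibble with columns `muscle`, `epoch`, `feature`, `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`, `converged`.
#' @export
fit_all_cells <- function(data) {
  cells <- distinct(data, .data$muscle, .data$epoch, .data$feature)
  purrr::pmap(cells, function(muscle, epoch, feature) {
    m <- fit_group_trial_model(data, muscle = muscle, epoch = epoch,
                               feature = feature)
    mutate(tidy(m), muscle = muscle, epoch = epoch, feature = feature,
           converged = m$converged)
  }) %>%
    bind_rows() %>%
    select("muscle", "epoch", "feature", "term", "estimate",
           "std_error", "statistic", "p_value", "converged")
}

#' Wide p-value table for one model term
#'
#' Reshapes [fit_all_cells()] output into the (muscle, epoch) x feature
#' p-value matrix layout used by the significance summary and the shipped
#' fixture tables.
#'
#' @param fits tibble from [fit_all_cells()].
#' @param term one of `"Group"`, `"Trial"`, `"Group:Trial"`.
#' @return Tibble with columns `muscle`, `epoch` and one column per feature.
#' @export
pvalue_table <- function(fits, term = "Group:Trial") {
  fits %>%
    filter(.data$term == .env$term) %>%
    select("muscle", "epoch", "feature", "p_value") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "p_value")
}

#' Count significant effects per epoch
#'
#' Tallies, per epoch, the (muscle, feature) cells whose interaction
#' (`Group:Trial`) and group-difference p-values fall at or below the
#' significance threshold, plus their sum. The threshold is inclusive
#' (`p <= alpha`) so that boundary values printed as 0.050 count as
#' significant. Missing cells are counted as non-significant with a warning.
#'
#' @param interaction,group wide p-value tables (columns `muscle`, `epoch`,
#'   then one column per feature), e.g. from [pvalue_table()] or
#'   [load_pvalue_fixture()].
#' @param alpha significance threshold.
#' @return Tibble with columns `epoch`, `n_interaction`, `n_group`,
#'   `n_total`, ordered in protocol epoch order.
#' @export
summarize_significance <- function(interaction, group, alpha = 0.05) {
  count_one <- function(tab, label) {
    long <- tidyr::pivot_longer(tab, -c("muscle", "epoch"),
                                names_to = "feature", values_to = "p")
    if (anyNA(long$p)) {
      warn(sprintf("%d missing %s p-value(s) counted as non-significant.",
                   sum(is.na(long$p)), label))
    }
    long %>%
      group_by(.data$epoch) %>%
      summarise(n = sum(.data$p <= alpha, na.rm = TRUE), .groups = "drop")
  }
  inter <- count_one(interaction, "interaction")
  grp <- count_one(group, "group")
  epochs_order <- intersect(epoch_specs()$epoch,
                            union(inter$epoch, grp$epoch))
  tibble(epoch = epochs_order) %>%
    left_join(rename(inter, n_interaction = "n"), by = "epoch") %>%
    left_join(rename(grp, n_group = "n"), by = "epoch") %>%
    mutate(across(c("n_interaction", "n_group"),
                  ~ tidyr::replace_na(.x, 0L)),
           n_total = .data$n_interaction + .data$n_group)
}

#' Annotate per-cell group trends
#'
#' Applies the figure-annotation rule: `V` for a significant group value
#' difference (`Group` p <= alpha), `S` for a significant slope difference
#' (`Group:Trial` p <= alpha), `V+S` for both, `none` otherwise, and derives
#' each group's fitted line over trials from the fixed effects.
#'
#' @param fits tibble from [fit_all_cells()].
#' @param alpha significance threshold.
#' @return Tibble of class `semg_trends`: one row per cell and group with
#'   `mark`, `intercept`, `slope`.
#' @export
annotate_trends <- function(fits, alpha = 0.05) {
  wide <- fits %>%
    select("muscle", "epoch", "feature", "term", "estimate", "p_value") %>%
    tidyr::pivot_wider(names_from = "term",
                       values_from = c("estimate", "p_value"))
  if (anyNA(wide$`p_value_Group`) || anyNA(wide$`p_value_Group:Trial`)) {
    warn("Missing p-values (non-converged fits) annotated as 'none'.")
  }
  marks <- wide %>%
    mutate(
      v = !is.na(.data$p_value_Group) & .data$p_value_Group <= alpha,
      s = !is.na(.data$`p_value_Group:Trial`) &
        .data$`p_value_Group:Trial` <= alpha,
      mark = dplyr::case_when(.data$v & .data$s ~ "V+S",
                              .data$v ~ "V",
                              .data$s ~ "S",
                              TRUE ~ "none")
    )
  out <- bind_rows(
    marks %>% mutate(group = "control",
                     intercept = .data$estimate_Intercept,
                     slope = .data$estimate_Trial),
    marks %>% mutate(group = "presarc",
                     intercept = .data$estimate_Intercept + .data$estimate_Group,
                     slope = .data$estimate_Trial + .data$`estimate_Group:Trial`)
  ) %>%
    select("muscle", "epoch", "feature", "group", "mark",
           "intercept", "slope") %>%
    arrange(.data$muscle, .data$epoch, .data$feature, .data$group)
  class(out) <- c("semg_trends", class(out))
  out
}

#' Plot annotated group trends
#'
#' One panel per (muscle, feature) cell showing each group's fitted line
#' over trials, labelled with the V/S significance mark; optional raw
#' per-trial group means as points.
#'
#' @param object an `semg_trends` tibble from [annotate_trends()].
#' @param data optional long feature tibble; when given, per-trial group
#'   means are overplotted as points.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.semg_trends <- function(object, data = NULL, ...) {
  trials <- if (!is.null(data)) sort(unique(data$trial)) else 1:10
  lines <- object %>%
    tidyr::expand_grid(trial = trials) %>%
    mutate(value = .data$intercept + .data$slope * .data$trial)
  p <- ggplot2::ggplot(lines, ggplot2::aes(x = .data$trial, y = .data$value,
                                           colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$feature),
                        cols = ggplot2::vars(.data$muscle), scales = "free_y") +
    ggplot2::geom_text(
      data = distinct(object, .data$muscle, .data$feature, .data$mark) %>%
        filter(.data$mark != "none"),
      ggplot2::aes(label = .data$mark), x = Inf, y = Inf,
      hjust = 1.1, vjust = 1.3, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "trial", y = "feature value", colour = "group")
  if (!is.null(data)) {
    pts <- data %>%
      dplyr::semi_join(distinct(object, .data$muscle, .data$feature),
                       by = c("muscle", "feature")) %>%
      group_by(.data$muscle, .data$feature, .data$group, .data$trial) %>%
      summarise(value = mean(.data$value), .groups = "drop")
    p <- p + ggplot2::geom_point(data = pts, size = 0.8, alpha = 0.7)
  }
  p
}
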