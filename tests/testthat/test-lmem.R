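test_that("noise-free data is interpolated exactly and Wald identity holds", {
  df <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:8), trial = 1:5)
  df$group <- rep(c("control", "presarc"), each = 20)
  g <- as.integer(df$group == "presarc")
  df$value <- 1 + 0.5 * g + 0.2 * df$trial - 0.1 * g * df$trial
  m <- fit_group_trial_model(df)
  est <- setNames(tidy(m)$estimate, tidy(m)$term)
  expect_equal(est[["Intercept"]], 1, tolerance = 1e-6)
  expect_equal(est[["Group"]], 0.5, tolerance = 1e-6)
  expect_equal(est[["Trial"]], 0.2, tolerance = 1e-6)
  expect_equal(est[["Group:Trial"]], -0.1, tolerance = 1e-6)

  set.seed(61)
  tab <- simulate_feature_table(beta = c(intercept = 1, group = 0.6,
                                         trial = 0.05, interaction = 0.02))
  td <- tidy(fit_group_trial_model(tab))
  expect_equal(td$p_value,
               2 * (1 - pnorm(abs(td$estimate / td$std_error))),
               tolerance = 1e-12)
  expect_true(glance(fit_group_trial_model(tab))$converged)

  one_group <- tab[tab$group == "control", ]
  expect_error(fit_group_trial_model(one_group),
               class = "semgadapt_error_design")
})

test_that("the Spearman screen flags monotone confounding with exact small-n p", {
  set.seed(62)
  base <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:6),
                             muscle = "TA", epoch = "Post-stab",
                             feature = "RMS", trial = 1:2)
  base$age <- rep(c(61, 64, 67, 70, 73, 76), each = 2)
  base$body_mass <- rep(c(60, 65, 70, 75, 80, 85), each = 2)
  base$height <- 1.6
  base$value <- base$age * 2 + 1 # strictly increasing in age

  scr <- spearman_screen(base)
  rho_age <- scr$rho[scr$cofactor == "age"]
  expect_equal(rho_age, 1)
  expect_true(scr$flagged[scr$cofactor == "age"])

  base$value <- -3 * (base$body_mass / base$height^2)
  scr2 <- spearman_screen(base)
  expect_equal(scr2$rho[scr2$cofactor == "bmi"], -1)

  # exact permutation p-value for n = 6: compare against full enumeration
  base$value <- rep(c(2.3, -1.1, 0.4, 5.2, 1.9, -0.7), each = 2)
  scr3 <- spearman_screen(base)
  enumerate_p <- function(x, y) {
    perm <- function(v) {
      if (length(v) == 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perm(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    obs <- cor(x, y, method = "spearman")
    all_r <- vapply(perm(seq_along(y)),
                    function(p) cor(x, y[p], method = "spearman"), numeric(1))
    mean(abs(all_r) >= abs(obs) - 1e-12)
  }
  subj_age <- c(61, 64, 67, 70, 73, 76)
  subj_val <- c(2.3, -1.1, 0.4, 5.2, 1.9, -0.7)
  expect_equal(scr3$p_value[scr3$cofactor == "age"],
               enumerate_p(subj_age, subj_val))

  base$age <- 70
  expect_error(spearman_screen(base, cofactors = "age"),
               class = "semgadapt_error_undefined_correlation")
})

test_that("smooth adjustment removes cofactor dependence without inventing one", {
  set.seed(63)
  x <- runif(200, 0, 6)
  y_indep <- rnorm(200)
  adj <- gam_adjust(y_indep, x)
  expect_equal(adj, y_indep - mean(y_indep), tolerance = 0.15)
  expect_lt(abs(cor(adj, x, method = "spearman")), 0.15)

  y_lin <- 2 * x + rnorm(200, 0, 1e-4)
  expect_lt(var(gam_adjust(y_lin, x)), 1e-6)

  y_sin <- sin(x) + rnorm(200, 0, 0.2)
  adj_sin <- gam_adjust(y_sin, x)
  expect_lt(abs(cor(adj_sin, x, method = "spearman")), 0.1)
  # adjustment never strengthens the monotone association
  expect_lte(abs(cor(adj_sin, x, method = "spearman")),
             abs(cor(y_sin, x, method = "spearman")))

  expect_warning(gam_adjust(rnorm(10), rep(1:5, 2)), "linear")
})

test_that("the sex screen reduces to the exact rank-sum distribution", {
  mk <- function(vals_m, vals_f) {
    tibble::tibble(
      subject_id = sprintf("S%d", seq_len(length(vals_m) + length(vals_f))),
      sex = rep(c("M", "F"), c(length(vals_m), length(vals_f))),
      muscle = "TA", feature = "RMS", epoch = "Post-stab",
      value = c(vals_m, vals_f), trial = 1
    )
  }
  same <- sex_difference_test(mk(c(1, 2, 3), c(3, 1, 2)), "Post-stab")
  expect_equal(same$p_value, 1)

  # disjoint ranges, 5 vs 5: the smallest achievable two-sided p
  disjoint <- sex_difference_test(mk(1:5, 6:10), "Post-stab")
  expect_equal(disjoint$p_value, 2 / choose(10, 5))

  # exact enumeration oracle for a small mixed case
  vm <- c(1.2, 3.4, 0.5)
  vf <- c(2.2, 5.1, 4.4, 0.9)
  got <- sex_difference_test(mk(vm, vf), "Post-stab")$p_value
  ranks <- rank(c(vm, vf))
  w_obs <- sum(ranks[1:3]) - 3 * 4 / 2
  all_w <- apply(utils::combn(7, 3), 2, function(i) sum(rank(c(vm, vf))[i])) -
    3 * 4 / 2
  p_exact <- min(1, 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs)))
  expect_equal(got, p_exact)

  onesex <- mk(c(1, 2), numeric(0))
  expect_error(sex_difference_test(onesex, "Post-stab"),
               class = "semgadapt_error_undefined_test")
})

test_that("significance counting reproduces the published per-epoch summary", {
  t3 <- load_pvalue_fixture(semgadapt_fixture("table3_interaction.csv"))
  t4 <- load_pvalue_fixture(semgadapt_fixture("table4_group.csv"))
  s <- summarize_significance(t3, t4)
  expect_equal(s$epoch,
               c("Pre-prep", "Pre-vol", "Auto-resp", "Stab", "Post-stab"))
  expect_equal(s$n_interaction, c(4, 3, 3, 1, 3))
  expect_equal(s$n_group, c(3, 5, 1, 5, 13))
  expect_equal(s$n_total, c(7, 8, 4, 6, 16))

  # the threshold is inclusive: a 0.050 entry counts
  expect_true(any(as.matrix(t3[semgadapt:::.features]) == 0.050))

  all_ones <- t3
  all_ones[semgadapt:::.features] <- 1
  s0 <- summarize_significance(all_ones, all_ones)
  expect_true(all(s0$n_total == 0))

  holed <- t3
  holed$RMS[3] <- NA
  expect_warning(s_na <- summarize_significance(holed, t4), "non-significant")
  expect_equal(s_na$n_total, s$n_total)
})

test_that("trend annotation applies the value/slope marking rule", {
  set.seed(64)
  tab <- dplyr::bind_rows(
    simulate_feature_table(beta = c(intercept = 0, group = 3, trial = 0,
                                    interaction = 0), resid_sd = 0.5) %>%
      dplyr::mutate(muscle = "TA", epoch = "Post-stab", feature = "RMS"),
    simulate_feature_table(beta = c(intercept = 0, group = 3, trial = 0,
                                    interaction = 1), resid_sd = 0.5) %>%
      dplyr::mutate(muscle = "GL", epoch = "Post-stab", feature = "RMS"),
    simulate_feature_table(beta = c(intercept = 0, group = 0, trial = 0,
                                    interaction = 0), resid_sd = 0.5) %>%
      dplyr::mutate(muscle = "GM", epoch = "Post-stab", feature = "RMS")
  )
  fits <- fit_all_cells(tab)
  ann <- annotate_trends(fits)
  marks <- ann %>% dplyr::distinct(muscle, mark)
  expect_equal(marks$mark[marks$muscle == "TA"], "V")
  expect_equal(marks$mark[marks$muscle == "GL"], "V+S")
  expect_equal(marks$mark[marks$muscle == "GM"], "none")

  # fitted lines come straight from the fixed effects
  gl <- fits[fits$muscle == "GL", ]
  b <- setNames(gl$estimate, gl$term)
  lines <- ann[ann$muscle == "GL", ]
  expect_equal(lines$slope[lines$group == "control"], b[["Trial"]])
  expect_equal(lines$slope[lines$group == "presarc"],
               b[["Trial"]] + b[["Group:Trial"]])

  p <- autoplot(ann, data = tab)
  expect_s3_class(p, "ggplot")
})
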