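test_that("Wald proportion intervals reproduce the published half-widths", {
  printed <- list(
    list(41, 67, 61.2, 11.7),   # low level-2 memory converters
    list(101, 268, 37.7, 5.8),  # overall conversion rate
    list(23, 35, 65.7, 15.7),   # low motor speed, APOE carrier
    list(14, 35, 40.0, 16.2),   # low motor speed, no APOE
    list(28, 48, 58.3, 13.9),   # low flexibility
    list(4, 41, 9.8, 9.1),      # high level-3 memory, no APOE
    list(16, 19, 84.2, 16.4))   # low memory + speed, APOE carrier
  for (case in printed) {
    got <- proportion_with_ci(case[[1]], case[[2]])
    expect_equal(round(got[["proportion"]], 1), case[[3]])
    expect_equal(round(got[["half_width"]], 1), case[[4]])
  }
  expect_equal(unname(proportion_with_ci(0, 50)), c(0, 0))
  expect_error(proportion_with_ci(3, 0), "n must be")
  expect_error(proportion_with_ci(5, 3), "k must lie")
})

test_that("two-sided Fisher matches full hypergeometric enumeration", {
  expect_lt(fisher_exact_two_sided(matrix(c(41, 26, 60, 141), 2)), 5e-4)
  expect_equal(fisher_exact_two_sided(matrix(c(1, 0, 0, 1), 2)), 1)
  set.seed(71)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    tab <- matrix(stats::rmultinom(1, n, prob = stats::runif(4, 0.2, 1)),
                  2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab), fisher_oracle(tab),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)),
               "degenerate")
})

test_that("subgroup rules follow their stated comparison semantics", {
  cohort <- data.frame(subject_id = c("a", "b", "c", "d"),
                       p_episodic_memory_level2 = c(0.20, 0.275, 0.30, 0.9),
                       p_perceptual_motor_speed_high = c(0.40, 0.41, 0.1, 1),
                       p_cognitive_flexibility_high = c(0.30, 0.31, 0.2, 1),
                       p_episodic_memory_level3 = c(0.80, 0.81, 0.1, 0.9),
                       apoe_e4 = c(0, 1, 2, 0))
  lab <- assign_subgroups(cohort)
  expect_equal(lab$em2_low, c(TRUE, FALSE, FALSE, FALSE))   # strictly below
  expect_equal(lab$pms_low, c(TRUE, FALSE, TRUE, FALSE))    # at or below
  expect_equal(lab$cf_low, c(TRUE, FALSE, TRUE, FALSE))     # at or below
  expect_equal(lab$em3_high, c(FALSE, TRUE, FALSE, TRUE))   # strictly above
  expect_equal(lab$apoe_positive, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(nrow(assign_subgroups(cohort[0, ])), 0)
  expect_error(assign_subgroups(data.frame(x = 1)), "missing probability")
})

test_that("contingency tables reproduce the published level-2 memory split", {
  # cohort built to the published counts: 41/67 converters among the
  # low-memory subgroup, 60/201 among the rest
  cohort <- data.frame(
    em2_low = rep(c(TRUE, FALSE), c(67, 201)),
    converted = c(rep(c(TRUE, FALSE), c(41, 26)),
                  rep(c(TRUE, FALSE), c(60, 141))))
  ct <- build_contingency(cohort, "em2_low")
  expect_equal(unname(ct$counts), matrix(c(41, 26, 60, 141), 2))
  expect_equal(unname(round(ct$proportions, 1)), c(61.2, 29.9))
  expect_equal(unname(round(ct$ci_half_widths, 1)), c(11.7, 6.3))
  expect_lt(ct$fisher_p, 5e-4)
  expect_equal(ct$odds_ratio, (41 * 141) / (26 * 60))
  # overall rate across both columns
  expect_equal(round(proportion_with_ci(41 + 60, 268)[["proportion"]], 1),
               37.7)
})

test_that("degenerate strata are flagged, uniform outcomes give p = 1", {
  cohort <- data.frame(em2_low = c(TRUE, TRUE, FALSE, FALSE),
                       converted = TRUE,
                       apoe_positive = FALSE)
  ct <- build_contingency(cohort, "em2_low")
  expect_true(ct$degenerate)
  ct2 <- build_contingency(cohort, "em2_low",
                           stratum = rep(FALSE, 4))
  expect_true(ct2$degenerate)
  expect_equal(sum(ct2$counts), 0)

  half <- data.frame(em2_low = c(TRUE, TRUE, FALSE, FALSE),
                     converted = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(build_contingency(half, "em2_low")$fisher_p, 1)
})

test_that("intercept-only logistic fit recovers the logit of the rate", {
  cohort <- data.frame(converted = rep(c(TRUE, FALSE), c(30, 70)))
  fit <- fit_logistic(cohort, "converted", character(0))
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               stats::qlogis(0.3), tolerance = 1e-6)
  expect_equal(fit$exp_b, exp(fit$coefficients), tolerance = 1e-9)
  expect_error(fit_logistic(data.frame(converted = rep(TRUE, 5)),
                            "converted", character(0)), "both classes")
})

test_that("complete separation is flagged, not silently returned", {
  cohort <- data.frame(x = c(-(5:1), 1:5),
                       converted = rep(c(FALSE, TRUE), each = 5))
  expect_warning(fit <- fit_logistic(cohort, "converted", "x"),
                 "separation")
  expect_true(fit$separation)
})

test_that("rank AUC equals the pairwise oracle and handles edge cases", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(72)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    sc <- sample(round(stats::rnorm(n), 1))  # coarse scores force ties
    lb <- stats::rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), auc_oracle(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("the model-based risk score outranks single covariates on training AUC", {
  cfg <- cohort_config(n_subjects = 800, seed = 73)
  coh <- generate_cohort(cfg, cp_model)
  em2 <- cogposet:::state_indicators(cp_model, "episodic_memory",
                                     "level2")[coh$subjects$true_state]
  pms <- cogposet:::state_indicators(cp_model, "perceptual_motor_speed",
                                     "high")[coh$subjects$true_state]
  cohort <- data.frame(converted = coh$subjects$converted,
                       em2 = em2, pms = pms,
                       apoe = as.numeric(coh$subjects$apoe_e4 >= 1))
  fit <- fit_logistic(cohort, "converted", c("em2", "pms", "apoe"))
  for (v in c("em2", "pms", "apoe")) {
    single <- fit_logistic(cohort, "converted", v)
    expect_gte(fit$auc + 1e-9, single$auc)
  }
})

test_that("nested-model comparison behaves like a chi-square deviance test", {
  set.seed(74)
  cohort <- data.frame(x = stats::rnorm(300))
  cohort$converted <- stats::runif(300) < stats::plogis(-0.3 + 0.8 * cohort$x)
  cohort$noise <- stats::rnorm(300)
  f1 <- fit_logistic(cohort, "converted", "x")
  f2 <- fit_logistic(cohort, "converted", c("x", "noise"))
  lt <- lr_test(f1, f2)
  expect_equal(lt$df, 1)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$p_value,
               stats::pchisq(lt$statistic, 1, lower.tail = FALSE))
})

test_that("trajectory profiles align converters to conversion and bin mass", {
  # one subject with constant certainty: all mass in the top bin everywhere
  rec <- data.frame(subject_id = "s1",
                    visit_month = c(0, 6, 12, 18, 24),
                    p = 1, converted = TRUE, conversion_month = 24)
  tp <- trajectory_profile(rec, "p")
  expect_true(all(tp$converters[, 10] == 1, na.rm = TRUE))
  expect_equal(unname(tp$n_converters), rep(1L, 5))
  expect_true(all(tp$n_nonconverters == 0))

  # no converters: populated non-converter panel only
  rec2 <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                     visit_month = c(0, 6, 0, 6), p = c(0.5, 0.5, 0.8, 0.8),
                     converted = FALSE, conversion_month = NA,
                     event_free_through = 36)
  tp2 <- trajectory_profile(rec2, "p", timepoints = c(0, 6))
  expect_true(all(tp2$n_converters == 0))
  expect_equal(unname(tp2$n_nonconverters), c(2L, 2L))

  # converters without a conversion month are dropped with a warning
  rec3 <- rec
  rec3$conversion_month <- NA
  expect_warning(tp3 <- trajectory_profile(rec3, "p"),
                 "without a conversion month")
  expect_true(all(tp3$n_converters == 0))
})
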