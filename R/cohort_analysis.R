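#' Define a cutoff subgroup rule
#'
#' A rule labels subjects by comparing one per-function functioning
#' probability against a cutoff. Comparison semantics are rule-level
#' because published cutoff wordings differ from rule to rule (e.g.
#' "less than 0.275" is strictly-below while "0.40 or less" is
#' at-or-below).
#'
#' @param fn function name.
#' @param level level label.
#' @param cutoff probability cutoff in (0, 1).
#' @param comparison one of `"lt"`, `"le"`, `"gt"`, `"ge"` (strictly below,
#'   at or below, strictly above, at or above).
#' @param label name for the resulting indicator column.
#' @return an object of class `subgroup_rule`.
#' @export
subgroup_rule <- function(fn, level, cutoff,
                          comparison = c("lt", "le", "gt", "ge"),
                          label = NULL) {
  comparison <- match.arg(comparison)
  stopifnot(cutoff > 0, cutoff < 1)
  if (is.null(label))
    label <- paste0(fn, "_", level, "_",
                    switch(comparison, lt = , le = "low",
                           gt = , ge = "high"))
  structure(list(fn = fn, level = level, cutoff = cutoff,
                 comparison = comparison, label = label),
            class = "subgroup_rule")
}

#' Default subgroup rules for the bundled battery
#'
#' The published cutoffs: episodic memory level 2 low when its probability
#' is strictly below 0.275; perceptual motor speed low at or below 0.40;
#' cognitive flexibility low at or below 0.30; episodic memory level 3 high
#' when strictly above 0.80.
#'
#' @return list of [subgroup_rule()] objects.
#' @export
default_subgroup_rules <- function() {
  list(subgroup_rule("episodic_memory", "level2", 0.275, "lt",
                     "em2_low"),
       subgroup_rule("perceptual_motor_speed", "high", 0.40, "le",
                     "pms_low"),
       subgroup_rule("cognitive_flexibility", "high", 0.30, "le",
                     "cf_low"),
       subgroup_rule("episodic_memory", "level3", 0.80, "gt",
                     "em3_high"))
}

#' Label a cohort by subgroup rules
#'
#' Applies each rule to its `p_<function>_<level>` probability column and
#' appends one logical indicator column per rule. An `apoe_e4` column, when
#' present, additionally yields an `apoe_positive` indicator (at least one
#' e4 allele).
#'
#' @param cohort data.frame containing the probability columns produced by
#'   [function_probability_table()] (plus covariates / outcomes).
#' @param rules list of [subgroup_rule()] objects.
#' @return `cohort` with indicator columns appended.
#' @export
assign_subgroups <- function(cohort, rules = default_subgroup_rules()) {
  if (inherits(rules, "subgroup_rule")) rules <- list(rules)
  for (r in rules) {
    col <- paste0("p_", r$fn, "_", r$level)
    if (!col %in% names(cohort))
      stop("missing probability column '", col, "' for rule '", r$label,
           "'", call. = FALSE)
    p <- cohort[[col]]
    cohort[[r$label]] <- switch(r$comparison,
                                lt = p < r$cutoff, le = p <= r$cutoff,
                                gt = p > r$cutoff, ge = p >= r$cutoff)
  }
  if ("apoe_e4" %in% names(cohort))
    cohort$apoe_positive <- cohort$apoe_e4 >= 1
  cohort
}

#' Binomial proportion with Wald confidence half-width
#'
#' Normal-approximation (Wald) interval on the percent scale:
#' `p +/- z * sqrt(p (1 - p) / n) * 100`. This is the interval form behind
#' published "percent +/- half-width" summaries of conversion rates.
#'
#' @param k number of successes.
#' @param n number of trials (`n >= 1`).
#' @param level confidence level.
#' @return named numeric vector `c(proportion, half_width)` in percent.
#' @export
proportion_with_ci <- function(k, n, level = 0.95) {
  k <- as.numeric(k); n <- as.numeric(n)
  if (length(n) != 1 || n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(proportion = 100 * p, half_width = 100 * z * sqrt(p * (1 - p) / n))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional exact test of no association: with margins fixed, the
#' two-sided p-value sums the hypergeometric probabilities of every table
#' at most as probable as the one observed.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero", call. = FALSE)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Cross-classify a subgroup against conversion
#'
#' Builds the 2x2 contingency table of a subgroup indicator against the
#' conversion outcome, with per-column conversion proportions, Wald
#' confidence half-widths, the two-sided Fisher exact p-value, and the
#' cross-product odds ratio. An optional stratum filter (e.g. APOE carrier
#' status) restricts the cohort first.
#'
#' @param cohort labelled cohort table from [assign_subgroups()].
#' @param label name of the logical subgroup column.
#' @param outcome name of the logical conversion column.
#' @param stratum optional name of a logical column used as a filter, or a
#'   logical vector over rows.
#' @param level confidence level for the Wald intervals.
#' @return an object of class `contingency_result`: `counts` (2x2, rows =
#'   converted yes/no, columns = in-subgroup / not), `proportions`,
#'   `ci_half_widths`, `fisher_p`, `odds_ratio`, `degenerate`.
#' @export
build_contingency <- function(cohort, label, outcome = "converted",
                              stratum = NULL, level = 0.95) {
  if (!label %in% names(cohort))
    stop("missing subgroup column '", label, "'", call. = FALSE)
  if (!outcome %in% names(cohort))
    stop("missing outcome column '", outcome, "'", call. = FALSE)
  if (!is.null(stratum)) {
    keep <- if (is.character(stratum)) isTRUE_vec(cohort[[stratum]])
            else isTRUE_vec(stratum)
    cohort <- cohort[keep, , drop = FALSE]
  }
  g <- factor(ifelse(cohort[[label]], "in", "out"), levels = c("in", "out"))
  y <- factor(ifelse(cohort[[outcome]], "yes", "no"),
              levels = c("yes", "no"))
  counts <- table(converted = y, subgroup = g)
  n_col <- colSums(counts)
  degenerate <- any(n_col == 0) || any(rowSums(counts) == 0)
  props <- ci <- stats::setNames(rep(NA_real_, 2), colnames(counts))
  for (j in seq_len(2)) {
    if (n_col[j] > 0) {
      pc <- proportion_with_ci(counts["yes", j], n_col[j], level)
      props[j] <- pc[["proportion"]]
      ci[j] <- pc[["half_width"]]
    }
  }
  fp <- if (degenerate) NA_real_ else fisher_exact_two_sided(counts)
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  structure(list(counts = unclass(counts), proportions = props,
                 ci_half_widths = ci, fisher_p = fp,
                 odds_ratio = as.numeric(or), degenerate = degenerate,
                 label = label, n = sum(counts)),
            class = "contingency_result")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.contingency_result <- function(x, ...) {
  cat("Contingency for subgroup '", x$label, "' (n = ", x$n, ")\n",
      sep = "")
  print(x$counts)
  cat("conversion %:", sprintf("%.1f%%+/-%.1f%%", x$proportions,
                               x$ci_half_widths), "\n")
  if (!x$degenerate)
    cat(sprintf("two-sided Fisher p = %.4g, odds ratio = %.3f\n",
                x$fisher_p, x$odds_ratio))
  else cat("degenerate stratum: a margin is empty\n")
  invisible(x)
}

#' Logistic conversion model
#'
#' Maximum-likelihood logistic regression of a binary conversion outcome on
#' arbitrary covariates (typically per-function functioning probabilities
#' and APOE carrier status), with per-coefficient Wald tests, odds-ratio
#' scale estimates, the model log-likelihood and the training-data AUC.
#' Complete separation is flagged rather than silently returned.
#'
#' @param cohort data.frame.
#' @param outcome name of the logical / 0-1 outcome column.
#' @param covariates character vector of covariate column names.
#' @return an object of class `prediction_model_result` with elements
#'   `coefficients`, `se`, `wald_p`, `exp_b`, `log_lik`, `auc`, `fitted`,
#'   `converged`, `separation`, `glm`.
#' @export
fit_logistic <- function(cohort, outcome = "converted", covariates) {
  y <- as.numeric(cohort[[outcome]])
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome must contain both classes", call. = FALSE)
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ")
         else "1"
  form <- stats::as.formula(paste0("y01 ~ ", rhs))
  dat <- cohort[, intersect(covariates, names(cohort)), drop = FALSE]
  dat$y01 <- y
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat))
  sm <- summary(fit)
  co <- sm$coefficients
  separation <- !fit$converged || any(abs(co[, "Estimate"]) > 15) ||
    any(co[, "Std. Error"] > 100)
  if (separation)
    warning("possible complete separation / non-convergence; estimates ",
            "are unreliable", call. = FALSE)
  scores <- stats::fitted(fit)
  b <- stats::setNames(co[, "Estimate"], rownames(co))
  structure(list(coefficients = b,
                 se = stats::setNames(co[, "Std. Error"], rownames(co)),
                 wald_p = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
                 exp_b = exp(b),
                 log_lik = as.numeric(stats::logLik(fit)),
                 auc = if (length(covariates)) roc_auc(scores, y) else NA_real_,
                 fitted = scores,
                 converged = fit$converged,
                 separation = separation,
                 glm = fit),
            class = "prediction_model_result")
}

#' @export
print.prediction_model_result <- function(x, ...) {
  tab <- data.frame(B = x$coefficients, wald_p = x$wald_p,
                    exp_B = x$exp_b)
  print(round(tab, 4))
  cat(sprintf("log-likelihood = %.3f", x$log_lik))
  if (!is.na(x$auc)) cat(sprintf(", training AUC = %.3f", x$auc))
  cat("\n")
  if (x$separation) cat("WARNING: possible separation\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested logistic models
#'
#' Goodness-of-fit statistic `-2 * (logLik(reduced) - logLik(full))`
#' referred to a chi-square distribution with the difference in parameter
#' counts as degrees of freedom.
#'
#' @param reduced,full `prediction_model_result` objects for nested fits.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(reduced, full) {
  stat <- -2 * (reduced$log_lik - full$log_lik)
  df <- length(full$coefficients) - length(reduced$coefficients)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Area under the ROC curve
#'
#' AUC as the probability that a randomly chosen positive outranks a
#' randomly chosen negative, ties counted half — the rank-statistic form,
#' exactly equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcomes (logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both outcome classes must be present",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Conversion-aligned trajectory histograms
#'
#' Bins per-visit functioning probabilities into per-timepoint histograms,
#' the longitudinal display behind "does this function decline before
#' conversion?". Converters' visits are re-indexed to months before their
#' conversion month; non-converters are kept on months from baseline and
#' restricted to subjects event-free through a horizon.
#'
#' @param records long data.frame with columns `subject_id`, `visit_month`,
#'   the probability column named by `prob_col`, and outcome columns
#'   `converted` plus `conversion_month` (NA for non-converters).
#' @param prob_col name of the probability column to profile.
#' @param timepoints months (before conversion, and from baseline) at which
#'   histograms are formed.
#' @param breaks histogram breaks on the probability scale.
#' @param horizon non-converters must be event-free through this month to
#'   be included.
#' @return an object of class `trajectory_profile`: two matrices
#'   (`converters`, `nonconverters`) of per-timepoint bin proportions, the
#'   per-timepoint sample sizes, and the raw per-timepoint value lists.
#' @export
trajectory_profile <- function(records, prob_col,
                               timepoints = c(24, 18, 12, 6, 0),
                               breaks = seq(0, 1, by = 0.1),
                               horizon = 36) {
  stopifnot(prob_col %in% names(records),
            all(c("subject_id", "visit_month", "converted") %in%
                  names(records)))
  conv <- records[isTRUE_vec(records$converted), , drop = FALSE]
  if (nrow(conv) && !"conversion_month" %in% names(records))
    stop("converters present but no conversion_month column",
         call. = FALSE)
  if (nrow(conv)) {
    bad <- is.na(conv$conversion_month)
    if (any(bad)) {
      warning("excluding ", length(unique(conv$subject_id[bad])),
              " converter(s) without a conversion month", call. = FALSE)
      conv <- conv[!bad, , drop = FALSE]
    }
    conv$timepoint <- conv$conversion_month - conv$visit_month
  }
  nonc <- records[!isTRUE_vec(records$converted), , drop = FALSE]
  if (nrow(nonc) && "event_free_through" %in% names(records))
    nonc <- nonc[nonc$event_free_through >= horizon, , drop = FALSE]
  nonc$timepoint <- nonc$visit_month

  hist_at <- function(dat) {
    vals <- lapply(timepoints, function(tp)
      dat[[prob_col]][!is.na(dat$timepoint) & dat$timepoint == tp])
    names(vals) <- paste0("t", timepoints)
    mat <- t(vapply(vals, function(v) {
      if (!length(v)) return(rep(NA_real_, length(breaks) - 1L))
      h <- graphics::hist(pmin(pmax(v, min(breaks)), max(breaks)),
                          breaks = breaks, plot = FALSE)
      h$counts / length(v)
    }, numeric(length(breaks) - 1L)))
    list(hist = mat, n = vapply(vals, length, integer(1)), values = vals)
  }
  cv <- hist_at(conv)
  nc <- hist_at(nonc)
  structure(list(converters = cv$hist, nonconverters = nc$hist,
                 n_converters = cv$n, n_nonconverters = nc$n,
                 values_converters = cv$values,
                 values_nonconverters = nc$values,
                 prob_col = prob_col, timepoints = timepoints,
                 breaks = breaks),
            class = "trajectory_profile")
}

#' @export
print.trajectory_profile <- function(x, ...) {
  cat("Trajectory profile of ", x$prob_col, "\n  converter n: ",
      paste(names(x$n_converters), x$n_converters, sep = "=",
            collapse = " "),
      "\n  non-converter n: ",
      paste(names(x$n_nonconverters), x$n_nonconverters, sep = "=",
            collapse = " "), "\n", sep = "")
  invisible(x)
}
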