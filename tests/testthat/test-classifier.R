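test_that("uninformative measures leave the prior unchanged", {
  flat <- lapply(spec_measure_names(cp_spec), function(j)
    response_pair_grid(j, breaks = c(-5, 5), dens_high = 1, dens_low = 1))
  prior <- uniform_prior(cp_model)
  x <- stats::setNames(rep(0.3, 10), spec_measure_names(cp_spec))
  expect_equal(posterior_update(prior, x, flat, cp_model), prior,
               tolerance = 1e-12)
})

test_that("a single 2:1 likelihood-ratio observation reweights the filter", {
  # only the delayed-recall measure observed, with f_high = 2 f_low at x:
  # the 7 states passing it get 2/36 each, the other 22 get 1/36
  pr <- response_pair_grid("adas_delayed_recall", breaks = c(0, 1, 2),
                           dens_high = c(2, 1), dens_low = c(1, 2),
                           direction = "lower")
  post <- posterior_update(uniform_prior(cp_model),
                           c(adas_delayed_recall = 0.5), list(pr),
                           cp_model)
  passing <- which(cp_model$patterns[, "adas_delayed_recall"] == 1L)
  expect_setequal(passing, 1:7)
  expect_equal(unname(post[passing]), rep(2 / 36, 7), tolerance = 1e-12)
  expect_equal(unname(post[-passing]), rep(1 / 36, 22), tolerance = 1e-12)
})

test_that("posterior sums to one and rejects unknown measures", {
  cfg <- cohort_config(n_subjects = 5, seed = 61)
  coh <- generate_cohort(cfg, cp_model)
  tp <- true_response_pairs(cp_model, cfg)
  x <- unlist(coh$responses[1, spec_measure_names(cp_spec)])
  post <- posterior_update(uniform_prior(cp_model), x, tp, cp_model)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_true(all(post >= 0))
  expect_error(posterior_update(uniform_prior(cp_model), c(ghost = 1), tp,
                                cp_model), "unknown measure")
  expect_error(posterior_update(rep(1, 29), x, tp, cp_model),
               "probability vector")
})

test_that("sequential updates equal one joint update", {
  cfg <- cohort_config(n_subjects = 3, seed = 62)
  coh <- generate_cohort(cfg, cp_model)
  tp <- true_response_pairs(cp_model, cfg)
  ms <- spec_measure_names(cp_spec)
  x <- unlist(coh$responses[2, ms])
  joint <- posterior_update(uniform_prior(cp_model), x, tp, cp_model)
  seq_post <- uniform_prior(cp_model)
  for (j in sample(ms))
    seq_post <- posterior_update(seq_post, x[j], tp, cp_model)
  expect_equal(seq_post, joint, tolerance = 1e-12)
})

test_that("a well-separated battery recovers the generating state", {
  # 200 seeded replicate subjects drawn from state 14's distributions
  cfg <- cohort_config(n_subjects = 200, separation = 5, seed = 63,
                       state_distribution = replace(rep(0, 29), 14, 1))
  coh <- generate_cohort(cfg, cp_model)
  tp <- true_response_pairs(cp_model, cfg)
  rec <- classify_cohort(responses_table(coh), tp, cp_model)
  expect_gte(mean(rec$map_state == 14), 0.95)
})

test_that("replicate batteries drive posterior certainty to one", {
  cfg <- cohort_config(n_subjects = 40, separation = 2.5, seed = 64)
  coh <- generate_cohort(cfg, cp_model)
  tp <- true_response_pairs(cp_model, cfg)
  ms <- spec_measure_names(cp_spec)
  truth <- coh$subjects$true_state
  mass_at <- function(k) {
    # posterior after k i.i.d. replicate batteries per subject
    med <- vapply(seq_len(nrow(coh$subjects)), function(i) {
      post <- uniform_prior(cp_model)
      set.seed(1000 + i)
      for (r in seq_len(k)) {
        x <- unlist(cogposet:::draw_responses(cp_model, cfg,
                                              truth[i])[1, ms])
        post <- posterior_update(post, x, tp, cp_model)
      }
      post[truth[i]]
    }, numeric(1))
    stats::median(med)
  }
  m1 <- mass_at(1); m5 <- mass_at(5); m25 <- mass_at(25)
  expect_lte(m1, m5 + 1e-9)
  expect_lte(m5, m25 + 1e-9)
  expect_gt(m25, 0.99)
})

test_that("classify_cohort is deterministic, order-invariant and warns on empty rows", {
  cfg <- cohort_config(n_subjects = 3, seed = 65)
  coh <- generate_cohort(cfg, cp_model)
  tab <- responses_table(coh)
  tp <- true_response_pairs(cp_model, cfg)
  rec <- classify_cohort(tab, tp, cp_model)
  expect_equal(nrow(rec), 3)
  probs <- as.matrix(rec[paste0("state_", 1:29)])
  expect_equal(unname(rowSums(probs)), rep(1, 3), tolerance = 1e-9)

  shuf <- classify_cohort(tab[c(3, 1, 2), ], tp, cp_model)
  expect_equal(shuf[order(shuf$subject_id), ],
               rec[order(rec$subject_id), ], ignore_attr = TRUE)

  empty <- classify_cohort(tab[0, ], tp, cp_model)
  expect_equal(nrow(empty), 0)

  tab2 <- tab
  tab2[1, spec_measure_names(cp_spec)] <- NA
  expect_warning(rec2 <- classify_cohort(tab2, tp, cp_model),
                 "no observed measures")
  expect_equal(unname(unlist(rec2[1, paste0("state_", 1:29)])),
               uniform_prior(cp_model), tolerance = 1e-12)
})

test_that("function probabilities aggregate up-sets with confound weighting", {
  point <- function(s) replace(rep(0, 29), s, 1)
  expect_equal(function_probability(point(1), cp_model,
                                    "episodic_memory", "level2"), 1)
  # uniform posterior: the level-2 filter holds 14 of 29 states and
  # episodic memory is never confounded
  expect_equal(function_probability(uniform_prior(cp_model), cp_model,
                                    "episodic_memory", "level2"),
               14 / 29, tolerance = 1e-12)
  # a flexibility-confounded state contributes half its mass
  expect_equal(function_probability(point(14), cp_model,
                                    "cognitive_flexibility", "high"), 0.5)
  expect_equal(function_probability(uniform_prior(cp_model), cp_model,
                                    "cognitive_flexibility", "high"),
               (length(upset(cp_model, "cognitive_flexibility", "high")) +
                  4 * 0.5) / 29, tolerance = 1e-12)
})

test_that("function probability is monotone in the level", {
  set.seed(66)
  for (i in 1:20) {
    post <- stats::runif(29); post <- post / sum(post)
    p1 <- function_probability(post, cp_model, "episodic_memory", "level1")
    p2 <- function_probability(post, cp_model, "episodic_memory", "level2")
    p3 <- function_probability(post, cp_model, "episodic_memory", "level3")
    expect_gte(p1, p2)
    expect_gte(p2, p3)
  }
})

test_that("probability columns and CSV export round out the records", {
  cfg <- cohort_config(n_subjects = 4, seed = 67)
  coh <- generate_cohort(cfg, cp_model)
  rec <- classify_cohort(responses_table(coh),
                         true_response_pairs(cp_model, cfg), cp_model)
  rec <- function_probability_table(rec, cp_model)
  expect_true(all(c("p_episodic_memory_level2", "p_word_fluency_high",
                    "p_cognitive_flexibility_high") %in% names(rec)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_posteriors(rec, path)
  back <- utils::read.csv(path)
  expect_equal(back$p_episodic_memory_level2,
               rec$p_episodic_memory_level2, tolerance = 1e-12)
})
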