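#' Configuration for a synthetic cohort
#'
#' Collects every knob of the synthetic-cohort generator. Defaults emulate
#' a mild-cognitive-impairment sample followed for conversion over 24
#' months: 268 subjects, a uniform distribution over latent states,
#' mastery / non-mastery response components 2 standard deviations apart,
#' APOE e4 carrier prevalence of one half, and a logistic conversion law
#' whose coefficients act on the truth indicators for episodic-memory
#' level-2 functioning, perceptual-motor-speed functioning and APOE
#' carriage (negative weights on the two cognitive indicators, positive on
#' APOE). The default intercept is solved analytically so that the
#' marginal conversion rate under these defaults is 37.7%, the overall
#' two-year conversion rate the cohort emulates.
#'
#' @param n_subjects cohort size.
#' @param state_distribution probability vector over states (default
#'   uniform).
#' @param separation location gap between the mastery and non-mastery
#'   response components, in standard-deviation units.
#' @param noise response component standard deviation.
#' @param apoe_prevalence probability of carrying at least one e4 allele;
#'   the allele count is Binomial(2, q) with q solved from the prevalence.
#' @param conversion_coef named coefficients `intercept`, `em2`, `pms`,
#'   `apoe` of the logistic conversion law.
#' @param visits visit months for longitudinal cohorts.
#' @param conversion_month month at which converters convert (on the visit
#'   grid).
#' @param decline_rates named per-visit probabilities that a converter
#'   drops one level of each function.
#' @param horizon month through which non-converters are event-free.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 268L,
                          state_distribution = NULL,
                          separation = 2.0,
                          noise = 1.0,
                          apoe_prevalence = 0.5,
                          conversion_coef = c(intercept = 0.296,
                                              em2 = -1.445,
                                              pms = -0.926,
                                              apoe = 0.623),
                          visits = c(0, 6, 12, 18, 24),
                          conversion_month = 24,
                          decline_rates = c(episodic_memory = 0.25,
                                            word_fluency = 0.05,
                                            selective_attention = 0.02,
                                            cognitive_flexibility = 0.15,
                                            perceptual_motor_speed = 0.15),
                          horizon = 36,
                          seed = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (!is.null(state_distribution)) {
    if (any(state_distribution < 0) ||
        abs(sum(state_distribution) - 1) > 1e-8)
      stop("state_distribution must be a probability vector",
           call. = FALSE)
  }
  if (apoe_prevalence < 0 || apoe_prevalence > 1)
    stop("apoe_prevalence must lie in [0, 1]", call. = FALSE)
  if (any(decline_rates < 0) || any(decline_rates > 1))
    stop("decline_rates must lie in [0, 1]", call. = FALSE)
  if (!length(visits)) stop("visits must be non-empty", call. = FALSE)
  if (!conversion_month %in% visits)
    stop("conversion_month must lie on the visit grid", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 state_distribution = state_distribution,
                 separation = separation, noise = noise,
                 apoe_prevalence = apoe_prevalence,
                 conversion_coef = conversion_coef,
                 visits = sort(visits),
                 conversion_month = conversion_month,
                 decline_rates = decline_rates,
                 horizon = horizon, seed = seed),
            class = "cohort_config")
}

#' Generating response pairs of a synthetic cohort
#'
#' The exact mastery / non-mastery response distributions a configuration
#' generates from: per measure, normal components `separation` apart (on
#' the performance scale) with standard deviation `noise`, the sign of the
#' raw scale following the measure's direction. Classifying a synthetic
#' cohort against these pairs gives the best-case (oracle-distribution)
#' classifier.
#'
#' @param model a [build_model()] result.
#' @param config a [cohort_config()].
#' @return a `response_model_set` of normal pairs.
#' @export
true_response_pairs <- function(model, config) {
  ms <- spec_measure_names(model$spec)
  pairs <- lapply(ms, function(j) {
    dir <- model$spec$measures[[j]]$direction
    sgn <- if (dir == "higher") 1 else -1
    response_pair_normal(j, mean_high = sgn * config$separation,
                         mean_low = 0, sd_high = config$noise,
                         direction = dir)
  })
  new_response_model_set(stats::setNames(pairs, ms),
                         meta = list(method = "generating"))
}

# truth indicator (possibly fractional for confounded states) that a state
# functions at >= level of fn
state_indicator <- function(model, sid, fn, level) {
  q <- level_index(model$spec, fn, level)
  mean(model$states[[sid]]$masked_members[, fn] >= q)
}

state_indicators <- function(model, fn, level)
  vapply(seq_len(model$n_states), state_indicator, numeric(1),
         model = model, fn = fn, level = level)

draw_responses <- function(model, config, states) {
  ms <- spec_measure_names(model$spec)
  n <- length(states)
  out <- matrix(NA_real_, n, length(ms), dimnames = list(NULL, ms))
  for (j in ms) {
    mastery <- model$patterns[states, j]
    perf <- stats::rnorm(n, mean = config$separation * mastery,
                         sd = config$noise)
    sgn <- if (model$spec$measures[[j]]$direction == "higher") 1 else -1
    out[, j] <- sgn * perf
  }
  as.data.frame(out)
}

conversion_probability <- function(model, config, states, apoe_e4) {
  cc <- config$conversion_coef
  em2 <- state_indicators(model, "episodic_memory", "level2")[states]
  pms <- state_indicators(model, "perceptual_motor_speed", "high")[states]
  stats::plogis(cc[["intercept"]] + cc[["em2"]] * em2 +
                  cc[["pms"]] * pms + cc[["apoe"]] * (apoe_e4 >= 1))
}

new_synthetic_cohort <- function(config, subjects, responses, truth) {
  structure(list(config = config, subjects = subjects,
                 responses = responses, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$subjects), " subjects, ",
      length(unique(x$responses$visit_month)), " visit(s), ",
      sum(x$subjects$converted), " converter(s)\n", sep = "")
  invisible(x)
}

#' Generate a cross-sectional synthetic cohort
#'
#' Draws latent true states from the configured state distribution, draws
#' each response from the normal component matching the true state's ideal
#' pattern entry for that measure, assigns APOE e4 allele counts, and draws
#' 24-month conversion outcomes from the configured logistic law. The
#' result is deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param model a [build_model()] result.
#' @return an object of class `synthetic_cohort` with elements `subjects`
#'   (id, true state, APOE count, conversion flag and month), `responses`
#'   (one row per subject, baseline visit), and `truth` (per-visit true
#'   states).
#' @export
generate_cohort <- function(config, model) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  p <- config$state_distribution
  if (is.null(p)) p <- rep(1 / model$n_states, model$n_states)
  if (length(p) != model$n_states)
    stop("state_distribution must have one entry per state", call. = FALSE)
  states <- sample.int(model$n_states, n, replace = TRUE, prob = p)
  q <- 1 - sqrt(1 - config$apoe_prevalence)
  apoe <- stats::rbinom(n, 2L, q)
  pconv <- conversion_probability(model, config, states, apoe)
  conv <- stats::runif(n) < pconv
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    true_state = states,
    apoe_e4 = apoe,
    converted = conv,
    conversion_month = ifelse(conv, config$conversion_month, NA_real_),
    event_free_through = ifelse(conv, NA_real_, config$horizon))
  responses <- cbind(data.frame(subject_id = subjects$subject_id,
                                visit_month = 0),
                     draw_responses(model, config, states))
  truth <- data.frame(subject_id = subjects$subject_id, visit_month = 0,
                      true_state = states)
  new_synthetic_cohort(config, subjects, responses, truth)
}

# one decline step applied to an integer profile: each function above its
# minimum drops one level with its configured probability
decline_step <- function(profile, rates) {
  for (fn in names(profile)) {
    r <- if (fn %in% names(rates)) rates[[fn]] else 0
    if (profile[[fn]] > 0L && stats::runif(1) < r)
      profile[[fn]] <- profile[[fn]] - 1L
  }
  profile
}

state_of_profile <- function(model, profile) {
  R <- requirement_matrix(model$spec)
  pat <- as.integer(colSums(t(R) > profile) == 0L)
  key <- paste(pat, collapse = "")
  keys <- apply(model$patterns, 1, paste, collapse = "")
  match(key, keys)
}

#' Generate a longitudinal synthetic cohort
#'
#' Extends [generate_cohort()] over the configured visit grid: converters'
#' latent profiles decay by single-level drops (each function dropping
#' with its per-visit decline rate), so their states move weakly downward
#' in the partial order, while non-converters' states are static.
#' Responses are regenerated at every visit from the then-current state.
#'
#' @inheritParams generate_cohort
#' @return a `synthetic_cohort` whose `responses` and `truth` tables have
#'   one row per subject-visit.
#' @export
generate_longitudinal <- function(config, model) {
  base <- generate_cohort(config, model)
  subjects <- base$subjects
  n <- nrow(subjects)
  fns <- spec_function_names(model$spec)
  # start from a concrete member profile of the true state (sampled
  # uniformly when the state is an equivalence class of several)
  profiles <- lapply(subjects$true_state, function(s) {
    mm <- model$states[[s]]$masked_members
    stats::setNames(mm[sample.int(nrow(mm), 1L), ], fns)
  })
  visits <- config$visits
  resp_rows <- truth_rows <- vector("list", length(visits))
  states_now <- subjects$true_state
  for (v in seq_along(visits)) {
    if (v > 1L) {
      for (i in seq_len(n)) {
        if (subjects$converted[i]) {
          profiles[[i]] <- decline_step(profiles[[i]],
                                        config$decline_rates)
          states_now[i] <- state_of_profile(model, profiles[[i]])
        }
      }
    }
    resp_rows[[v]] <- cbind(data.frame(subject_id = subjects$subject_id,
                                       visit_month = visits[v]),
                            draw_responses(model, config, states_now))
    truth_rows[[v]] <- data.frame(subject_id = subjects$subject_id,
                                  visit_month = visits[v],
                                  true_state = states_now)
  }
  responses <- do.call(rbind, resp_rows)
  truth <- do.call(rbind, truth_rows)
  ord <- order(responses$subject_id, responses$visit_month)
  responses <- responses[ord, ]; truth <- truth[ord, ]
  rownames(responses) <- rownames(truth) <- NULL
  new_synthetic_cohort(config, subjects, responses, truth)
}

#' Response table of a synthetic cohort
#'
#' Joins responses with covariates and outcomes into the delimited-text
#' layout consumed by [classify_cohort()] and [fit_response_models()]: one
#' row per subject-visit with columns `subject_id`, `visit_month`, one
#' column per measure, `apoe_e4`, `converted`, `conversion_month`,
#' `event_free_through`.
#'
#' @param cohort a `synthetic_cohort`.
#' @return data.frame.
#' @export
responses_table <- function(cohort) {
  merge(cohort$responses,
        cohort$subjects[c("subject_id", "apoe_e4", "converted",
                          "conversion_month", "event_free_through")],
        by = "subject_id", sort = FALSE)
}

#' Per-row mastery labels of a synthetic cohort
#'
#' The true mastery indicator per subject-visit and measure (the ideal
#' pattern of the then-current true state), for supervised response-model
#' fitting and for scoring classification accuracy.
#'
#' @param cohort a `synthetic_cohort`.
#' @param model the [build_model()] result the cohort was generated from.
#' @return logical data.frame, rows matching `cohort$responses`.
#' @export
mastery_labels <- function(cohort, model) {
  st <- cohort$truth$true_state
  out <- as.data.frame(model$patterns[st, , drop = FALSE] == 1L)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to CSV
#'
#' Writes the response table and the ground-truth state table side by
#' side.
#'
#' @param cohort a `synthetic_cohort`.
#' @param responses_path,truth_path output files.
#' @export
write_cohort <- function(cohort, responses_path, truth_path = NULL) {
  utils::write.csv(responses_table(cohort), responses_path,
                   row.names = FALSE)
  if (!is.null(truth_path))
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(responses_path)
}

#' Read a subject response table from CSV
#'
#' @param path CSV file in the layout of [responses_table()].
#' @return data.frame.
#' @export
read_responses <- function(path) {
  if (!file.exists(path))
    stop("response file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
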