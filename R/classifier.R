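# state-posterior matrix for a whole response table, in log space
posterior_matrix <- function(responses, set, model, prior) {
  ms <- intersect(spec_measure_names(model$spec), names(responses))
  n <- nrow(responses)
  ll <- matrix(0, n, model$n_states)
  for (j in ms) {
    x <- responses[[j]]
    obs <- !is.na(x)
    if (!any(obs)) next
    lh <- log(pair_density(set$pairs[[j]], x[obs], TRUE))
    lf <- log(pair_density(set$pairs[[j]], x[obs], FALSE))
    pat <- model$patterns[, j]
    ll[obs, ] <- ll[obs, ] + outer(lh, pat) + outer(lf, 1 - pat)
  }
  lp <- sweep(ll, 2, log(prior), `+`)
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

#' Bayesian posterior update over poset states
#'
#' Applies Bayes' rule to a prior over states given a subject's observed
#' responses: the posterior of state `s` is proportional to
#' `prior(s) * prod_j f_j(x_j | pattern(s)_j)` over the observed measures
#' `j`, where the likelihood component is the measure's mastery density
#' when the state's ideal pattern passes the measure and its non-mastery
#' density otherwise. Missing measures are skipped (likelihood 1), never
#' imputed, so updating on measures one at a time is identical to a single
#' joint update.
#'
#' @param prior numeric probability vector over states (sums to 1).
#' @param responses named numeric vector mapping measure names to observed
#'   values; `NA` entries are skipped.
#' @param models a `response_model_set` from [fit_response_models()] or
#'   built from [response_pair_normal()] / [response_pair_grid()] pairs.
#' @param model a [build_model()] result.
#' @return numeric posterior vector over states (sums to 1).
#' @export
posterior_update <- function(prior, responses, models, model) {
  if (abs(sum(prior) - 1) > 1e-6 || any(prior < 0))
    stop("prior must be a probability vector over states", call. = FALSE)
  if (length(prior) != model$n_states)
    stop("prior length must equal the number of states", call. = FALSE)
  if (inherits(models, "response_pair")) models <- list(models)
  if (!inherits(models, "response_model_set")) {
    names(models) <- vapply(models, `[[`, "", "measure")
    models <- new_response_model_set(models, meta = list(method = "given"))
  }
  responses <- responses[!is.na(responses)]
  unknown <- setdiff(names(responses), spec_measure_names(model$spec))
  if (length(unknown))
    stop("unknown measure(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lp <- log(prior)
  for (j in names(responses)) {
    pat <- model$patterns[, j]
    lh <- log(pair_density(models$pairs[[j]], responses[[j]], TRUE))
    lf <- log(pair_density(models$pairs[[j]], responses[[j]], FALSE))
    lp <- lp + ifelse(pat == 1L, lh, lf)
  }
  if (!any(is.finite(lp)))
    stop("posterior update produced all-zero mass", call. = FALSE)
  p <- exp(lp - max(lp))
  unname(p / sum(p))
}

#' Classify a cohort of subjects
#'
#' Vectorised wrapper around [posterior_update()]: one posterior record per
#' row of the response table (per subject, or per subject-visit when a
#' visit column is present). Classification is independent per row and
#' starts from the same prior (uniform by default), and is deterministic
#' given its inputs.
#'
#' @param responses data.frame with a subject id column, an optional visit
#'   month column, and one numeric column per measure; extra columns are
#'   carried along unused.
#' @param models a `response_model_set`.
#' @param model a [build_model()] result.
#' @param prior prior over states (default uniform, e.g. 1/29 per state for
#'   the bundled battery).
#' @param id_col,visit_col column names for subject id and visit month.
#' @return a data.frame of class `posterior_records`: id and visit columns,
#'   one `state_<i>` probability column per state, `map_state` (maximal
#'   posterior, ties broken by lowest state id) and `map_tie`.
#' @export
classify_cohort <- function(responses, models, model, prior = NULL,
                            id_col = "subject_id",
                            visit_col = "visit_month") {
  if (is.null(prior)) prior <- rep(1 / model$n_states, model$n_states)
  ms <- intersect(spec_measure_names(model$spec), names(responses))
  n <- nrow(responses)
  ids <- if (id_col %in% names(responses)) responses[[id_col]] else seq_len(n)
  visits <- if (visit_col %in% names(responses)) responses[[visit_col]]
            else rep(NA_real_, n)
  if (n == 0L) {
    out <- data.frame(subject_id = character(), visit_month = numeric())
    for (s in seq_len(model$n_states)) out[[paste0("state_", s)]] <- numeric()
    out$map_state <- integer(); out$map_tie <- logical()
    class(out) <- c("posterior_records", "data.frame")
    return(out)
  }
  none <- if (length(ms))
    rowSums(!is.na(as.data.frame(responses[ms]))) == 0L
  else rep(TRUE, n)
  if (any(none))
    warning(sum(none), " row(s) with no observed measures; their ",
            "posterior equals the prior", call. = FALSE)
  post <- posterior_matrix(responses, models, model, prior)
  map <- apply(post, 1, which.max)
  tie <- vapply(seq_len(n), function(i)
    sum(abs(post[i, ] - post[i, map[i]]) < 1e-12) > 1L, logical(1))
  out <- data.frame(subject_id = ids, visit_month = visits)
  colnames(post) <- paste0("state_", seq_len(model$n_states))
  out <- cbind(out, as.data.frame(post))
  out$map_state <- as.integer(map)
  out$map_tie <- tie
  class(out) <- c("posterior_records", "data.frame")
  out
}

confound_weight <- function(model, sid, fn, q,
                            weighting = c("equal", "member_count")) {
  weighting <- match.arg(weighting)
  st <- model$states[[sid]]
  members <- if (weighting == "equal") st$masked_members
             else mask_profiles(st$members, model$gates)
  mean(members[, fn] >= q)
}

#' Per-function functioning probability
#'
#' Aggregates a state posterior into the probability that a subject
#' functions at or above a given level of one cognitive function: the
#' posterior mass of the function-level up-set, plus, for each state
#' confounded on that function, its posterior weighted by the fraction of
#' its member profiles that meet the level (equal profile weights by
#' default).
#'
#' @param posterior numeric probability vector over states.
#' @param model a [build_model()] result.
#' @param fn function name.
#' @param level level label.
#' @param weighting `"equal"` (over the distinct member profiles of a
#'   confounded state, the default) or `"member_count"` (over raw member
#'   profiles, counting multiplicity).
#' @return probability in `[0, 1]`.
#' @export
function_probability <- function(posterior, model, fn, level,
                                 weighting = c("equal", "member_count")) {
  weighting <- match.arg(weighting)
  q <- level_index(model$spec, fn, level)
  up <- upset(model, fn, level)
  p <- sum(posterior[up])
  conf <- which(vapply(model$states, function(s)
    fn %in% s$confounded_functions, logical(1)))
  for (sid in conf)
    p <- p + posterior[sid] * confound_weight(model, sid, fn, q, weighting)
  p
}

#' Add per-function probability columns to posterior records
#'
#' Computes [function_probability()] for every requested (function, level)
#' target on each record and appends the results as columns named
#' `p_<function>_<level>`.
#'
#' @param records a `posterior_records` data.frame from
#'   [classify_cohort()].
#' @param model a [build_model()] result.
#' @param targets data.frame with columns `fn` and `level`; defaults to
#'   every above-minimum level of every function.
#' @inheritParams function_probability
#' @return `records` with the probability columns appended.
#' @export
function_probability_table <- function(records, model, targets = NULL,
                                       weighting = c("equal",
                                                     "member_count")) {
  weighting <- match.arg(weighting)
  if (is.null(targets)) targets <- default_function_targets(model$spec)
  post <- as.matrix(records[paste0("state_", seq_len(model$n_states))])
  for (k in seq_len(nrow(targets))) {
    fn <- targets$fn[k]; lv <- targets$level[k]
    col <- paste0("p_", fn, "_", lv)
    records[[col]] <- apply(post, 1, function_probability, model = model,
                            fn = fn, level = lv, weighting = weighting)
  }
  records
}

default_function_targets <- function(spec) {
  rows <- lapply(spec$functions, function(f)
    data.frame(fn = f$name, level = f$levels[-1L],
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write posterior records to CSV
#'
#' @param records a `posterior_records` data.frame.
#' @param path output file.
#' @export
write_posteriors <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
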