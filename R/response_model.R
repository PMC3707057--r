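#' Construct a normal mastery / non-mastery response pair
#'
#' Convenience constructor for a pair of normal response densities — one for
#' subjects mastering every requirement of the measure, one for the rest.
#' Used chiefly to express the generating distributions of synthetic
#' cohorts and as the small-sample parametric variant of
#' [fit_response_models()].
#'
#' @param measure measure name.
#' @param mean_high,mean_low component means on the raw response scale.
#' @param sd_high,sd_low component standard deviations.
#' @param direction `"higher"` or `"lower"` (which raw direction is better).
#' @param floor_rel density floor relative to the component maximum.
#' @return an object of class `response_pair`.
#' @export
response_pair_normal <- function(measure, mean_high, mean_low, sd_high = 1,
                                 sd_low = sd_high,
                                 direction = c("higher", "lower"),
                                 floor_rel = 1e-9) {
  structure(list(measure = measure, type = "normal",
                 direction = match.arg(direction),
                 mean_high = mean_high, mean_low = mean_low,
                 sd_high = sd_high, sd_low = sd_low,
                 support = c(-Inf, Inf), floor_rel = floor_rel),
            class = "response_pair")
}

#' Construct a binned mastery / non-mastery response pair
#'
#' The two components are piecewise-constant densities on a shared grid.
#' Supplied bin values are normalised so each component integrates to 1
#' over the support.
#'
#' @param measure measure name.
#' @param breaks increasing numeric vector of bin boundaries (length B+1).
#' @param dens_high,dens_low non-negative bin values (length B).
#' @inheritParams response_pair_normal
#' @return an object of class `response_pair`.
#' @export
response_pair_grid <- function(measure, breaks, dens_high, dens_low,
                               direction = c("higher", "lower"),
                               floor_rel = 1e-9) {
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0),
            length(dens_high) == length(breaks) - 1L,
            length(dens_low) == length(breaks) - 1L,
            all(dens_high >= 0), all(dens_low >= 0))
  w <- diff(breaks)
  norm <- function(d) if (sum(d * w) > 0) d / sum(d * w) else rep(1 / sum(w),
                                                                  length(d))
  structure(list(measure = measure, type = "grid",
                 direction = match.arg(direction),
                 breaks = breaks,
                 dens_high = norm(dens_high), dens_low = norm(dens_low),
                 support = range(breaks), floor_rel = floor_rel),
            class = "response_pair")
}

#' @export
print.response_pair <- function(x, ...) {
  cat("Response pair for '", x$measure, "' (", x$type, ", ",
      x$direction, "-is-better)\n", sep = "")
  invisible(x)
}

# raw component maximum, used for the relative density floor
pair_max_density <- function(pair, mastery) {
  if (pair$type == "normal") {
    sd <- if (mastery) pair$sd_high else pair$sd_low
    stats::dnorm(0, sd = sd)
  } else {
    max(if (mastery) pair$dens_high else pair$dens_low)
  }
}

# vectorised density evaluation with clamping to the support and the
# relative floor applied; no user-facing logging (see likelihood())
pair_density <- function(pair, x, mastery) {
  if (pair$type == "normal") {
    d <- stats::dnorm(x, mean = if (mastery) pair$mean_high else pair$mean_low,
                      sd = if (mastery) pair$sd_high else pair$sd_low)
  } else {
    xc <- pmin(pmax(x, pair$support[1]), pair$support[2])
    bin <- findInterval(xc, pair$breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    d <- (if (mastery) pair$dens_high else pair$dens_low)[bin]
  }
  fl <- pair$floor_rel * pair_max_density(pair, mastery)
  pmax(d, fl)
}

#' Likelihood of a response under one component
#'
#' Evaluates the mastery (`f_high`) or non-mastery (`f_low`) density of a
#' response pair at an observed value. Values outside the support are
#' clamped to its nearest edge (a message notes the clamp) and the relative
#' density floor guarantees a strictly positive return, so a single
#' outlying response can never zero a posterior.
#'
#' @param pair a `response_pair`.
#' @param value numeric response value.
#' @param mastery logical: evaluate the mastery component?
#' @return positive density value.
#' @export
likelihood <- function(pair, value, mastery) {
  if (any(value < pair$support[1] | value > pair$support[2]))
    message("response value outside support of '", pair$measure,
            "' clamped to ", "[", pair$support[1], ", ", pair$support[2],
            "]")
  pair_density(pair, value, mastery)
}

pair_cdf <- function(pair, x, mastery) {
  if (pair$type == "normal") {
    stats::pnorm(x, mean = if (mastery) pair$mean_high else pair$mean_low,
                 sd = if (mastery) pair$sd_high else pair$sd_low)
  } else {
    d <- if (mastery) pair$dens_high else pair$dens_low
    w <- diff(pair$breaks)
    cum <- c(0, cumsum(d * w))
    xc <- pmin(pmax(x, pair$support[1]), pair$support[2])
    bin <- findInterval(xc, pair$breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    cum[bin] + d[bin] * (xc - pair$breaks[bin])
  }
}

new_response_model_set <- function(pairs, meta) {
  structure(list(pairs = pairs, meta = meta), class = "response_model_set")
}

#' @export
print.response_model_set <- function(x, ...) {
  cat("Response model set: ", length(x$pairs), " measures, method '",
      x$meta$method, "'", sep = "")
  if (!is.null(x$meta$iterations) && x$meta$iterations > 0)
    cat(", ", x$meta$iterations, " EM iterations", sep = "")
  cat("\n")
  invisible(x)
}

# Kish effective sample size of a weight vector
kish_ess <- function(w) if (sum(w) > 0) sum(w)^2 / sum(w^2) else 0

# weighted two-component estimate for one measure; w = mastery weight per row
fit_pair <- function(x, w, measure, direction, method, bins, smoothing,
                     floor_rel) {
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  ess <- c(high = kish_ess(w), low = kish_ess(1 - w))
  attach_ess <- function(p) { p$ess <- ess; p }
  if (length(unique(x)) < 2L) {
    warning("measure '", measure, "' is degenerate (all responses ",
            "identical); its components are set equal", call. = FALSE)
    v <- if (length(x)) x[1L] else 0
    return(attach_ess(response_pair_grid(measure,
                                         breaks = c(v - 0.5, v + 0.5),
                                         dens_high = 1, dens_low = 1,
                                         direction = direction,
                                         floor_rel = floor_rel)))
  }
  if (method == "normal") {
    wm <- function(wt) {
      s <- sum(wt)
      if (s <= 0) wt <- rep(1, length(x))
      m <- sum(wt * x) / sum(wt)
      v <- sum(wt * (x - m)^2) / sum(wt)
      c(m, sqrt(max(v, 1e-12)))
    }
    hi <- wm(w); lo <- wm(1 - w)
    return(attach_ess(response_pair_normal(measure, hi[1], lo[1],
                                           max(hi[2], 1e-6),
                                           max(lo[2], 1e-6),
                                           direction = direction,
                                           floor_rel = floor_rel)))
  }
  if (method == "kde") {
    rg <- range(x); pad <- 3 * stats::bw.nrd0(x)
    comp <- function(wt) {
      s <- sum(wt)
      if (s <= 0) wt <- rep(1, length(x))
      stats::density(x, weights = wt / sum(wt), from = rg[1] - pad,
                     to = rg[2] + pad, n = 256)$y
    }
    d <- stats::density(x, from = rg[1] - pad, to = rg[2] + pad, n = 256)
    step <- diff(d$x[1:2])
    breaks <- c(d$x - step / 2, d$x[256] + step / 2)
    return(attach_ess(response_pair_grid(measure, breaks, comp(w),
                                         comp(1 - w), direction = direction,
                                         floor_rel = floor_rel)))
  }
  # histogram estimator: shared Freedman-Diaconis grid, additive smoothing
  nb <- if (is.null(bins)) max(5L, min(60L, grDevices::nclass.FD(x))) else bins
  rg <- range(x)
  pad <- max(diff(rg) * 1e-3, 1e-9)
  breaks <- seq(rg[1] - pad, rg[2] + pad, length.out = nb + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- function(wt) {
    c0 <- vapply(seq_len(nb), function(b) sum(wt[bin == b]), numeric(1))
    c0 + smoothing
  }
  attach_ess(response_pair_grid(measure, breaks, cnt(w), cnt(1 - w),
                                direction = direction,
                                floor_rel = floor_rel))
}

# observed-data log-likelihood of a response table under a model set, with
# latent state marginalised against the prior
observed_loglik <- function(responses, set, model, prior) {
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
  sum(m + log(rowSums(exp(lp - m))))
}

#' Fit mastery / non-mastery response distributions
#'
#' Estimates, for every measure of the model, the pair of response
#' distributions used to weigh likelihoods in Bayesian classification: one
#' component for subjects mastering all of the measure's requirements and
#' one for the rest. With `labels` supplied (a logical subject-by-measure
#' mastery matrix) the fit is supervised; without labels an EM algorithm
#' treats the latent state as missing data — the E-step computes each
#' subject's posterior over states under the current fit (uniform prior by
#' default) and the M-step re-estimates each component with
#' responsibility weights equal to the posterior mass on states whose ideal
#' pattern passes the measure. The observed-data log-likelihood trace is
#' recorded in the returned set's `meta`.
#'
#' @param responses data.frame with one numeric column per measure (extra
#'   columns are ignored); missing values allowed.
#' @param model a [build_model()] result.
#' @param method `"histogram"` (Freedman-Diaconis grid with additive
#'   smoothing, the default), `"kde"` (Gaussian kernel) or `"normal"`.
#' @param labels optional logical matrix / data.frame (rows matching
#'   `responses`, columns named by measure) of per-subject mastery; its
#'   presence selects the supervised fit.
#' @param aux_responses optional auxiliary response table (e.g. a
#'   supplementary clinical sample) merged into estimation only. When
#'   `labels` is given, `aux_labels` must accompany it.
#' @param aux_labels mastery labels for `aux_responses`.
#' @param prior prior over states for the EM fit (default uniform).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param bins optional fixed bin count for the histogram estimator.
#' @param smoothing additive pseudo-count per bin (kept small so that
#'   sparsely populated components are not shrunk toward the pooled grid
#'   centre).
#' @param floor_rel relative density floor for every fitted component.
#' @return an object of class `response_model_set`.
#' @export
fit_response_models <- function(responses, model,
                                method = c("histogram", "kde", "normal"),
                                labels = NULL, aux_responses = NULL,
                                aux_labels = NULL, prior = NULL,
                                max_iter = 50L, tol = 1e-6, bins = NULL,
                                smoothing = 0.1, floor_rel = 1e-9) {
  method <- match.arg(method)
  ms <- spec_measure_names(model$spec)
  miss <- setdiff(ms, names(responses))
  if (length(miss))
    stop("measure(s) absent from response table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  est <- responses[ms]
  if (!is.null(aux_responses)) {
    amiss <- setdiff(ms, names(aux_responses))
    if (length(amiss))
      stop("measure(s) absent from auxiliary table: ",
           paste(amiss, collapse = ", "), call. = FALSE)
    est <- rbind(est, aux_responses[ms])
  }
  dirs <- vapply(model$spec$measures, `[[`, "", "direction")
  if (is.null(prior)) prior <- rep(1 / model$n_states, model$n_states)

  fit_all <- function(W) {
    pairs <- lapply(ms, function(j)
      fit_pair(est[[j]], W[, j], j, dirs[[j]], method, bins, smoothing,
               floor_rel))
    new_response_model_set(stats::setNames(pairs, ms),
                           meta = list(method = method, bins = bins,
                                       smoothing = smoothing,
                                       iterations = 0L,
                                       loglik_trace = numeric()))
  }

  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (!is.null(aux_responses)) {
      if (is.null(aux_labels))
        stop("aux_labels required for a supervised fit with aux_responses",
             call. = FALSE)
      labels <- rbind(labels[ms], as.data.frame(aux_labels)[ms])
    }
    if (nrow(labels) != nrow(est))
      stop("labels must have one row per estimation row", call. = FALSE)
    W <- vapply(ms, function(j) as.numeric(labels[[j]]),
                numeric(nrow(est)))
    set <- fit_all(W)
    set$meta$mode <- "supervised"
    return(set)
  }

  # EM with latent states: initial weights from a direction-oriented
  # median split, then alternate classification and re-estimation
  W <- vapply(ms, function(j) {
    x <- est[[j]]
    sc <- if (dirs[[j]] == "higher") x else -x
    w <- ifelse(sc > stats::median(sc, na.rm = TRUE), 0.75, 0.25)
    ifelse(is.na(w), 0.5, w)
  }, numeric(nrow(est)))
  set <- fit_all(W)
  trace <- observed_loglik(est, set, model, prior)
  for (it in seq_len(max_iter)) {
    post <- posterior_matrix(est, set, model, prior)
    W <- post %*% model$patterns
    set <- fit_all(W)
    trace <- c(trace, observed_loglik(est, set, model, prior))
    if (abs(trace[it + 1L] - trace[it]) < tol) break
  }
  set$meta$mode <- "em"
  set$meta$iterations <- length(trace) - 1L
  set$meta$loglik_trace <- trace
  set
}

#' Check stochastic dominance of fitted pairs
#'
#' For each measure, checks that the mastery component stochastically
#' dominates the non-mastery component in the better-score direction: for
#' higher-is-better measures `F_high(x) <= F_low(x)` everywhere on a grid
#' over the support (and the reverse for lower-is-better). A fitted set in
#' which every measure passes mirrors the substantive validation that
#' subjects expected to score well do tend to do so.
#'
#' For pairs fitted from data the comparison allows a
#' Dvoretzky-Kiefer-Wolfowitz 95% band at the component's effective
#' (Kish) sample size — with a handful of non-mastery subjects a few
#' percent of empirical-CDF wiggle is sampling noise, not an order
#' violation. Analytic pairs (no recorded sample size) are checked
#' strictly. The raw maximal violation is always reported.
#'
#' @param set a `response_model_set` (or list of `response_pair`s).
#' @param n_grid grid resolution for the CDF comparison.
#' @param tol tolerated CDF violation for analytic pairs.
#' @param band `"dkw"` (default) or `"none"` to disable the finite-sample
#'   band for fitted pairs.
#' @return data.frame with columns `measure`, `direction`, `holds`,
#'   `max_violation`, `tolerance`.
#' @export
dominance_check <- function(set, n_grid = 201L, tol = 1e-8,
                            band = c("dkw", "none")) {
  band <- match.arg(band)
  pairs <- if (inherits(set, "response_model_set")) set$pairs else set
  rows <- lapply(pairs, function(p) {
    sup <- p$support
    if (!all(is.finite(sup))) {
      ctr <- c(p$mean_high, p$mean_low)
      sd <- max(p$sd_high, p$sd_low)
      sup <- c(min(ctr) - 6 * sd, max(ctr) + 6 * sd)
    }
    g <- seq(sup[1], sup[2], length.out = n_grid)
    diffs <- pair_cdf(p, g, TRUE) - pair_cdf(p, g, FALSE)
    viol <- if (p$direction == "higher") max(diffs) else max(-diffs)
    tol_p <- tol
    if (band == "dkw" && !is.null(p$ess) && min(p$ess) > 0)
      tol_p <- max(tol, sqrt(log(2 / 0.05) / (2 * min(p$ess))))
    data.frame(measure = p$measure, direction = p$direction,
               holds = viol <= tol_p, max_violation = max(viol, 0),
               tolerance = tol_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a response model set to JSON
#'
#' @param set a `response_model_set`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @export
write_response_models <- function(set, path = NULL) {
  pairs <- lapply(set$pairs, function(p) {
    out <- list(measure = p$measure, type = p$type, direction = p$direction,
                floor_rel = p$floor_rel)
    if (p$type == "normal")
      out <- c(out, p[c("mean_high", "mean_low", "sd_high", "sd_low")])
    else
      out <- c(out, list(breaks = p$breaks, dens_high = p$dens_high,
                         dens_low = p$dens_low))
    if (!is.null(p$ess)) out$ess <- as.list(p$ess)
    out
  })
  js <- jsonlite::toJSON(list(meta = set$meta[c("method", "mode",
                                                "iterations")],
                              pairs = unname(pairs)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read a response model set from JSON
#'
#' @param source path to a JSON file written by [write_response_models()],
#'   or the JSON string itself.
#' @return a `response_model_set`.
#' @export
read_response_models <- function(source) {
  txt <- source
  if (length(source) == 1 && !grepl("[{\n]", source)) {
    if (!file.exists(source))
      stop("response model file not found: ", source, call. = FALSE)
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  pairs <- lapply(doc$pairs, function(p) {
    out <- if (p$type == "normal")
      response_pair_normal(p$measure, p$mean_high, p$mean_low, p$sd_high,
                           p$sd_low, direction = p$direction,
                           floor_rel = p$floor_rel)
    else
      response_pair_grid(p$measure, unlist(p$breaks), unlist(p$dens_high),
                         unlist(p$dens_low), direction = p$direction,
                         floor_rel = p$floor_rel)
    if (!is.null(p$ess)) out$ess <- unlist(p$ess)
    out
  })
  names(pairs) <- vapply(pairs, `[[`, "", "measure")
  meta <- doc$meta
  meta$loglik_trace <- numeric()
  new_response_model_set(pairs, meta)
}
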