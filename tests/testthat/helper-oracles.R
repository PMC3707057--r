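# Shared fixtures and independent brute-force oracles.

cp_spec <- adni_table1_spec()
cp_model <- build_model(cp_spec)

# minimal specs used across files
spec_one_binary <- incidence_spec(
  list(cognitive_function("attention", "binary")),
  list(np_measure("m1", c(attention = "high"))),
  name = "one_binary")

spec_two_binary <- incidence_spec(
  list(cognitive_function("a", "binary"), cognitive_function("b", "binary")),
  list(np_measure("m_a", c(a = "high")), np_measure("m_b", c(b = "high"))),
  name = "two_binary")

# Independent state oracle: enumerate profiles straight from the spec,
# evaluate each measure's requirements by direct scan, and hash the
# pass/fail patterns. Shares no code with build_model().
oracle_states <- function(spec) {
  grids <- lapply(spec$functions, function(f) seq_along(f$levels) - 1L)
  P <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(P) <- names(spec$functions)
  pat <- sapply(spec$measures, function(m) {
    ok <- rep(TRUE, nrow(P))
    for (fn in names(m$requires)) {
      need <- match(m$requires[[fn]], spec$functions[[fn]]$levels) - 1L
      ok <- ok & P[[fn]] >= need
    }
    as.integer(ok)
  })
  if (is.null(dim(pat))) pat <- matrix(pat, nrow = nrow(P))
  key <- apply(pat, 1, paste, collapse = "")
  split(seq_len(nrow(P)), key)
}

# random valid small spec for property tests (seed controlled by caller)
random_small_spec <- function() {
  n_lev <- sample(2:4, 1)
  n_bin <- sample(1:3, 1)
  fns <- c(list(cognitive_function("lev", "leveled",
                                   paste0("L", seq_len(n_lev) - 1L))),
           lapply(seq_len(n_bin), function(i)
             cognitive_function(paste0("b", i), "binary")))
  fnames <- vapply(fns, `[[`, "", "name")
  n_meas <- sample(2:6, 1)
  ms <- lapply(seq_len(n_meas), function(j) {
    picked <- sample(fnames, sample(1:length(fnames), 1))
    req <- vapply(picked, function(fn) {
      lv <- if (fn == "lev") paste0("L", seq_len(n_lev) - 1L)
            else c("low", "high")
      sample(lv[-1L], 1)
    }, "")
    np_measure(paste0("m", j), req,
               direction = sample(c("higher", "lower"), 1))
  })
  incidence_spec(fns, ms, name = "random")
}

# full hypergeometric enumeration for the two-sided Fisher exact test
fisher_oracle <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x <- max(0, k - n):min(k, m)
  p <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# O(n^2) pairwise-comparison AUC oracle, ties counted half
auc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

uniform_prior <- function(model) rep(1 / model$n_states, model$n_states)
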