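# cogposet

Poset-based classification of cognitive functioning profiles from
neuropsychological (NP) test batteries, with downstream analysis of
conversion risk from mild cognitive impairment (MCI) to Alzheimer's
disease (AD).

## The problem

NP measures are impure: a verbal list-learning trial taps attention and
word fluency as well as episodic memory, so a poor score does not
identify the impaired function, and sum scores or factor subscales do
not resolve the ambiguity. `cogposet` implements a latent-state
alternative built on partially ordered sets:

1. **State model.** An incidence specification (a Q-matrix-style table)
   lists, per measure *j*, the (function, minimum level) requirements
   for performing well on it. Every assignment of levels to functions
   (a *profile*) implies an ideal response pattern — pass measure *j*
   iff all its requirements are met — and profiles with identical
   patterns are merged into one distinguishable *state*. States are
   partially ordered by componentwise dominance of their patterns. For
   the bundled ten-measure battery (episodic memory at levels 0–3 plus
   binary word fluency, selective attention, cognitive flexibility and
   perceptual motor speed) the 64 profiles merge into **29 states**,
   four of them confounded for cognitive flexibility.
2. **Classification.** Each measure carries two response densities,
   `f_high` for subjects mastering its requirements and `f_low` for the
   rest. From a uniform prior `π(s) = 1/29`, Bayes' rule gives
   `p(s | x) ∝ π(s) · Π_j f_{pattern(s)_j}(x_j)` over observed measures.
   The probability of functioning at level ≥ *l* of a function is the
   posterior mass of the corresponding up-set, with confounded states
   contributing weighted mass.
3. **Outcome analysis.** Cutoff subgroups on those probabilities, 2×2
   contingency tables with Wald CIs (`p ± z·sqrt(p(1−p)/n)`) and
   two-sided Fisher exact tests, multivariate logistic prediction with
   ROC/AUC, and conversion-aligned trajectory histograms.
4. **Synthetic cohorts.** A generator with known ground truth (latent
   states, state-dependent responses, APOE e4, logistic conversion law,
   longitudinal decline) makes the whole pipeline testable without
   clinical data.

## Worked example

```r
library(cogposet)

spec <- adni_table1_spec()          # bundled ten-measure battery
model <- build_model(spec)
model
#> Poset model on 'adni_table1': 29 states (4 confounded), 10 measures
which(model$confounded)
#> [1]  7 14 21 28
upset(model, "episodic_memory", "level2")
#>  [1]  1  2  3  4  5  6  7  8  9 10 11 12 13 14

# synthetic MCI-like cohort with known ground truth
cfg <- cohort_config(n_subjects = 268, seed = 42)
cohort <- generate_cohort(cfg, model)
tab <- responses_table(cohort)

# fit response distributions, classify, derive function probabilities
fit <- fit_response_models(tab, model, labels = mastery_labels(cohort, model))
records <- classify_cohort(tab, fit, model)
records <- function_probability_table(records, model)
mean(records$map_state == cohort$truth$true_state)
#> [1] 0.5597015

# cutoff subgroup vs conversion, published-style summary
an <- merge(records, cohort$subjects[c("subject_id", "apoe_e4", "converted")],
            by = "subject_id")
an <- assign_subgroups(an)
build_contingency(an, "em2_low")
#> Contingency for subgroup 'em2_low' (n = 268)
#>          subgroup
#> converted in out
#>       yes 69  31
#>       no  47 121
#> conversion %: 59.5%+/-8.9% 20.4%+/-6.4%
#> two-sided Fisher p = 8.586e-11, odds ratio = 5.730
```

Reading the output: 29 distinguishable states with the four
flexibility-confounded classes at ids 7/14/21/28; the level-2
episodic-memory up-set (states 1–14); ~56% single-battery MAP state
accuracy on the synthetic cohort (state identity is only partly
determined by one battery — certainty accrues over repeated batteries);
and a contingency table showing the low-level-2-memory subgroup
converting at 59.5% ± 8.9% (Wald 95%) against 20.4% outside it.

Published summary statistics are reproduced directly from their counts:

```r
proportion_with_ci(41, 67)
#> proportion half_width
#>   61.19403   11.66849          # printed as 61.2% ± 11.7%
fisher_exact_two_sided(matrix(c(41, 26, 60, 141), 2))
#> [1] 9.158264e-06               # printed as "0.000"
```

## Command line

A thin wrapper over the same functions ships in
`inst/scripts/cogposet.R`:

```sh
Rscript inst/scripts/cogposet.R build-model --out out/
Rscript inst/scripts/cogposet.R end-to-end --n 268 --seed 1 --out out/
```

Commands: `build-model`, `simulate`, `fit`, `classify`, `analyze`,
`end-to-end`; every run writes a `manifest.json` recording inputs and
the seed.

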