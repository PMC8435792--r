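---
title: "Evaluating minimal-dose strength training against an elicited ROPE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating minimal-dose strength training against an elicited ROPE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Powerlifters and their coaches often want the *least* training that still
produces a worthwhile gain in competition strength — a minimum effective
training dose (METD). Intervention studies in this population are
necessarily small (a handful of competitive athletes per arm), so the
usual significance-testing machinery is close to useless: what matters is
not whether a change is distinguishable from zero, but whether it is
large enough for athletes and coaches to *care about*, and with what
probability.

`metdose` implements an estimation-based Bayesian workflow built around
that question:

1. **An elicited, distributional ROPE.** Survey respondents (athletes and
   coaches) state what 6-week strength change they would consider
   meaningful, per lift and for the powerlifting total. An intercept-only
   Bayesian model, $Y_i = a + e_i$, is fit to these responses; the
   posterior draws of $a$ form a *distribution* over the minimal
   meaningful change — a region of practical equivalence (ROPE) that
   carries the disagreement between respondents instead of a hard
   threshold.
2. **Change-score ANCOVA.** Each two-arm training study is analysed with
   $Y^{change}_i = \beta_{00} + \beta_{10} Y^{pre}_i + \beta_{20}
   \mathrm{Group}_i + e_i$, baseline-adjusted and with an informative
   normal prior available for the intercept, which under treatment
   coding is the reference group's adjusted mean. Per-group estimated
   marginal means (EMMs) are evaluated at the pooled mean baseline.
3. **Posterior-vs-ROPE statistics.** Each group's EMM draw set is
   summarized by its KDE mode, 95% highest-density interval, the
   probability of superiority over the ROPE (ROC AUC between the two
   draw sets), and the overlap coefficient of the two kernel densities
   (a probability-of-equivalence proxy).
4. **Internal meta-analysis.** Arms sharing the same broad approach
   (near-maximal "daily max" singles) are pooled across studies with
   `change ~ pre + (1 | study/group/participant)` — nested random
   intercepts, no condition coefficient — to estimate the overall
   adjusted change of that style of training.

A synthetic-data module generates elicitation surveys and
quasi-randomized cohorts with this exact structure, so the complete
pipeline can be exercised, tested and calibrated without any external
data.

## Worked example

```{r, eval = FALSE}
library(metdose)

# elicited minimal meaningful changes, moment-matched to the survey
# summaries (n = 137; powerlifting total 17.5 +/- 12.1 kg)
survey <- generate_elicitation(elicitation_config(seed = 1))
total <- survey$value_kg[survey$outcome == "Total"]

rope_fit <- fit_intercept_model(total, mcmc = mcmc_config(seed = 2))
hdi(draws_of(rope_fit, "a"))          # c. 15.4 .. 19.5 kg
kde_mode(draws_of(rope_fit, "a"))     # c. 17.5 kg

# a two-arm cohort at the published study-3 characteristics
cohort <- generate_cohort(cohort_config(
  list(reference_arm("study3_MAX"), reference_arm("study3_MAX_BOFF")),
  seed = 3
))
fit <- fit_ancova(cohort, outcome = "Total", reference = "MAX",
                  prior = prior_from_summary(11.4, 10),
                  mcmc = mcmc_config(seed = 4))
rope <- as_rope(rope_fit)
lapply(emm_draws(fit), summarize_effect, rope = rope)
```

## Models and priors

**Backend.** All three models are Gaussian linear models fit by MCMC
with JAGS (via `rjags`), four chains by default with 1,000 warmup and
1,000 retained iterations each; chain $c$ is seeded `seed + c` so every
fit is reproducible from one base seed. The JAGS `glm` module is loaded
at package load so the regression coefficients are block-updated; this
matters at the sample sizes this package targets (n = 4–8 per arm),
where single-site updates of a treatment-coded intercept and contrast
are strongly autocorrelated.

**Default ("uninformed") priors.** Where no informative prior is given,
location parameters get Student-t(3, median(y), 2.5·MAD(y)) and the
residual scale a half-Student-t(3, 0, 2.5·MAD(y)) — the data-scaled
weakly-informative convention of modern Bayesian regression software.
The MAD-based scale is floored at 1 kg so degenerate inputs (all values
equal) remain fittable. Group contrasts and the baseline slope get
near-flat normal priors (precision $10^{-6}$).

**Informed and chained priors.** `prior_from_summary(location, scale)`
encodes a published mean ± SD as a normal prior on the reference-group
intercept; `prior_from_posterior(draws)` summarizes a previous fit's
draws into the next study's prior (sequential updating), with a
documented scale floor of $10^{-3}$ kg for degenerate draw sets.

**Residual-scale floor.** All models truncate the residual SD below at
$10^{-3}$ kg (far below the smallest plate increment). Without it,
exactly-degenerate synthetic data (zero configured noise) puts infinite
density at $\sigma = 0$ and no sampler can proceed; with it, degenerate
data concentrate the posterior against the floor and the location
parameters behave as expected.

**Convergence gate.** Every fit computes split R-hat and a bulk
effective sample size (autocorrelation-based, summed over chains) for
each monitored parameter and *errors* — rather than warns — when split
R-hat ≥ 1.01 or ESS ≤ 400. The AUC and overlap statistics downstream
consume raw draw sets and would silently absorb non-convergence, so a
hard gate is the safer default. Thresholds are configurable in
`mcmc_config()`.

**The meta-model and weak identification.** With one observation per
participant, the participant-level variance and the residual variance
are only jointly identified: the likelihood constrains their sum, and
the two chains random-walk against each other (about 40 effective draws
per 1,000). The model is therefore parameterized with hierarchical
centring (participant means centred on group means, and so on upward) —
the same model, much better Gibbs mixing — and its default sampler
settings retain 20,000 draws per chain, which costs roughly two seconds
and clears the gate with a comfortable margin. The same reasoning
applies to the optional participant intercept in `fit_ancova()`
(`participant_intercept = TRUE`); it is off by default because, at one
observation per participant, it changes the EMMs by less than the Monte
Carlo error while requiring meta-model-scale draw counts.

## Posterior summaries

- **HDI** is computed on the draws directly (shortest contiguous window
  of the sorted draws containing ⌈mass·n⌉ of them), the convention of
  the Bayesian-summary literature this workflow follows; ties between
  equal-width windows resolve to the lowest window.
- **KDE mode** uses a Gaussian kernel with Silverman's rule on a
  512-point grid over the draw range. The estimator the original
  analyses used is not specified beyond "density"; Silverman/512 is the
  de facto default and both are exposed as arguments.
- **AUC** is computed by midranks, exactly equal to pairwise
  enumeration with a half-count for ties, in O((n+m) log(n+m)).
- **Overlap** integrates min(f̂, ĝ) of the two KDEs on a shared grid
  spanning the union range padded by three bandwidths, by trapezoid
  rule, clamped to [0, 1] (trapezoid error can exceed the bounds by a
  hair). Note that mode, HDI, AUC and overlap answer different
  questions; in particular the mode may fall outside a multimodal HDI,
  and no such ordering is asserted.

## The synthetic-data generator

The generator reproduces the *statistical shape* of the study data, not
its physiology:

- **Elicitation**: normal per-outcome draws at the published summary
  values (total 17.5 ± 12.1 kg, n = 137, role mix 99/31/7), optionally
  truncated at zero. With `moment_match = TRUE` (default) draws are
  standardized and affinely rescaled so the sample mean and SD equal
  the configured values to machine precision — ROPE-recovery tests are
  then anchored in location/spread, while the draw shape stays random.
  When truncation and moment matching are combined, matching is applied
  after truncation and can push the smallest value marginally below
  zero when the mean is within ~1.5 SD of zero; the two flags are
  mostly useful separately.
- **Cohorts**: per-lift baselines from the published per-arm means/SDs;
  change scores as true mean + optional slope·(centred baseline) +
  noise; the total always the sum of the three lifts. The true change
  means default to a split of the published modal total changes (11.4,
  33.7, 26.8, 15.3 kg across the four arms) and the per-lift change SD
  defaults to 7 kg, chosen once so the implied total-change SD (~12 kg)
  matches the width of the published uncertainty intervals; the raw
  change scores themselves are archived externally and not printed.
- **Sessions**: 6 weeks × 3 days with the 2-3-1 squat/bench/deadlift
  frequency; main RPE near the 9–9.5 target, back-off sets at 80% of
  the day's single, AMRAP repetitions at the published per-lift means
  (13.1/16.7/11.5), soreness on the 0–5 scale.
- **Dropout** is participant-level and missing-completely-at-random,
  reflecting that the original attrition was facility-driven, not
  treatment-driven.
- **Allocation** stratifies by Wilks-score class (bands 300–340 up to
  510–550; gap values map to the nearest boundary, ties to the lower
  band) and deals athletes within class in seeded permuted blocks, so
  group sizes stay within one and no group systematically receives a
  class's leftover athlete. Whether the original allocation re-drew
  freely within class is not stated; this deterministic-under-seed
  scheme is our documented choice. Wilks coefficients are the classic
  fifth-order male/female polynomials, supplied as a swappable table.

What passing tests on these data do *not* show: real elicitation
responses are integer-ish, skewed and heaped at round numbers (the
generator's normality is an assumption, flagged here); real change
scores can violate the linear change-on-baseline form; and real dropout
may correlate with training response. Parameter recovery on the
generator validates the *machinery*, not those assumptions.

## Problem sizes and numerical choices

The test suite runs the full survey-scale ROPE fit (n = 137, 4×1,000
retained draws), a 50-replicate coverage study of the ANCOVA contrast at
n = 8 per arm, and meta-model fits at up to 50,000 retained draws per
chain; the whole suite completes in about a minute on one core. Grids
for KDE statistics are 512 points; HDI mass defaults to 0.95;
`auc_superiority` and `hdi` are verified against brute-force oracles up
to n, m = 200 in the tests.

## Known limitations

- The "objective" ROPE (derived from competition-record databases) is
  supported only as an externally supplied draw file; no ranking model
  is implemented.
- Outcomes (SQ, BP, DL, total) are modelled independently; no shared
  structure across lifts.
- No frequentist ANCOVA, model comparison, or within-block progression
  modelling.
- Session logs are generated for descriptive summaries only; they do
  not feed back into the outcome models.
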