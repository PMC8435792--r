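# metdose

Bayesian evaluation of minimal-dose strength-training interventions
against an **elicited region of practical equivalence (ROPE)**.

## What problem this solves

Powerlifting intervention studies are small — a few competitive athletes
per arm — so asking "is the change significantly different from zero?"
is the wrong question. The workable question is: *what is the
probability that the strength change produced by a protocol exceeds
what athletes and coaches themselves consider meaningful?*

`metdose` implements that workflow end to end:

- **Elicited ROPE.** Survey responses on the minimal meaningful 6-week
  change (per lift and for the powerlifting total) are modelled with an
  intercept-only Bayesian model, `Y_i = a + e_i`. The posterior draws
  of `a` form a *distribution* over the minimal meaningful change,
  carrying respondent disagreement instead of a hard cut-off.
- **Change-score ANCOVA.** Each two-arm study is analysed with
  `change = b00 + b10 * pre + b20 * group + e`, the baseline centred so
  the treatment-coded intercept is the reference group's adjusted mean;
  an informative normal prior (e.g. pilot data, or the previous study's
  posterior via `prior_from_posterior()`) can anchor it. Per-group
  estimated marginal means (EMMs) are evaluated at the pooled mean
  baseline.
- **Posterior-vs-ROPE statistics.** KDE mode, 95% highest-density
  interval, probability of superiority over the ROPE (ROC AUC between
  draw sets, midrank tie handling), and the kernel-density overlap
  coefficient (a probability-of-equivalence proxy).
- **Internal meta-analysis.** Arms sharing an approach are pooled
  across studies with `change ~ pre + (1 | study/group/participant)`
  (nested random intercepts, no condition coefficient).
- **Synthetic data.** Generators for elicitation surveys (optionally
  moment-matched exactly to target summaries), quasi-randomized
  Wilks-stratified cohorts, session logs (RPE, soreness, AMRAP reps)
  and MCAR dropout, plus training-protocol volume accounting
  (`weekly_reps()`, `relative_volume()`) and Wilks scoring.

Models are fit with JAGS via `rjags` (4 chains × 1,000 warmup + 1,000
sampling by default) behind a hard convergence gate: split R-hat < 1.01
and bulk ESS > 400, or the fit errors.

## Worked example

```r
library(metdose)

# 137 elicited responses, moment-matched to the survey summary
# (powerlifting total: 17.5 +/- 12.1 kg)
survey <- generate_elicitation(elicitation_config(seed = 1))
total  <- survey$value_kg[survey$outcome == "Total"]

rope_fit <- fit_intercept_model(total, mcmc = mcmc_config(seed = 2))
round(hdi(draws_of(rope_fit, "a")), 2)
#>   low  high
#> 15.49 19.58
round(kde_mode(draws_of(rope_fit, "a")), 2)
#> [1] 17.67

# a synthetic two-arm cohort at published study characteristics:
# "daily max" singles (MAX) vs singles + back-off sets (MAX+boff)
cohort <- generate_cohort(cohort_config(
  list(reference_arm("study3_MAX"), reference_arm("study3_MAX_BOFF")),
  seed = 3
))
fit  <- fit_ancova(cohort, outcome = "Total", reference = "MAX",
                   prior = prior_from_summary(11.4, 10),
                   mcmc = mcmc_config(seed = 4))
rope <- as_rope(rope_fit)
for (g in names(emm_draws(fit)))
  print(summarize_effect(emm_draws(fit)[[g]], rope, label = g))
#> MAX: mode 8.6 kg, 95% HDI [0.5, 16.7] kg; P(> ROPE) = 2.0%, P(~ ROPE) = 6.8% (subjective ROPE)
#> MAX_boff: mode 34.9 kg, 95% HDI [25.6, 43.7] kg; P(> ROPE) = 100.0%, P(~ ROPE) = 0.3% (subjective ROPE)
```

Reading: the elicited minimal meaningful total change concentrates
around 17.7 kg (95% HDI 15.5–19.6 kg). In this simulated cohort the
singles-only arm's most probable change (8.6 kg) has a 2% chance of
exceeding the ROPE, while adding two back-off sets lifts the most
probable change to ~35 kg with effectively certain superiority — at the
cost of 600% more weekly volume (`relative_volume(protocol_preset("MAX_BOFF"),
protocol_preset("MAX"))`).

The whole sequence (simulate → ROPE → fit → compare → meta → report)
can be run in one call with `run_pipeline(run_config(...))`, or from a
shell via the thin CLI in `inst/cli/metdose.R` (verbs `simulate`,
`rope`, `fit`, `compare`, `meta`, `report`, `all`; exit codes 0/2/3 for
success / config error / convergence error). Outputs are CSV draws,
JSON summaries with provenance fields, a descriptives table, density
plots and a full run log; reruns from the same config and seed are
byte-identical.

See `vignettes/elicitation-anchored-evaluation.Rmd` for the models,
priors, numerical choices and the generator's scope and limits.

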