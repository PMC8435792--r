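test_that("conjugate oracle returns the closed-form posterior summary", {
  expect_equal(conjugate_oracle(c(0, 0, 0, 0))$location, 0)
  expect_equal(conjugate_oracle(c(1, 2, 3))$location, 2)
  # moment-matched survey sample: location equals the configured mean
  s <- generate_elicitation(elicitation_config(seed = 1))
  tot <- s$value_kg[s$outcome == "Total"]
  orc <- conjugate_oracle(tot)
  expect_equal(orc$location, 17.5, tolerance = 1e-9)
  expect_equal(orc$scale, 12.1 / sqrt(137), tolerance = 1e-9)
  expect_error(conjugate_oracle(5), ">= 2")
})

test_that("intercept model concentrates on degenerate data", {
  fit <- fit_intercept_model(rep(17.5, 137), mcmc = fast_mcmc(1))
  expect_lt(abs(kde_mode(draws_of(fit, "a")) - 17.5), 0.1)
})

test_that("intercept model agrees with the conjugate oracle", {
  check_against_oracle <- function(values, seed) {
    fit <- fit_intercept_model(values, mcmc = fast_mcmc(seed))
    a <- draws_of(fit, "a")
    orc <- conjugate_oracle(values)
    ess <- fit$diagnostics$ess[fit$diagnostics$parameter == "a"]
    mcse <- sd(a) / sqrt(ess)
    expect_lt(abs(mean(a) - orc$location), 3 * mcse)
    invisible(NULL)
  }
  # hand-sized input: oracle location is the sample mean 17.5
  check_against_oracle(c(10, 15, 20, 25), seed = 2)
  # survey-scale moment-matched sample
  s <- generate_elicitation(elicitation_config(seed = 3))
  check_against_oracle(s$value_kg[s$outcome == "Total"], seed = 4)
  # a spread of random datasets
  set.seed(5)
  for (i in 1:8) {
    check_against_oracle(rnorm(sample(20:200, 1), runif(1, -5, 30),
                               runif(1, 1, 15)), seed = 5 + i)
  }
})

test_that("posterior SD tracks the conjugate oracle across datasets", {
  set.seed(6)
  for (i in 1:5) {
    values <- rnorm(100, 15, 10)
    fit <- fit_intercept_model(values, mcmc = fast_mcmc(20 + i))
    a <- draws_of(fit, "a")
    orc <- conjugate_oracle(values)
    # sd of an sd estimate ~ sd / sqrt(2 ess); allow 3 of those
    ess <- fit$diagnostics$ess[fit$diagnostics$parameter == "a"]
    expect_lt(abs(sd(a) - orc$sd), 3 * orc$sd / sqrt(2 * ess) + 0.02 * orc$sd)
  }
})

test_that("prior specifications map summaries and draws to normal priors", {
  p <- prior_from_summary(10, 5)
  expect_identical(p$family, "normal")
  expect_equal(c(p$location, p$scale), c(10, 5))
  expect_error(prior_from_summary(10, 0), "> 0")

  p2 <- prior_from_summary(0, 1)
  expect_equal(c(p2$location, p2$scale), c(0, 1))

  set.seed(7)
  z <- rnorm(4000)
  p3 <- prior_from_posterior(z)
  expect_lt(abs(p3$location), 0.05)
  expect_lt(abs(p3$scale - 1), 0.05)
  expect_error(prior_from_posterior(rnorm(50)), ">= 100")
  # degenerate draws get the documented scale floor
  p4 <- prior_from_posterior(rep(3, 500))
  expect_equal(p4$location, 3)
  expect_equal(p4$scale, 1e-3)
})

test_that("chaining a prior from a fit recovers the generating change", {
  coh <- generate_cohort(two_arm_config(c(7, 6, 7), c(7, 6, 7), n = 30,
                                        sd = 0.5, seed = 8))
  fit <- fit_ancova(coh, "Total", mcmc = fast_mcmc(9))
  p <- prior_from_posterior(emm_draws(fit)[["A"]])
  expect_lt(abs(p$location - 20), 0.5)
})

test_that("ANCOVA recovers true group effects", {
  coh <- generate_cohort(two_arm_config(c(4, 3, 3), c(10, 10, 10), n = 50,
                                        sd = 2 / sqrt(3), seed = 10))
  fit <- fit_ancova(coh, "Total", mcmc = fast_mcmc(11))
  modes <- vapply(emm_draws(fit), kde_mode, numeric(1))
  expect_lt(abs(modes[["A"]] - 10), 1)
  expect_lt(abs(modes[["B"]] - 30), 1)
})

test_that("zero-noise ANCOVA concentrates slope at 0 and EMMs at truth", {
  coh <- generate_cohort(two_arm_config(c(4, 3, 3), c(10, 10, 10), n = 10,
                                        sd = 0, seed = 12))
  fit <- fit_ancova(coh, "Total",
                    mcmc = mcmc_config(chains = 2, warmup = 1000,
                                       sampling = 4000, seed = 13))
  b10 <- draws_of(fit, "b10")
  expect_lt(abs(mean(b10)) + 3 * sd(b10), 0.01)
  emm <- emm_draws(fit)
  expect_equal(mean(emm[["A"]]), 10, tolerance = 1e-3)
  expect_equal(mean(emm[["B"]]), 30, tolerance = 1e-3)
})

test_that("EMM contrast draws equal the group coefficient exactly", {
  coh <- generate_cohort(two_arm_config(c(5, 4, 4), c(8, 8, 8), n = 8,
                                        sd = 3, seed = 14))
  fit <- fit_ancova(coh, "Total", mcmc = fast_mcmc(15))
  emm <- emm_draws(fit)
  expect_equal((emm[["A"]] - emm[["B"]]), -draws_of(fit, "b20_B"),
               tolerance = 1e-12)
})

test_that("the informed prior anchors the reference group", {
  coh <- generate_cohort(two_arm_config(c(4, 3, 3), c(10, 10, 10), n = 4,
                                        sd = 5, seed = 16))
  tight <- prior_from_summary(0, 0.5) # pulls the reference mean to 0
  fit_w <- fit_ancova(coh, "Total", mcmc = fast_mcmc(17))
  fit_i <- fit_ancova(coh, "Total", prior = tight, mcmc = fast_mcmc(17))
  expect_lt(mean(emm_draws(fit_i)[["A"]]), mean(emm_draws(fit_w)[["A"]]))
  expect_lt(abs(mean(emm_draws(fit_i)[["A"]])), 4)
})

test_that("participant intercepts leave single-observation EMMs unchanged", {
  coh <- generate_cohort(two_arm_config(c(4, 3, 3), c(10, 10, 10), n = 12,
                                        sd = 2, seed = 18))
  f0 <- fit_ancova(coh, "Total", mcmc = fast_mcmc(19))
  # the participant/residual variance split is only weakly identified,
  # so the u0i variant needs meta-model-scale draw counts
  f1 <- fit_ancova(coh, "Total",
                   mcmc = fast_mcmc(19, warmup = 2000, sampling = 25000),
                   participant_intercept = TRUE)
  m0 <- vapply(emm_draws(f0), kde_mode, numeric(1))
  m1 <- vapply(emm_draws(f1), kde_mode, numeric(1))
  mcse <- sd(emm_draws(f0)[["A"]]) / sqrt(400) # gate floor on ESS
  expect_lt(max(abs(m0 - m1)), 3 * mcse)
})

test_that("ANCOVA input validation rejects unusable designs", {
  coh <- generate_cohort(cohort_config(list(group_config("A", 8)), seed = 20))
  expect_error(fit_ancova(coh, "Total"), ">= 2 groups")
  coh2 <- generate_cohort(two_arm_config(c(1, 1, 1), c(2, 2, 2), n = 4,
                                         seed = 21))
  expect_error(fit_ancova(coh2, "Total", reference = "Z"), "reference")
  expect_error(fit_intercept_model(c(1)), ">= 2")
})

test_that("meta model recovers a homogeneous overall change", {
  mk <- function(label, study, seed_offset) {
    group_config(label, n = 8, study = study, lifts = tibble::tibble(
      lift = c("SQ", "BP", "DL"),
      pre_location = c(180, 120, 210), pre_scale = c(30, 18, 32),
      change_mean = c(5, 5, 5), change_sd = rep(2 / sqrt(3), 3)
    ))
  }
  cc <- cohort_config(list(mk("MAX", "s1"), mk("MAX_boff", "s1"),
                           mk("MAX_boff", "s2")), seed = 22)
  coh <- generate_cohort(cc)
  # near-zero heterogeneity makes the variance components mix slowest;
  # this fit needs the largest draw count in the suite
  fit <- fit_meta(coh, "Total",
                  mcmc = mcmc_config(warmup = 2000, sampling = 50000,
                                     seed = 23))
  b0 <- draws_of(fit, "b0")
  expect_lt(abs(kde_mode(b0) - 15), 1.5)
  # between-group heterogeneity near zero under homogeneity
  expect_lt(median(draws_of(fit, "sd_group")), 3)
  expect_true(all(draws_of(fit, "sd_part") >= 0))
})

test_that("meta overall change lies between heterogeneous group means", {
  cc <- two_arm_config(c(4, 3, 3), c(10, 10, 10), n = 8, sd = 2, seed = 24)
  coh <- generate_cohort(cc)
  fit <- fit_meta(coh, "Total",
                  mcmc = mcmc_config(warmup = 2000, sampling = 20000,
                                     seed = 25))
  m <- kde_mode(draws_of(fit, "b0"))
  expect_gt(m, 10)
  expect_lt(m, 30)
})

test_that("meta model demands nesting labels", {
  coh <- generate_cohort(two_arm_config(c(4, 3, 3), c(5, 5, 5), n = 4,
                                        seed = 26))
  coh$study <- NULL
  expect_error(fit_meta(coh, "Total"), "study")
})

test_that("convergence gate reports the offending parameters", {
  s <- generate_elicitation(elicitation_config(seed = 27))
  vals <- s$value_kg[s$outcome == "Total"]
  strict <- mcmc_config(chains = 2, warmup = 500, sampling = 1000,
                        seed = 28, ess_min = 1e6)
  expect_error(fit_intercept_model(vals, mcmc = strict), "ESS")
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(29)
  good <- list(rnorm(1000), rnorm(1000))
  bad <- list(rnorm(1000), rnorm(1000, 5))
  expect_lt(split_rhat(good), 1.01)
  expect_gt(split_rhat(bad), 1.5)
  expect_equal(split_rhat(list(rep(1, 100), rep(1, 100))), 1)
})
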