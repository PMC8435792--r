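# JAGS model fragments -------------------------------------------------

# Prior line for a location parameter: informed normal, or the
# weakly-informative data-scaled default (Student-t, 3 df).
location_prior_line <- function(par, prior, loc_name, prec_name) {
  if (!is.null(prior) && prior$family == "normal") {
    sprintf("%s ~ dnorm(%s, %s)", par, loc_name, prec_name)
  } else {
    sprintf("%s ~ dt(%s, %s, 3)", par, loc_name, prec_name)
  }
}

jags_intercept_model <- function(informed) {
  paste0(
    "model {\n",
    "  for (i in 1:N) { y[i] ~ dnorm(a, tau) }\n",
    "  ", location_prior_line("a", if (informed) list(family = "normal"),
                             "a_loc", "a_prec"), "\n",
    "  sigma ~ dt(0, s_prec, 3) T(1.0E-3,)\n",
    "  tau <- pow(sigma, -2)\n",
    "}\n"
  )
}

#' Fit the intercept-only elicitation (ROPE) model
#'
#' Fits `y_i = a + e_i` to elicited minimal-meaningful-change values so
#' the posterior of the intercept `a` captures both the central elicited
#' change and the uncertainty across respondents; the intercept draws
#' define the distributional region of practical equivalence (ROPE).
#' By default the priors are weakly informative and data-scaled
#' (Student-t(3, median(y), 2.5 MAD(y)) on `a`, half-t(3, 0, 2.5 MAD(y))
#' on the residual scale); an informative normal prior on `a` can be
#' supplied instead. The fit errors if the convergence gate (split
#' R-hat, bulk ESS) fails.
#'
#' @param values Numeric vector of >= 2 elicited changes (kg).
#' @param prior `NULL` for the default prior, or a normal [prior_spec()]
#'   on the intercept.
#' @param mcmc An [mcmc_config()].
#' @return An object of class `rope_posterior` with elements `draws`
#'   (long tibble of `a` and `sigma` draws), `diagnostics`, `n`, `mcmc`.
#' @export
#' @examples
#' \donttest{
#' fit <- fit_intercept_model(rnorm(50, 17.5, 12.1),
#'                            mcmc = mcmc_config(seed = 1))
#' hdi(draws_of(fit, "a"))
#' }
fit_intercept_model <- function(values, prior = NULL, mcmc = mcmc_config()) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need >= 2 values")
  if (anyNA(values)) stop("values must not contain NA")
  informed <- !is.null(prior) && prior$family == "normal"
  s_scale <- default_prior_scale(values)
  data <- list(
    y = values, N = length(values),
    a_loc = if (informed) prior$location else median(values),
    a_prec = 1 / (if (informed) prior$scale else s_scale)^2,
    s_prec = 1 / s_scale^2
  )
  samples <- run_jags(jags_intercept_model(informed), data,
                      c("a", "sigma"), mcmc)
  diag <- fit_diagnostics(samples)
  check_convergence(diag, mcmc, "intercept-only model")
  structure(
    list(draws = draws_long(samples), diagnostics = diag,
         n = length(values), mcmc = mcmc,
         prior = prior %||% prior_spec(family = "default")),
    class = "rope_posterior"
  )
}

#' Closed-form conjugate posterior for the mean of a normal sample
#'
#' Independent oracle for [fit_intercept_model()] under vague priors: in
#' the vague limit of the normal-inverse-gamma conjugate family, the
#' marginal posterior of the mean is a Student-t with `n - 1` degrees of
#' freedom, location `mean(y)` and scale `sd(y)/sqrt(n)`.
#'
#' @param values Numeric vector of >= 2 values.
#' @return List with `location`, `scale`, `df` and the implied posterior
#'   `sd` (`scale * sqrt(df / (df - 2))`, `NA` if `df <= 2`).
#' @export
conjugate_oracle <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need >= 2 values")
  n <- length(values)
  df <- n - 1
  scale <- sd(values) / sqrt(n)
  list(location = mean(values), scale = scale, df = df,
       sd = if (df > 2) scale * sqrt(df / (df - 2)) else NA_real_)
}

# ANCOVA ---------------------------------------------------------------

jags_ancova_model <- function(informed, participant_intercept) {
  resid <- if (participant_intercept) "mu[i] + u[part[i]]" else "mu[i]"
  u_block <- if (participant_intercept) {
    paste0("  for (j in 1:NP) { u[j] ~ dnorm(0, tau_u) }\n",
           "  sd_u ~ dt(0, s_prec, 3) T(0,)\n",
           "  tau_u <- pow(sd_u, -2)\n")
  } else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    mu[i] <- b00 + b10 * x[i] + inprod(b2, G[i,])\n",
    "    y[i] ~ dnorm(", resid, ", tau)\n",
    "  }\n",
    "  ", location_prior_line("b00", if (informed) list(family = "normal"),
                             "b00_loc", "b00_prec"), "\n",
    "  b10 ~ dnorm(0, 1.0E-6)\n",
    "  for (k in 1:K1) { b2[k] ~ dnorm(0, 1.0E-6) }\n",
    u_block,
    "  sigma ~ dt(0, s_prec, 3) T(1.0E-3,)\n",
    "  tau <- pow(sigma, -2)\n",
    "}\n"
  )
}

#' Fit the change-score ANCOVA model
#'
#' Fits `change_i = (b00 [+ u0i]) + b10 * pre_i + b20 * group_i + e_i`
#' for one outcome, with the baseline (pre) score centred at its pooled
#' mean so the intercept is the estimated marginal mean (EMM) of the
#' reference group at the average baseline. Treatment (dummy) coding is
#' used with the informed-prior group as reference, so an informative
#' normal prior on the intercept anchors that group's mean. Per-group
#' EMM draws evaluated at the pooled mean pre score are returned as
#' parameters `emm_<group>`.
#'
#' The optional participant-level intercept `u0i` is off by default:
#' with one observation per participant it is exchangeable with the
#' residual and only weakly identified.
#'
#' @param data Intervention dataset tibble (as from [generate_cohort()]).
#' @param outcome One of `"SQ"`, `"BP"`, `"DL"`, `"Total"`.
#' @param reference Reference group label (defaults to the first group
#'   in the data); the intercept prior applies to this group's mean.
#' @param prior `NULL` or a normal [prior_spec()] on the intercept.
#' @param mcmc An [mcmc_config()].
#' @param participant_intercept Include `u0i`.
#' @return An object of class `ancova_posterior` with `draws` (long
#'   tibble: `b00`, `b10`, `b20_<group>`, `sigma`, `emm_<group>`),
#'   `diagnostics`, `groups`, `reference`, `pre_center`, `n`, `mcmc`.
#' @export
fit_ancova <- function(data, outcome = "Total", reference = NULL,
                       prior = NULL, mcmc = mcmc_config(),
                       participant_intercept = FALSE) {
  stopifnot(outcome %in% OUTCOMES)
  d <- data[data$lift == outcome, ]
  if (!nrow(d)) stop("no rows for outcome ", outcome)
  groups <- unique(d$group)
  if (length(groups) < 2) stop("ANCOVA needs >= 2 groups")
  if (any(table(d$group) < 2)) stop("need >= 2 participants per group")
  reference <- reference %||% groups[1]
  if (!reference %in% groups) stop("reference group not present in data")
  others <- setdiff(groups, reference)
  pre_center <- mean(d$pre_kg)
  x <- d$pre_kg - pre_center
  G <- vapply(others, function(g) as.numeric(d$group == g),
              numeric(nrow(d)))
  G <- matrix(G, nrow = nrow(d))
  informed <- !is.null(prior) && prior$family == "normal"
  y <- d$change_kg
  s_scale <- default_prior_scale(y)
  part <- match(d$participant_id, unique(d$participant_id))
  jdata <- list(
    y = y, x = x, G = G, N = nrow(d), K1 = length(others),
    b00_loc = if (informed) prior$location else median(y),
    b00_prec = 1 / (if (informed) prior$scale else s_scale)^2,
    s_prec = 1 / s_scale^2
  )
  if (participant_intercept) jdata$part <- part
  if (participant_intercept) jdata$NP <- max(part)
  params <- c("b00", "b10", "b2", "sigma",
              if (participant_intercept) "sd_u")
  samples <- run_jags(jags_ancova_model(informed, participant_intercept),
                      jdata, params, mcmc)
  diag <- fit_diagnostics(samples)
  check_convergence(diag, mcmc, "ANCOVA model")
  draws <- draws_long(samples)
  # rename b2[k] to the group contrast it measures, and derive EMM draws
  for (k in seq_along(others)) {
    cand <- c(sprintf("b2[%d]", k), if (length(others) == 1) "b2")
    b2k <- intersect(cand, draws$parameter)[1]
    draws$parameter[draws$parameter == b2k] <- paste0("b20_", others[k])
  }
  b00 <- draws[draws$parameter == "b00", ]
  emm <- dplyr::bind_rows(c(
    list(dplyr::mutate(b00, parameter = paste0("emm_", reference))),
    lapply(others, function(g) {
      contrast <- draws$value[draws$parameter == paste0("b20_", g)]
      dplyr::mutate(b00, parameter = paste0("emm_", g),
                    value = .data$value + contrast)
    })
  ))
  structure(
    list(draws = dplyr::bind_rows(draws, emm), diagnostics = diag,
         groups = groups, reference = reference, pre_center = pre_center,
         n = nrow(d), mcmc = mcmc,
         prior = prior %||% prior_spec(family = "default")),
    class = "ancova_posterior"
  )
}

#' Per-group estimated-marginal-mean draws from an ANCOVA fit
#'
#' @param fit An `ancova_posterior`.
#' @return Named list of numeric draw vectors, one per group.
#' @export
emm_draws <- function(fit) {
  stopifnot(inherits(fit, "ancova_posterior"))
  setNames(
    lapply(fit$groups, function(g) draws_of(fit, paste0("emm_", g))),
    fit$groups
  )
}

# Internal meta-analysis ------------------------------------------------

# Hierarchically centred parameterization of the nested random
# intercepts (participant means centred on group means, group means on
# study means, study means on the overall intercept): equivalent to the
# additive random-effects form but with far better Gibbs mixing on
# small, shallow hierarchies.
jags_meta_model <- function() {
  "model {
  for (i in 1:N) {
    y[i] ~ dnorm(m_p[part[i]] + b1 * x[i], tau)
  }
  for (j in 1:NP) { m_p[j] ~ dnorm(m_g[part_grp[j]], tau_p) }
  for (k in 1:NG) { m_g[k] ~ dnorm(m_s[grp_study[k]], tau_g) }
  for (s in 1:NS) { m_s[s] ~ dnorm(b0, tau_s) }
  b0 ~ dt(b0_loc, b0_prec, 3)
  b1 ~ dnorm(0, 1.0E-6)
  sd_study ~ dt(0, s_prec, 3) T(0,)
  sd_group ~ dt(0, s_prec, 3) T(0,)
  sd_part ~ dt(0, s_prec, 3) T(0,)
  tau_s <- pow(sd_study, -2)
  tau_g <- pow(sd_group, -2)
  tau_p <- pow(sd_part, -2)
  sigma ~ dt(0, s_prec, 3) T(1.0E-3,)
  tau <- pow(sigma, -2)
}
"
}

#' Fit the internal meta-analytic multilevel model
#'
#' Pools arms that followed the same broad training approach across
#' studies with the mixed-effects extension of the change-score ANCOVA,
#' `change ~ pre + (1 | study/group/participant)`: a common baseline
#' slope, nested random intercepts for study, group-within-study and
#' participant-within-group, and no condition coefficient. The draws of
#' the population-level intercept `b0` (at the pooled mean baseline) are
#' the overall adjusted change. With one observation per participant the
#' participant-level variance is only weakly identified and is reported
#' as-is; the gate on convergence applies to all monitored parameters.
#' Because the participant and residual variances are only jointly
#' identified, their chains mix an order of magnitude more slowly than
#' the location parameters, so this model's default sampler settings
#' retain 20,000 draws per chain (a couple of seconds of sampling)
#' rather than the 1,000 used by the within-study models.
#'
#' @param data Intervention dataset covering >= 2 groups with `study`
#'   labels present.
#' @param outcome One of `"SQ"`, `"BP"`, `"DL"`, `"Total"`.
#' @param mcmc An [mcmc_config()].
#' @return An object of class `meta_posterior` with `draws` (parameters
#'   `b0`, `b1`, `sd_study`, `sd_group`, `sd_part`, `sigma`),
#'   `diagnostics`, `n`, `mcmc`.
#' @export
fit_meta <- function(data, outcome = "Total",
                     mcmc = mcmc_config(warmup = 2000L, sampling = 20000L)) {
  stopifnot(outcome %in% OUTCOMES)
  d <- data[data$lift == outcome, ]
  if (!nrow(d)) stop("no rows for outcome ", outcome)
  if (!all(c("study", "group", "participant_id") %in% names(d)) ||
      anyNA(d$study) || anyNA(d$group)) {
    stop("meta model requires study, group and participant_id labels")
  }
  grp_full <- interaction(d$study, d$group, drop = TRUE)
  if (nlevels(grp_full) < 2) stop("meta model needs >= 2 groups")
  pre_center <- mean(d$pre_kg)
  y <- d$change_kg
  s_scale <- default_prior_scale(y)
  part <- match(d$participant_id, unique(d$participant_id))
  grp <- as.integer(grp_full)
  study <- as.integer(factor(d$study))
  # nesting maps: participant -> group, group -> study
  part_grp <- grp[match(seq_len(max(part)), part)]
  grp_study <- study[match(seq_len(max(grp)), grp)]
  jdata <- list(
    y = y, x = d$pre_kg - pre_center, N = nrow(d),
    part = part, part_grp = part_grp, grp_study = grp_study,
    NS = max(study), NG = max(grp), NP = max(part),
    b0_loc = median(y), b0_prec = 1 / s_scale^2, s_prec = 1 / s_scale^2
  )
  params <- c("b0", "b1", "sd_study", "sd_group", "sd_part", "sigma")
  samples <- run_jags(jags_meta_model(), jdata, params, mcmc)
  diag <- fit_diagnostics(samples)
  check_convergence(diag, mcmc, "meta-analytic model")
  structure(
    list(draws = draws_long(samples), diagnostics = diag,
         n = nrow(d), pre_center = pre_center, mcmc = mcmc),
    class = "meta_posterior"
  )
}
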