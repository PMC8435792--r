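#' MCMC sampler settings
#'
#' Defaults follow the analysis convention of four chains with 1,000
#' warmup and 1,000 sampling iterations each (4,000 retained draws).
#' Chain `c` is seeded with `seed + c` so runs are reproducible from a
#' single base seed. The convergence gate (split R-hat and bulk
#' effective sample size) is part of the configuration; model fits raise
#' an error rather than a warning when it fails, because downstream
#' AUC/overlap statistics silently inherit any non-convergence.
#'
#' @param chains Number of chains (>= 2).
#' @param warmup Warmup iterations per chain (>= 100; includes the
#'   sampler's adaptation phase).
#' @param sampling Retained sampling iterations per chain (>= 100).
#' @param seed Integer base seed.
#' @param rhat_max Split R-hat threshold (error above).
#' @param ess_min Bulk effective-sample-size threshold (error below).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, warmup = 1000L, sampling = 1000L,
                        seed = 1L, rhat_max = 1.01, ess_min = 400) {
  if (chains < 2) stop("chains must be >= 2")
  if (warmup < 100 || sampling < 100) stop("iterations must be >= 100")
  structure(
    list(chains = as.integer(chains), warmup = as.integer(warmup),
         sampling = as.integer(sampling), seed = as.integer(seed),
         rhat_max = rhat_max, ess_min = ess_min),
    class = "mcmc_config"
  )
}

# Run a JAGS model: returns a coda::mcmc.list with one element per chain.
# Warmup is split between JAGS adaptation and burn-in updates.
run_jags <- function(model_string, data, params, mcmc) {
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed + ch)
  })
  n_adapt <- max(100L, mcmc$warmup %/% 2L)
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  model <- rjags::jags.model(con, data = data, inits = inits,
                             n.chains = mcmc$chains, n.adapt = n_adapt,
                             quiet = TRUE)
  stats::update(model, n.iter = mcmc$warmup - n_adapt + 1L,
                progress.bar = "none")
  rjags::coda.samples(model, variable.names = params,
                      n.iter = mcmc$sampling, progress.bar = "none")
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half, so within-chain trends register as between-sequence variance.
#'
#' @param chains A list of numeric vectors (one per chain), or a matrix
#'   with one column per chain.
#' @return The split R-hat statistic.
#' @export
split_rhat <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[seq(length(x) - n + 1, length(x))])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Per-parameter diagnostics for an mcmc.list: split R-hat and bulk ESS
# (coda autocorrelation-based effective size, summed over chains).
fit_diagnostics <- function(samples) {
  pars <- colnames(samples[[1]])
  ess <- colSums(do.call(rbind, lapply(samples, coda::effectiveSize)))
  rhat <- vapply(pars, function(p) {
    split_rhat(lapply(samples, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  tibble::tibble(parameter = pars, rhat = rhat, ess = as.numeric(ess[pars]))
}

# Enforce the convergence gate; errors listing the offending parameters.
check_convergence <- function(diag, mcmc, context) {
  bad <- diag$parameter[!is.finite(diag$rhat) | diag$rhat > mcmc$rhat_max |
                          diag$ess < mcmc$ess_min]
  if (length(bad)) {
    stop("convergence failure in ", context, " for parameter(s): ",
         paste(bad, collapse = ", "),
         " (split R-hat > ", mcmc$rhat_max, " or bulk ESS < ", mcmc$ess_min,
         "); increase warmup/sampling iterations", call. = FALSE)
  }
  invisible(diag)
}

# Long-format draws tibble (chain, iteration, parameter, value).
draws_long <- function(samples) {
  out <- lapply(seq_along(samples), function(ch) {
    m <- as.matrix(samples[[ch]])
    tibble::tibble(
      chain = ch,
      iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.numeric(m)
    )
  })
  dplyr::bind_rows(out)
}

#' Extract the draws of one parameter from a fitted model
#'
#' @param fit A fitted model object (`rope_posterior`, `ancova_posterior`
#'   or `meta_posterior`).
#' @param parameter Parameter name as it appears in `fit$draws`.
#' @return Numeric vector of pooled posterior draws.
#' @export
draws_of <- function(fit, parameter) {
  d <- fit$draws
  v <- d$value[d$parameter == parameter]
  if (!length(v)) {
    stop("no draws for parameter '", parameter, "'; available: ",
         paste(unique(d$parameter), collapse = ", "))
  }
  v
}
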