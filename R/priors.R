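#' Specify a prior for a model parameter
#'
#' @param parameter Parameter name (e.g. `"intercept"`).
#' @param family `"normal"` for an informative normal prior, or
#'   `"default"` for the weakly-informative data-scaled default
#'   (Student-t(3, median(y), 2.5 MAD(y)) on location parameters).
#' @param location,scale Hyperparameters in kg (required for
#'   `"normal"`; `scale` must be > 0).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(parameter = "intercept",
                       family = c("normal", "default"),
                       location = NULL, scale = NULL) {
  family <- match.arg(family)
  if (family == "normal") {
    if (is.null(location) || is.null(scale)) {
      stop("normal prior requires location and scale")
    }
    if (scale <= 0) stop("prior scale must be > 0")
  }
  structure(
    list(parameter = parameter, family = family,
         location = location, scale = scale),
    class = "prior_spec"
  )
}

#' Normal prior from a reported mean and SD
#'
#' Builds the informed intercept prior used when anchoring a model to a
#' previously reported change-score summary (mean and SD in kg), e.g.
#' pilot data for the same protocol.
#'
#' @param location Mean (kg).
#' @param scale SD (kg), > 0.
#' @param parameter Parameter the prior applies to.
#' @return A [prior_spec()].
#' @export
prior_from_summary <- function(location, scale, parameter = "intercept") {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  prior_spec(parameter, "normal", location = location, scale = scale)
}

#' Chain a prior from posterior draws
#'
#' Summarizes a previous fit's posterior draws into a normal prior with
#' the draws' mean and SD, implementing sequential updating across
#' studies (e.g. the second study's intercept prior is the first study's
#' posterior for the same arm).
#'
#' @param draws Numeric vector of >= 100 posterior draws.
#' @param parameter Parameter the prior applies to.
#' @param scale_floor Minimum prior scale (kg); degenerate draw sets get
#'   this floor instead of a zero scale.
#' @return A [prior_spec()].
#' @export
prior_from_posterior <- function(draws, parameter = "intercept",
                                 scale_floor = 1e-3) {
  if (length(draws) < 100) stop("need >= 100 draws to form a prior")
  prior_spec(parameter, "normal",
             location = mean(draws),
             scale = max(sd(draws), scale_floor))
}

# Hyperparameters of the weakly-informative default priors, mirroring
# data-scaled regression defaults: Student-t(3, median(y), 2.5 MAD(y))
# on the intercept and half-t(3, 0, 2.5 MAD(y)) on the residual scale,
# with a floor of 1 kg on the scale for degenerate samples.
default_prior_scale <- function(y) max(2.5 * mad(y), 1)
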