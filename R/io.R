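# CSV / JSON interchange. All tables are UTF-8 CSV with a header row;
# masses are kg throughout.

#' Write / read an elicitation sample
#'
#' Columns: `respondent_id`, `role`, `outcome`, `value_kg`.
#' @param data Elicitation tibble.
#' @param path File path.
#' @return `read_elicitation()` returns the tibble; writers return the
#'   path invisibly.
#' @export
write_elicitation <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_elicitation
#' @export
read_elicitation <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    respondent_id = readr::col_integer(), role = readr::col_character(),
    outcome = readr::col_character(), value_kg = readr::col_double()
  ))
  if (anyNA(d$value_kg)) stop("elicited values must not be missing")
  d
}

#' Write / read an intervention dataset
#'
#' Columns: `study`, `group`, `participant_id`, `lift`, `pre_kg`,
#' `post_kg`, `change_kg`, `body_mass_kg`, `sex`, `wilks`,
#' `strength_class`. Reading validates the structural invariants via
#' [validate_cohort()].
#' @param data Cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the validated tibble.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  validate_cohort(d)
  d
}

#' Write / read a session log
#'
#' Columns: `study`, `group`, `participant_id`, `session_index`, `lift`,
#' `set_type`, `reps`, `load_kg`, `rpe`, `soreness_next_day`.
#' @param data Sessions tibble.
#' @param path File path.
#' @return `read_sessions()` returns the tibble.
#' @export
write_sessions <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write the draws of a fitted model to CSV
#'
#' Long format: `chain`, `iteration`, `parameter`, `value`.
#' @param fit A fitted model object with a `draws` tibble.
#' @param path File path.
#' @export
write_draws <- function(fit, path) {
  readr::write_csv(fit$draws, path)
  invisible(path)
}

#' Read posterior or ROPE draws from a file
#'
#' Accepts either the long `draws.csv` format written by [write_draws()]
#' (optionally filtered to one `parameter`) or a headerless/single-column
#' numeric file, so externally produced ROPE draw sets can be supplied.
#'
#' @param path File path.
#' @param parameter Parameter to select when reading a long draws file;
#'   defaults to `"a"` then the first parameter present.
#' @return Numeric vector of draws.
#' @export
read_draws <- function(path, parameter = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("parameter", "value") %in% names(d))) {
    pars <- unique(d$parameter)
    parameter <- parameter %||% if ("a" %in% pars) "a" else pars[1]
    v <- d$value[d$parameter == parameter]
    if (!length(v)) stop("parameter '", parameter, "' not found in ", path)
    return(v)
  }
  if (ncol(d) == 1L) return(as.numeric(d[[1]]))
  stop("unrecognized draws file format: ", path)
}

#' Write model diagnostics to JSON
#'
#' @param fit A fitted model object with a `diagnostics` tibble.
#' @param path File path.
#' @export
write_diagnostics <- function(fit, path) {
  jsonlite::write_json(
    setNames(
      lapply(seq_len(nrow(fit$diagnostics)), function(i) {
        list(rhat = fit$diagnostics$rhat[i], ess = fit$diagnostics$ess[i])
      }),
      fit$diagnostics$parameter
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write effect summaries to JSON
#'
#' @param summaries A single `effect_summary` or a list of them.
#' @param path File path.
#' @export
write_summary <- function(summaries, path) {
  if (inherits(summaries, "effect_summary")) summaries <- list(summaries)
  jsonlite::write_json(
    lapply(summaries, function(s) unclass(s)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
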