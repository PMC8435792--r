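#' Define a training protocol
#'
#' A protocol describes one week of training for the three competition
#' lifts: how many days per week each lift is trained, the main work
#' performed in each session (sets x reps within a target RPE band), an
#' optional back-off rule (extra sets at a fraction of the day's heaviest
#' single), and an optional AMRAP rule (a single as-many-reps-as-possible
#' set at a fixed fraction of 1RM, terminated at a stop RPE).
#'
#' @param label Character protocol name.
#' @param frequency Named integer vector of weekly training days per lift.
#'   The default 2-3-1 squat-bench-deadlift split is the conventional
#'   powerlifting frequency.
#' @param main_sets,main_reps Sets and repetitions of the main work per
#'   session. `main_reps` may be `NA` when the repetition count is
#'   autoregulated (AMRAP protocols).
#' @param main_rpe Length-2 numeric target RPE band for the main work.
#' @param backoff `NULL`, or a list with elements `sets`, `reps` and
#'   `load_fraction` (fraction of the day's heaviest single, in (0, 1]).
#' @param amrap `NULL`, or a list with elements `load_fraction` (fraction
#'   of 1RM, in (0, 1]) and `stop_rpe` (length-2 band).
#'
#' @return An object of class `protocol_spec`.
#' @export
#' @examples
#' weekly_reps(protocol_preset("MAX_BOFF"))
protocol_spec <- function(label,
                          frequency = c(SQ = 2L, BP = 3L, DL = 1L),
                          main_sets = 1L, main_reps = 1L,
                          main_rpe = c(9, 9.5),
                          backoff = NULL, amrap = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!all(LIFTS %in% names(frequency))) {
    stop("`frequency` must name all of ", paste(LIFTS, collapse = ", "))
  }
  frequency <- frequency[LIFTS]
  if (any(frequency < 0)) stop("frequencies must be >= 0")
  check_rpe_band <- function(b, what) {
    if (any(b < 1) || any(b > 10)) stop(what, " RPE band must lie in [1, 10]")
  }
  check_rpe_band(main_rpe, "main")
  if (!is.null(backoff)) {
    stopifnot(all(c("sets", "reps", "load_fraction") %in% names(backoff)))
    if (backoff$load_fraction <= 0 || backoff$load_fraction > 1) {
      stop("back-off load fraction must be in (0, 1]")
    }
  }
  if (!is.null(amrap)) {
    stopifnot(all(c("load_fraction", "stop_rpe") %in% names(amrap)))
    if (amrap$load_fraction <= 0 || amrap$load_fraction > 1) {
      stop("AMRAP load fraction must be in (0, 1]")
    }
    check_rpe_band(amrap$stop_rpe, "AMRAP stop")
  }
  structure(
    list(label = label, frequency = frequency,
         main_sets = as.integer(main_sets), main_reps = main_reps,
         main_rpe = main_rpe, backoff = backoff, amrap = amrap),
    class = "protocol_spec"
  )
}

#' Built-in protocol presets
#'
#' Three minimal-dose protocols: `"MAX"` (one autoregulated near-maximal
#' single at RPE 9-9.5 per session), `"MAX_BOFF"` (the same single plus
#' two back-off sets of three repetitions at 80% of the single), and
#' `"AMRAP"` (one as-many-reps-as-possible set at 70% 1RM terminated at
#' RPE 9-9.5). All use the 2-3-1 SQ-BP-DL weekly frequency.
#'
#' @param name One of `"MAX"`, `"MAX_BOFF"`, `"AMRAP"`.
#' @return A [protocol_spec()].
#' @export
protocol_preset <- function(name = c("MAX", "MAX_BOFF", "AMRAP")) {
  name <- match.arg(name)
  switch(name,
    MAX = protocol_spec("MAX"),
    MAX_BOFF = protocol_spec(
      "MAX_BOFF",
      backoff = list(sets = 2L, reps = 3L, load_fraction = 0.8)
    ),
    AMRAP = protocol_spec(
      "AMRAP", main_sets = 1L, main_reps = NA_real_,
      amrap = list(load_fraction = 0.7, stop_rpe = c(9, 9.5))
    )
  )
}

#' Build a protocol from a configuration list or YAML/JSON file
#'
#' @param x A preset name, a list with fields mirroring [protocol_spec()]
#'   arguments, or a path to a YAML (or JSON) file containing such a list.
#' @return A [protocol_spec()].
#' @export
protocol_from_config <- function(x) {
  if (inherits(x, "protocol_spec")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("MAX", "MAX_BOFF", "AMRAP")) return(protocol_preset(x))
    if (!file.exists(x)) stop("protocol config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x), !is.null(x$label))
  freq <- unlist(x$frequency %||% c(SQ = 2L, BP = 3L, DL = 1L))
  protocol_spec(
    label = x$label, frequency = freq,
    main_sets = x$main_sets %||% 1L, main_reps = x$main_reps %||% 1L,
    main_rpe = unlist(x$main_rpe %||% c(9, 9.5)),
    backoff = x$backoff, amrap = x$amrap
  )
}

#' Weekly repetition accounting for a protocol
#'
#' Main-work repetitions are `frequency x main_sets x main_reps`; back-off
#' repetitions are `frequency x backoff sets x backoff reps`. AMRAP
#' protocols have autoregulated repetition counts, so their main reps are
#' `NA` unless an expected reps-per-set value is supplied.
#'
#' @param protocol A [protocol_spec()].
#' @param amrap_expected_reps Optional named numeric vector (per lift) of
#'   expected repetitions per AMRAP set, used in place of `NA`.
#' @return A tibble with columns `lift`, `main_reps`, `backoff_reps`,
#'   `total_reps`.
#' @export
weekly_reps <- function(protocol, amrap_expected_reps = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"))
  reps_per_set <- rep(protocol$main_reps, length(LIFTS))
  names(reps_per_set) <- LIFTS
  if (!is.null(protocol$amrap) && !is.null(amrap_expected_reps)) {
    reps_per_set[names(amrap_expected_reps)] <- amrap_expected_reps
  }
  main <- protocol$frequency * protocol$main_sets * reps_per_set
  bo <- if (is.null(protocol$backoff)) {
    setNames(rep(0, length(LIFTS)), LIFTS)
  } else {
    protocol$frequency * protocol$backoff$sets * protocol$backoff$reps
  }
  tibble::tibble(
    lift = LIFTS,
    main_reps = as.numeric(main[LIFTS]),
    backoff_reps = as.numeric(bo[LIFTS]),
    total_reps = as.numeric(main[LIFTS] + bo[LIFTS])
  )
}

#' Relative weekly volume of one protocol versus another
#'
#' Percent difference in total weekly repetitions:
#' `100 * (total(a) - total(b)) / total(b)`.
#'
#' @param a,b [protocol_spec()] objects (`b` is the baseline).
#' @param ... Passed to [weekly_reps()] (e.g. `amrap_expected_reps`).
#' @return A single percentage.
#' @export
#' @examples
#' relative_volume(protocol_preset("MAX_BOFF"), protocol_preset("MAX")) # 600
relative_volume <- function(a, b, ...) {
  ta <- sum(weekly_reps(a, ...)$total_reps)
  tb <- sum(weekly_reps(b, ...)$total_reps)
  if (is.na(tb) || tb == 0) stop("baseline protocol has zero or undefined weekly volume")
  100 * (ta - tb) / tb
}

#' Longitudinal strength-gain extrapolation
#'
#' Linear extrapolation of a daily strength-gain rate over a horizon, used
#' to put elicited "meaningful change" values in context of the gains
#' competitive powerlifters actually accrue. Registered raw competitors
#' have been estimated to gain about 0.15 kg/day (males) and 0.12 kg/day
#' (females) of powerlifting total since their first competition;
#' [latella_rates] stores these reference rates.
#'
#' @param rate_kg_per_day Daily rate of total gain (kg/day).
#' @param days Horizon in days (365 for a year, 42 for a 6-week block).
#' @return Extrapolated gain in kg.
#' @export
#' @examples
#' extrapolate_rate(latella_rates[["female"]], 365) # 43.8 kg/year
#' extrapolate_rate(latella_rates[["male"]], 42)    # ~6.3 kg per 6 weeks
extrapolate_rate <- function(rate_kg_per_day, days) {
  stopifnot(is.numeric(rate_kg_per_day), is.numeric(days), all(days >= 0))
  rate_kg_per_day * days
}

#' Reference daily strength-gain rates (kg of powerlifting total per day)
#' for registered raw competitors, by sex.
#' @format Named numeric vector with elements `male` and `female`.
#' @export
latella_rates <- c(male = 0.15, female = 0.12)
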