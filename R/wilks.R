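#' Wilks coefficient polynomial tables
#'
#' Coefficients of the classic fifth-order Wilks body-mass polynomial
#' (Wilks, Australian Powerlifting Federation; as distributed with the
#' pre-2019 IPF scoring tables). The Wilks coefficient for a lifter of
#' body mass `x` kg is `500 / (a + b x + c x^2 + d x^3 + e x^4 + f x^5)`
#' with sex-specific coefficients; the score multiplies the lifted mass by
#' this coefficient. The table is an argument to [wilks_score()] so an
#' alternative coefficient set can be swapped in.
#'
#' @return Named list with numeric vectors `M` and `F` of polynomial
#'   coefficients (constant term first).
#' @export
wilks_coefficients <- function() {
  list(
    M = c(-216.0475144, 16.2606339, -0.002388645, -0.00113732,
          7.01863e-06, -1.291e-08),
    F = c(594.31747775582, -27.23842536447, 0.82112226871, -0.00930733913,
          4.731582e-05, -9.054e-08)
  )
}

#' Wilks score
#'
#' Body-mass-adjusted strength score: lifted mass times the sex-specific
#' Wilks coefficient of body mass. Linear in the lifted mass; a zero lift
#' scores zero points.
#'
#' @param body_mass Body mass in kg (> 0). Vectorized.
#' @param lifted Lifted mass in kg (>= 0). Vectorized.
#' @param sex `"M"` or `"F"` (recycled).
#' @param coefficients Coefficient table, by default [wilks_coefficients()].
#' @return Wilks points.
#' @export
#' @examples
#' wilks_score(90, 600, "M")
wilks_score <- function(body_mass, lifted, sex = "M",
                        coefficients = wilks_coefficients()) {
  if (any(body_mass <= 0)) stop("body_mass must be > 0")
  if (any(lifted < 0)) stop("lifted mass must be >= 0")
  sex <- rep_len(toupper(sex), max(length(body_mass), length(lifted)))
  if (!all(sex %in% names(coefficients))) {
    stop("sex must be one of: ", paste(names(coefficients), collapse = ", "))
  }
  denom <- vapply(seq_along(sex), function(i) {
    co <- coefficients[[sex[i]]]
    bm <- rep_len(body_mass, length(sex))[i]
    sum(co * bm^(seq_along(co) - 1))
  }, numeric(1))
  lifted * 500 / denom
}

#' Default strength classification bands
#'
#' Five Wilks-score bands used to stratify athletes before group
#' allocation: 300-340 is class 1, 350-400 class 2, 410-450 class 3,
#' 460-500 class 4 and 510-550 class 5.
#'
#' @return Tibble with columns `low`, `high`, `class`.
#' @export
strength_class_table <- function() {
  tibble::tibble(
    low = c(300, 350, 410, 460, 510),
    high = c(340, 400, 450, 500, 550),
    class = 1:5
  )
}

#' Assign a strength class from a Wilks score
#'
#' Scores inside a band get that band's class. The bands have gaps
#' (e.g. 341-349); a score in a gap maps to the band with the nearest
#' boundary, with ties going to the lower band. Scores below the lowest
#' band map to class 1 and above the highest band to class 5, so the
#' classification is a total, monotone non-decreasing function of the
#' Wilks score.
#'
#' @param wilks Wilks points (> 0). Vectorized.
#' @param table Band table as from [strength_class_table()].
#' @return Integer class indices.
#' @export
#' @examples
#' strength_class(c(375, 300, 345))
strength_class <- function(wilks, table = strength_class_table()) {
  if (any(wilks <= 0)) stop("wilks must be > 0")
  if (is.unsorted(table$low) || any(table$low > table$high) ||
      any(head(table$high, -1) >= table$low[-1])) {
    stop("class bands must be ascending and non-overlapping")
  }
  vapply(wilks, function(w) {
    inside <- which(w >= table$low & w <= table$high)
    if (length(inside)) return(as.integer(table$class[inside[1]]))
    if (w < table$low[1]) return(as.integer(table$class[1]))
    n <- nrow(table)
    if (w > table$high[n]) return(as.integer(table$class[n]))
    # in a gap between band i and band i + 1
    i <- max(which(table$high < w))
    d_lo <- w - table$high[i]
    d_hi <- table$low[i + 1] - w
    as.integer(if (d_lo <= d_hi) table$class[i] else table$class[i + 1])
  }, integer(1))
}

#' Quasi-randomized, strength-stratified group allocation
#'
#' Athletes are classified by Wilks score, shuffled within each strength
#' class under the given seed, and dealt in permuted blocks: athletes
#' are assigned one at a time to a randomly permuted cycle of the
#' groups, with incomplete cycles carrying over between classes. Every
#' complete cycle gives each group exactly one athlete, so overall group
#' sizes differ by at most one, classes are spread evenly across groups,
#' and the random permutation of each cycle makes the allocation
#' symmetric in expectation (no group systematically receives the
#' leftover athlete of a class). Deterministic under a seed.
#'
#' @param athletes Data frame with at least columns `participant_id` and
#'   `wilks`.
#' @param n_groups Number of groups (>= 2).
#' @param seed Integer RNG seed.
#' @param group_labels Optional character labels; default `"G1"`, ...
#' @param table Strength-class band table.
#' @return The input with added columns `strength_class` and `group`.
#' @export
quasi_randomize <- function(athletes, n_groups, seed = 1L,
                            group_labels = NULL,
                            table = strength_class_table()) {
  stopifnot(is.data.frame(athletes))
  if (nrow(athletes) == 0) stop("no athletes to allocate")
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (!all(c("participant_id", "wilks") %in% names(athletes))) {
    stop("athletes must have columns participant_id and wilks")
  }
  group_labels <- group_labels %||% paste0("G", seq_len(n_groups))
  stopifnot(length(group_labels) == n_groups)
  athletes$strength_class <- strength_class(athletes$wilks, table)
  assigned <- rep(NA_character_, nrow(athletes))
  set.seed(seed)
  cycle <- character(0)
  for (cl in sort(unique(athletes$strength_class))) {
    idx <- which(athletes$strength_class == cl)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      if (!length(cycle)) cycle <- group_labels[sample.int(n_groups)]
      assigned[i] <- cycle[1]
      cycle <- cycle[-1]
    }
  }
  athletes$group <- assigned
  athletes
}
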