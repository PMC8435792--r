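#' Configure an end-to-end pipeline run
#'
#' Assembles everything one reproducible run needs: data sources (either
#' generator configurations or paths to existing CSVs), the outcomes to
#' analyse, the ROPE source, the intercept prior, sampler settings and
#' the output directory. All randomness derives from `seed` unless a
#' component config carries its own.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer base seed.
#' @param outcomes Character vector of outcomes to analyse (subset of
#'   SQ, BP, DL, Total).
#' @param elicitation An [elicitation_config()], or a path to an
#'   elicitation CSV. Ignored when `rope_file` is given.
#' @param cohort A [cohort_config()], or a path to a cohort CSV.
#' @param rope_file Optional path to an external ROPE draw file (single
#'   column or long draws format); when given, the elicitation model is
#'   skipped and the ROPE is tagged `"external"`.
#' @param prior `NULL` or a normal [prior_spec()] for the ANCOVA
#'   intercept (the reference group's mean).
#' @param reference Reference group label for the ANCOVA.
#' @param mcmc An [mcmc_config()]; its seed is re-derived from `seed`.
#' @param run_meta Fit the pooled multilevel meta-model as well.
#' @param meta_mcmc Optional [mcmc_config()] for the meta-model; by
#'   default it retains 20,000 draws per chain (see [fit_meta()]).
#' @param meta_groups Optional character vector restricting which groups
#'   enter the meta-model (e.g. the daily-max arms).
#' @param dropout_rate Participant-level dropout applied to a generated
#'   cohort.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, outcomes = "Total",
                       elicitation = NULL, cohort = NULL,
                       rope_file = NULL, prior = NULL, reference = NULL,
                       mcmc = mcmc_config(), run_meta = FALSE,
                       meta_mcmc = NULL, meta_groups = NULL,
                       dropout_rate = 0) {
  if (!all(outcomes %in% OUTCOMES)) {
    stop("outcomes must be among: ", paste(OUTCOMES, collapse = ", "))
  }
  seed <- as.integer(seed)
  elicitation <- elicitation %||% elicitation_config(seed = seed)
  cohort <- cohort %||% cohort_config(
    list(reference_arm("study3_MAX"), reference_arm("study3_MAX_BOFF")),
    seed = seed + 1L
  )
  for (p in c(rope_file,
              if (is.character(elicitation)) elicitation,
              if (is.character(cohort)) cohort)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  mcmc$seed <- seed + 2L
  meta_mcmc <- meta_mcmc %||% mcmc_config(warmup = 2000L, sampling = 20000L)
  meta_mcmc$seed <- seed + 5L
  structure(
    list(out_dir = out_dir, seed = seed, outcomes = outcomes,
         elicitation = elicitation, cohort = cohort,
         rope_file = rope_file, prior = prior, reference = reference,
         mcmc = mcmc, run_meta = run_meta, meta_mcmc = meta_mcmc,
         meta_groups = meta_groups, dropout_rate = dropout_rate),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML or JSON file
#'
#' Top-level keys mirror the [run_config()] arguments; `prior` is given
#' as `{location, scale}` and `mcmc` as `{chains, warmup, sampling}`.
#'
#' @param path Config file path.
#' @param out_dir Optional override of the configured output directory.
#' @param seed Optional override of the configured seed.
#' @return A [run_config()].
#' @export
run_config_from_file <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  mc <- cfg$mcmc %||% list()
  run_config(
    out_dir = out_dir %||% cfg$out_dir %||% stop("config needs out_dir"),
    seed = seed %||% cfg$seed %||% 1L,
    outcomes = unlist(cfg$outcomes %||% "Total"),
    elicitation = if (is.character(cfg$elicitation)) cfg$elicitation,
    cohort = if (is.character(cfg$cohort)) cfg$cohort,
    rope_file = cfg$rope_file,
    prior = if (!is.null(cfg$prior)) {
      prior_from_summary(cfg$prior$location, cfg$prior$scale)
    },
    reference = cfg$reference,
    mcmc = mcmc_config(chains = mc$chains %||% 4L,
                       warmup = mc$warmup %||% 1000L,
                       sampling = mc$sampling %||% 1000L),
    run_meta = isTRUE(cfg$run_meta),
    meta_groups = unlist(cfg$meta_groups),
    dropout_rate = cfg$dropout_rate %||% 0
  )
}

pipeline_logger <- function(out_dir, verbose = TRUE) {
  log_file <- file.path(out_dir, "run.log")
  function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_file, append = TRUE, sep = "")
    if (verbose) message(line)
  }
}

run_stage <- function(stage, log, expr) {
  log("stage ", stage, ": start")
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> ROPE -> ANCOVA fit -> posterior
#' vs. ROPE comparison -> optional meta-model -> report. Every stage's
#' inputs, seed and diagnostics are logged to `run.log`; outputs are
#' written under the configured directory: the data CSVs, per-model
#' `*_draws.csv` and `*_diagnostics.json`, `summary.json` (one record
#' per outcome x group, each carrying provenance fields naming the
#' outcome its draws came from), `descriptives.csv`, and one
#' posterior-vs-ROPE density plot per outcome.
#'
#' @param config A [run_config()].
#' @param verbose Also log to stderr.
#' @return Invisibly, a list with the fitted objects and summaries.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- pipeline_logger(config$out_dir, verbose)
  log("run: package metdose ", as.character(utils::packageVersion("metdose")),
      ", seed ", config$seed,
      ", outcomes ", paste(config$outcomes, collapse = "/"),
      ", mcmc ", config$mcmc$chains, "x(", config$mcmc$warmup, "+",
      config$mcmc$sampling, ")")

  data <- run_stage("simulate", log, {
    elic <- NULL
    if (is.null(config$rope_file)) {
      elic <- if (is.character(config$elicitation)) {
        read_elicitation(config$elicitation)
      } else {
        generate_elicitation(config$elicitation)
      }
      write_elicitation(elic, file.path(config$out_dir, "elicitation.csv"))
    }
    sessions <- NULL
    if (is.character(config$cohort)) {
      cohort <- read_cohort(config$cohort)
    } else {
      cohort <- generate_cohort(config$cohort)
      if (config$dropout_rate > 0) {
        cohort <- apply_dropout(cohort, config$dropout_rate,
                                seed = config$seed + 3L)
        log("dropout applied at rate ", config$dropout_rate, "; ",
            length(unique(cohort$participant_id)), " participants retained")
      }
      sessions <- generate_sessions(cohort, config$cohort,
                                    seed = config$seed + 4L)
      write_sessions(sessions, file.path(config$out_dir, "sessions.csv"))
    }
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    list(elicitation = elic, cohort = cohort, sessions = sessions)
  })

  ropes <- run_stage("rope", log, {
    if (!is.null(config$rope_file)) {
      draws <- read_draws(config$rope_file)
      log("external ROPE: ", length(draws), " draws from ", config$rope_file)
      setNames(
        lapply(config$outcomes, function(o) rope_distribution(draws, "external")),
        config$outcomes
      )
    } else {
      setNames(lapply(config$outcomes, function(o) {
        vals <- data$elicitation$value_kg[data$elicitation$outcome == o]
        fit <- fit_intercept_model(vals, mcmc = config$mcmc)
        write_draws(fit, file.path(config$out_dir,
                                   paste0("rope_", o, "_draws.csv")))
        write_diagnostics(fit, file.path(config$out_dir,
                                         paste0("rope_", o, "_diagnostics.json")))
        log("ROPE[", o, "]: n=", fit$n, ", max rhat ",
            round(max(fit$diagnostics$rhat), 4), ", min ess ",
            round(min(fit$diagnostics$ess)))
        as_rope(fit)
      }), config$outcomes)
    }
  })

  fits <- run_stage("fit", log, {
    setNames(lapply(config$outcomes, function(o) {
      fit <- fit_ancova(data$cohort, outcome = o,
                        reference = config$reference,
                        prior = config$prior, mcmc = config$mcmc)
      write_draws(fit, file.path(config$out_dir,
                                 paste0("ancova_", o, "_draws.csv")))
      write_diagnostics(fit, file.path(config$out_dir,
                                       paste0("ancova_", o, "_diagnostics.json")))
      log("ANCOVA[", o, "]: n=", fit$n, ", reference ", fit$reference,
          ", max rhat ", round(max(fit$diagnostics$rhat), 4),
          ", min ess ", round(min(fit$diagnostics$ess)))
      fit
    }), config$outcomes)
  })

  summaries <- run_stage("compare", log, {
    out <- list()
    for (o in config$outcomes) {
      for (g in fits[[o]]$groups) {
        s <- summarize_effect(emm_draws(fits[[o]])[[g]], ropes[[o]],
                              label = paste0(o, ":", g))
        rec <- c(list(outcome = o, group = g, draws_from = paste0("emm_", g)),
                 unclass(s))
        out[[paste0(o, ":", g)]] <- rec
        log("summary ", o, ":", g, ": mode ", round(s$mode, 1),
            " kg, HDI [", round(s$hdi_low, 1), ", ", round(s$hdi_high, 1),
            "], AUC ", round(s$auc_vs_rope, 3),
            ", overlap ", round(s$overlap_vs_rope, 3))
      }
    }
    jsonlite::write_json(out, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  meta <- NULL
  if (config$run_meta) {
    meta <- run_stage("meta", log, {
      d <- data$cohort
      if (!is.null(config$meta_groups)) {
        d <- d[d$group %in% config$meta_groups, ]
      }
      out <- list()
      for (o in config$outcomes) {
        fit <- fit_meta(d, outcome = o, mcmc = config$meta_mcmc)
        write_draws(fit, file.path(config$out_dir,
                                   paste0("meta_", o, "_draws.csv")))
        s <- summarize_effect(draws_of(fit, "b0"), ropes[[o]],
                              label = paste0(o, ":overall"))
        out[[o]] <- list(fit = fit,
                         summary = c(list(outcome = o), unclass(s)))
        log("meta[", o, "]: overall mode ", round(s$mode, 1), " kg")
      }
      jsonlite::write_json(
        lapply(out, `[[`, "summary"),
        file.path(config$out_dir, "meta_summary.json"),
        auto_unbox = TRUE, digits = NA
      )
      out
    })
  }

  run_stage("report", log, {
    if (!is.null(data$sessions)) {
      readr::write_csv(descriptives(data$sessions),
                       file.path(config$out_dir, "descriptives.csv"))
    }
    for (o in config$outcomes) {
      p <- plot_effect_vs_rope(emm_draws(fits[[o]]), ropes[[o]], outcome = o)
      ggplot2::ggsave(
        file.path(config$out_dir, paste0("effects_", o, ".pdf")),
        p, width = 7, height = 4.5
      )
    }
    log("report written to ", config$out_dir)
  })

  invisible(list(data = data, ropes = ropes, fits = fits,
                 summaries = summaries, meta = meta))
}

#' Descriptive training characteristics from a session log
#'
#' Mean and SD per group, lift and set type of the logged RPE, plus
#' next-day soreness and (for autoregulated AMRAP work) repetitions per
#' set — the per-protocol training summary conventionally reported next
#' to the outcome analysis.
#'
#' @param sessions Session log tibble (see [generate_sessions()]).
#' @return Tibble with columns `group`, `lift`, `set_type`, `rpe_mean`,
#'   `rpe_sd`, `reps_mean`, `reps_sd`, `soreness_mean`, `soreness_sd`.
#' @export
descriptives <- function(sessions) {
  need <- c("group", "lift", "set_type", "reps", "rpe", "soreness_next_day")
  missing <- setdiff(need, names(sessions))
  if (length(missing)) {
    stop("session log is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!nrow(sessions)) stop("session log is empty")
  dplyr::summarise(
    dplyr::group_by(sessions, .data$group, .data$lift, .data$set_type),
    rpe_mean = mean(.data$rpe), rpe_sd = sd(.data$rpe),
    reps_mean = mean(.data$reps), reps_sd = sd(.data$reps),
    soreness_mean = mean(.data$soreness_next_day),
    soreness_sd = sd(.data$soreness_next_day),
    .groups = "drop"
  )
}

#' Posterior-vs-ROPE density plot
#'
#' Overlays the per-group posterior effect densities with the ROPE
#' density and annotates each group with its AUC probability of
#' exceeding the ROPE.
#'
#' @param effects Named list of per-group effect draw vectors.
#' @param rope A [rope_distribution()].
#' @param outcome Outcome label for the title.
#' @return A ggplot object.
#' @export
plot_effect_vs_rope <- function(effects, rope, outcome = "Total") {
  stopifnot(is.list(effects), inherits(rope, "rope_distribution"))
  aucs <- vapply(effects, function(d) auc_superiority(d, rope$draws),
                 numeric(1))
  labs <- sprintf("%s (AUC %.1f%%)", names(effects), 100 * aucs)
  df <- dplyr::bind_rows(
    tibble::tibble(set = "ROPE", value = rope$draws),
    dplyr::bind_rows(lapply(seq_along(effects), function(i) {
      tibble::tibble(set = labs[i], value = effects[[i]])
    }))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$set,
                                   colour = .data$set)) +
    ggplot2::geom_density(alpha = 0.35) +
    ggplot2::labs(
      title = paste0(outcome, ": posterior change vs. ROPE"),
      x = "change score (kg)", y = "density",
      fill = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}
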