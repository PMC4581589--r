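# Orchestration: cohort IO, analysis configuration, end-to-end runs and
# tabular reports.

#' Write / read a person-period cohort as CSV
#'
#' One row per person-interval with a documented header; logical columns
#' are stored as 0/1.
#'
#' @param cohort person-period `data.table`.
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort keyed by person and
#'   interval.
#' @export
write_cohort_csv <- function(cohort, path) {
  data.table::fwrite(data.table::as.data.table(cohort), path,
                     logical01 = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  dt <- data.table::fread(path)
  logicals <- c("bmi_low", "hb_low", "who4_wk24_48", "cotrim_prev",
                "on_first_line", "switched", "cd4_measured",
                "ev_who3", "ev_cand", "ev_who4", "ev_tbp", "ev_tbe",
                "miss_visits", "miss_doses", "death", "ltfu")
  for (cn in intersect(logicals, names(dt))) {
    data.table::set(dt, j = cn, value = as.logical(dt[[cn]]))
  }
  ints <- c("switch_day", "substudy_entry", "cd4_obs", "cd4_true",
            grep("_day$", names(dt), value = TRUE))
  for (cn in intersect(ints, names(dt))) {
    data.table::set(dt, j = cn, value = as.integer(dt[[cn]]))
  }
  data.table::setkey(dt, person_id, k)
  dt[]
}

#' Fixture cohort for examples and tests
#'
#' A small synthetic cohort (default 200 persons, 30 intervals) generated
#' deterministically from a fixed seed; used throughout the test suite.
#'
#' @param n_individuals,n_intervals cohort dimensions.
#' @param seed fixed seed.
#' @return person-period `data.table`.
#' @export
fixture_cohort <- function(n_individuals = 200L, n_intervals = 30L,
                           seed = 424242L) {
  generate_cohort(sim_config(n_individuals = n_individuals,
                             n_intervals = n_intervals, seed = seed))
}

#' Standard strategy sets
#'
#' Convenience constructors for the strategy families analysed in the
#' workflow: CD4-threshold switching strategies under 12-weekly
#' monitoring, event-only strategies, and CD4-monitoring-frequency
#' variants of a fixed switching rule.
#'
#' @param thresholds CD4 thresholds in cells/mm3.
#' @param max_week largest monitoring week to schedule.
#' @return list of [strategy()] objects.
#' @export
cd4_switch_strategies <- function(thresholds = seq(100, 10, by = -10),
                                  max_week = 960) {
  lapply(thresholds, function(x)
    strategy(paste0("cd4_lt", x), cd4_threshold = x,
             event_triggers = "who4",
             monitoring_weeks = seq(0, max_week, by = 12)))
}

#' @rdname cd4_switch_strategies
#' @export
event_only_strategies <- function(max_week = 960) {
  wk <- seq(0, max_week, by = 12)
  list(strategy("who4_only", event_triggers = "who4",
                monitoring_weeks = wk),
       strategy("two_who3_or_who4",
                event_triggers = c("who4", "two_who3"),
                monitoring_weeks = wk))
}

#' @rdname cd4_switch_strategies
#' @param threshold CD4 threshold of the fixed switching rule.
#' @export
monitoring_strategies <- function(threshold = 100, max_week = 960) {
  scheds <- list(mon_12wk = seq(0, max_week, by = 12),
                 mon_24wk = seq(0, max_week, by = 24),
                 mon_48wk = seq(0, max_week, by = 48),
                 mon_96wk = seq(0, max_week, by = 96),
                 mon_baseline_only = 0,
                 mon_none = numeric(0))
  lapply(names(scheds), function(nm)
    strategy(nm, cd4_threshold = threshold, event_triggers = "who4",
             monitoring_weeks = scheds[[nm]]))
}

#' Analysis configuration
#'
#' Bundles everything [run_pipeline()] needs: a cohort source (a
#' [sim_config()] or a CSV path), a strategy list, the outcome-model
#' encoding, weight truncation, bootstrap size and seed, the survival
#' horizon, and an output directory.
#'
#' @param cohort a `sim_config` or a path to a cohort CSV.
#' @param strategies list of [strategy()] objects.
#' @param encoding `"hg"`, `"f"`, or `"none"`.
#' @param horizon survival horizon in intervals (`NULL`: 60 or the
#'   observed range).
#' @param bootstrap_B bootstrap replicates (0 = point estimates only).
#' @param seed bootstrap seed.
#' @param cap weight truncation point (`Inf` = raw weights).
#' @param outcome `"death"` or `"death_or_ltfu"`.
#' @param out_dir output directory (`NULL` = write nothing).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(cohort, strategies, encoding = "hg",
                            horizon = NULL, bootstrap_B = 0L, seed = 1L,
                            cap = 10, outcome = "death", out_dir = NULL) {
  ids <- vapply(strategies, function(s) s$strategy_id, character(1))
  if (anyDuplicated(ids)) stop("strategy ids must be unique", call. = FALSE)
  if (bootstrap_B < 0) stop("bootstrap_B must be >= 0", call. = FALSE)
  structure(list(cohort = cohort, strategies = strategies,
                 encoding = encoding, horizon = horizon,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), cap = cap, outcome = outcome,
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' simulate/load -> fit switch and LTFU models -> expand clones -> weight
#' -> fit outcome model -> predict survival -> bootstrap -> report.
#' Deterministic given the config seeds. When `out_dir` is set, writes
#' per-strategy survival curves (CSV), model coefficients and weight
#' diagnostics (JSON), the compliance report (CSV) and a run log with
#' package version and seeds.
#'
#' @param config an [analysis_config()].
#' @return list with the cohort, the `msm_estimate`, and the report table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- if (inherits(config$cohort, "sim_config")) {
    generate_cohort(config$cohort)
  } else {
    read_cohort_csv(config$cohort)
  }
  est <- estimate_survival(cohort, config$strategies,
                           encoding = config$encoding,
                           horizon = config$horizon,
                           B = config$bootstrap_B, seed = config$seed,
                           cap = config$cap, outcome = config$outcome)
  report <- write_report(est)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    surv <- data.table::rbindlist(lapply(est$curves, function(cv) {
      data.table::data.table(strategy_id = cv$strategy_id,
                             k = seq_along(cv$S) - 1L,
                             week = 4 * (seq_along(cv$S) - 1L),
                             S = cv$S,
                             lower = if (is.null(cv$lower)) NA_real_ else cv$lower,
                             upper = if (is.null(cv$upper)) NA_real_ else cv$upper)
    }))
    data.table::fwrite(surv, file.path(config$out_dir, "survival_curves.csv"))
    data.table::fwrite(report, file.path(config$out_dir, "report.csv"))
    jsonlite::write_json(
      list(switch_coef = as.list(est$switch_coef),
           outcome_coef = as.list(est$outcome_coef),
           weight_diagnostics = est$weight_diagnostics,
           n_failed_replicates = est$n_failed_replicates),
      file.path(config$out_dir, "model_fits.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(c(paste("dynmsm version:",
                       as.character(utils::packageVersion("dynmsm"))),
                 paste("R version:", R.version.string),
                 paste("bootstrap seed:", config$seed),
                 paste("bootstrap B:", config$bootstrap_B),
                 paste("weight cap:", config$cap),
                 paste("run time:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
               file.path(config$out_dir, "run_log.txt"))
  }
  list(cohort = cohort, estimate = est, report = report)
}

#' Tabular strategy report
#'
#' One row per strategy: persons eligible to switch, switched within the
#' grace period (count and percentage), compatible deaths, and survival
#' (with bootstrap CI when available) at 192 and 240 weeks or at the
#' estimation horizon when shorter.
#'
#' @param est an `msm_estimate`.
#' @return `data.table`.
#' @export
write_report <- function(est) {
  hz <- est$horizon
  ks <- unique(pmin(c(48L, 60L), hz))
  rows <- lapply(est$curves, function(cv) {
    comp <- est$compliance[est$compliance$strategy_id == cv$strategy_id]
    out <- data.table::data.table(
      strategy_id = cv$strategy_id,
      n_eligible = comp$n_eligible,
      n_switched_in_grace = comp$n_switched_in_grace,
      pct_switched_in_grace = round(comp$pct_switched_in_grace, 1),
      n_deaths_compatible = comp$n_deaths_compatible)
    for (K in ks) {
      out[[sprintf("S_%dwk", 4 * K)]] <- cv$S[K + 1L]
      if (!is.null(cv$lower)) {
        out[[sprintf("S_%dwk_lo", 4 * K)]] <- cv$lower[K + 1L]
        out[[sprintf("S_%dwk_hi", 4 * K)]] <- cv$upper[K + 1L]
      }
    }
    out
  })
  data.table::rbindlist(rows, fill = TRUE)
}

#' Write / read an analysis or simulation configuration as YAML
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @export
write_sim_config_yaml <- function(config, path) {
  y <- unclass(config)
  # yaml drops names on atomic vectors; keep the arm labels as a map
  y$arm_fractions <- as.list(config$arm_fractions)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  y$arm_fractions <- unlist(y$arm_fractions)
  if (is.null(names(y$arm_fractions))) {
    names(y$arm_fractions) <- c("LCM", "CDM")
  }
  y$event_hazards <- lapply(y$event_hazards, unlist)
  do.call(sim_config, y)
}
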