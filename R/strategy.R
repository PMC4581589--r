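#' Define a switching strategy
#'
#' A strategy couples a switching rule (a CD4 threshold and/or WHO clinical
#' event triggers, with an optional CD4 tie-breaker on event triggers), a
#' CD4-monitoring schedule that determines which 12-weekly measurements the
#' strategy is allowed to see, and a grace period. Under strategy `X` a
#' person becomes eligible to switch (interval `Q_x`) in the first 4-week
#' interval after an observed-under-schedule CD4 count drops below the
#' threshold, or in the same interval as a qualifying WHO event provided the
#' event occurred strictly before any switch and the last prior
#' schedule-observed CD4 was below the tie-breaker (vacuously satisfied when
#' no CD4 has been observed). Switching within the grace period
#' (`Q_x, ..., Q_x + grace_intervals - 1`) is compliant.
#'
#' @param strategy_id unique label.
#' @param cd4_threshold switch-triggering CD4 threshold in cells/mm3
#'   (`NA` for event-only strategies); must lie in (0, 250).
#' @param event_triggers character subset of `"who4"` (first non-Candida
#'   WHO4 event; includes extrapulmonary TB unless excluded by variant) and
#'   `"two_who3"` (second WHO3-level event: WHO3, esophageal candidiasis or
#'   pulmonary TB).
#' @param tiebreaker_cd4 CD4 tie-breaker in cells/mm3 applied to event
#'   triggers (default 250), or `NA` for none.
#' @param monitoring_weeks week offsets (multiples of 12, aligned to the
#'   12-weekly measurement grid) at which the strategy observes CD4;
#'   `numeric(0)` for no CD4 monitoring.
#' @param grace_intervals length of the grace period in 4-week intervals
#'   (default 3, i.e. `m = 2` intervals beyond the first).
#' @param exclude_extrapulmonary_tb drop extrapulmonary TB from the WHO4
#'   trigger (sensitivity variant).
#' @param who4_ignore_cd4_restriction ignore the CD4 tie-breaker on event
#'   triggers (sensitivity variant).
#' @param lag_events_4wk shift event-trigger eligibility one interval later
#'   (sensitivity variant).
#' @return an object of class `strategy`.
#' @export
strategy <- function(strategy_id,
                     cd4_threshold = NA_real_,
                     event_triggers = "who4",
                     tiebreaker_cd4 = 250,
                     monitoring_weeks = seq(0, 960, by = 12),
                     grace_intervals = 3L,
                     exclude_extrapulmonary_tb = FALSE,
                     who4_ignore_cd4_restriction = FALSE,
                     lag_events_4wk = FALSE) {
  if (length(event_triggers) &&
      !all(event_triggers %in% c("who4", "two_who3"))) {
    stop("event_triggers must be a subset of {'who4', 'two_who3'}",
         call. = FALSE)
  }
  if (!is.na(cd4_threshold) &&
      (cd4_threshold <= 0 || cd4_threshold >= 250)) {
    stop("cd4_threshold must lie in (0, 250)", call. = FALSE)
  }
  if (grace_intervals < 1L) stop("grace_intervals must be >= 1", call. = FALSE)
  monitoring_weeks <- sort(unique(as.numeric(monitoring_weeks)))
  if (length(monitoring_weeks) && any(monitoring_weeks %% 4 != 0)) {
    stop("monitoring_weeks must be multiples of 4 weeks", call. = FALSE)
  }
  structure(list(strategy_id = strategy_id,
                 cd4_threshold = as.numeric(cd4_threshold),
                 event_triggers = as.character(event_triggers),
                 tiebreaker_cd4 = as.numeric(tiebreaker_cd4),
                 monitoring_weeks = monitoring_weeks,
                 grace_intervals = as.integer(grace_intervals),
                 exclude_extrapulmonary_tb = isTRUE(exclude_extrapulmonary_tb),
                 who4_ignore_cd4_restriction = isTRUE(who4_ignore_cd4_restriction),
                 lag_events_4wk = isTRUE(lag_events_4wk)),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cd4 <- if (is.na(x$cd4_threshold)) "none" else
    paste0("CD4<", x$cd4_threshold)
  mon <- if (!length(x$monitoring_weeks)) "none" else if
  (length(x$monitoring_weeks) > 4) {
    paste0("weeks ", paste(x$monitoring_weeks[1:3], collapse = ","),
           ",... (", length(x$monitoring_weeks), " visits)")
  } else paste("weeks", paste(x$monitoring_weeks, collapse = ","))
  cat("<strategy>", x$strategy_id, "\n")
  cat("  trigger:", cd4,
      if (length(x$event_triggers)) paste("+", paste(x$event_triggers,
                                                     collapse = "+")),
      " tie-breaker:",
      if (is.na(x$tiebreaker_cd4)) "none" else x$tiebreaker_cd4, "\n")
  cat("  monitoring:", mon, " grace:", x$grace_intervals, "intervals\n")
  invisible(x)
}

# schedule weeks -> measurement interval indices; errors if a week is off
# the 12-weekly measurement grid
schedule_intervals <- function(strat) {
  wk <- strat$monitoring_weeks
  if (!length(wk)) return(integer(0))
  if (any(wk %% 12 != 0)) {
    stop("monitoring schedule weeks must align with the 12-weekly ",
         "CD4 measurement grid", call. = FALSE)
  }
  as.integer(wk %/% 4)
}

#' CD4 series observed under a monitoring schedule
#'
#' Restricts a person's measured 12-weekly CD4 series to the measurements a
#' strategy's monitoring schedule retains.
#'
#' @param person_history person-period rows for one person (with
#'   `cd4_measured`, `cd4_obs`, `k`).
#' @param monitoring_weeks schedule week offsets (or a [strategy()]).
#' @return `data.table` with columns `k` and `cd4_obs`.
#' @export
observed_cd4_series <- function(person_history, monitoring_weeks) {
  if (inherits(monitoring_weeks, "strategy")) {
    sched <- schedule_intervals(monitoring_weeks)
  } else {
    sched <- schedule_intervals(list(monitoring_weeks =
                                       sort(unique(as.numeric(monitoring_weeks)))))
  }
  h <- data.table::as.data.table(person_history)
  out <- h[h$cd4_measured & h$k %in% sched, c("k", "cd4_obs")]
  data.table::setnames(out, c("k", "cd4_obs"))
  out[]
}

# Vectorized eligibility + artificial censoring for one strategy over a
# whole cohort. Returns one row per person: Q (NA if never eligible),
# reason, switch interval, censor interval (Inf if never censored).
strategy_eligibility <- function(cohort, strat) {
  k <- person_id <- cd4_measured <- cd4_obs <- NULL # R CMD check appeasement
  m <- strat$grace_intervals - 1L
  sched <- schedule_intervals(strat)
  lag <- if (strat$lag_events_4wk) 1L else 0L

  dt <- cohort[, c("person_id", "k", "cd4_measured", "cd4_obs",
                   "ev_who3", "ev_who3_day", "ev_cand", "ev_cand_day",
                   "ev_who4", "ev_who4_day", "ev_tbp", "ev_tbp_day",
                   "ev_tbe", "ev_tbe_day", "switched", "switch_day")]
  data.table::setkey(dt, person_id, k)

  sched_row <- dt$cd4_measured & dt$k %in% sched
  obs <- ifelse(sched_row, dt$cd4_obs, NA_real_)
  # last schedule-observed CD4 up to and including interval k (measurement
  # is taken at the start of the interval, before any event or switch)
  last_obs <- locf_by(obs, dt$person_id)

  # CD4 trigger: first schedule-observed CD4 below threshold -> next interval
  empty_q <- function(col) {
    out <- data.table::data.table(person_id = integer(0), q = integer(0))
    data.table::setnames(out, c("person_id", col))
    out
  }
  if (!is.na(strat$cd4_threshold)) {
    hit <- sched_row & !is.na(obs) & obs < strat$cd4_threshold
    q_cd4_tab <- if (any(hit)) {
      dt[hit, list(q_cd4 = min(k) + 1L), by = "person_id"]
    } else empty_q("q_cd4")
  } else {
    q_cd4_tab <- data.table::data.table(person_id = integer(0),
                                        q_cd4 = integer(0))
  }

  # event triggers: tie-breaker on last prior schedule-observed CD4
  # (vacuously satisfied when none observed), event strictly before any
  # same-interval switch
  tie_ok <- if (strat$who4_ignore_cd4_restriction || is.na(strat$tiebreaker_cd4)) {
    rep(TRUE, nrow(dt))
  } else is.na(last_obs) | last_obs < strat$tiebreaker_cd4
  before_switch <- function(flag, day) {
    flag & (is.na(dt$switch_day) | (!is.na(day) & day < dt$switch_day))
  }
  q_ev_tab <- data.table::data.table(person_id = integer(0),
                                     q_ev = integer(0))
  if ("who4" %in% strat$event_triggers) {
    w4 <- before_switch(dt$ev_who4, dt$ev_who4_day) |
      (!strat$exclude_extrapulmonary_tb &
         before_switch(dt$ev_tbe, dt$ev_tbe_day))
    hit4 <- w4 & tie_ok
    q_ev_tab <- if (any(hit4)) {
      dt[hit4, list(q_ev = min(k) + lag), by = "person_id"]
    } else empty_q("q_ev")
  }
  if ("two_who3" %in% strat$event_triggers) {
    w3n <- before_switch(dt$ev_who3, dt$ev_who3_day) +
      before_switch(dt$ev_cand, dt$ev_cand_day) +
      before_switch(dt$ev_tbp, dt$ev_tbp_day)
    cum3 <- ave_cumsum(w3n, dt$person_id)
    hit3 <- cum3 >= 2L & w3n > 0L & tie_ok
    q3 <- if (any(hit3)) {
      dt[hit3, list(q_ev3 = min(k) + lag), by = "person_id"]
    } else empty_q("q_ev3")
    q_ev_tab <- merge(q_ev_tab, q3, by = "person_id", all = TRUE)
    q_ev_tab$q_ev <- pmin(q_ev_tab$q_ev, q_ev_tab$q_ev3, na.rm = TRUE)
    q_ev_tab$q_ev3 <- NULL
  }

  sw_tab <- if (any(dt$switched)) {
    dt[dt$switched, list(switch_k = min(k)), by = "person_id"]
  } else empty_q("switch_k")
  per <- data.table::data.table(person_id = unique(dt$person_id))
  per <- Reduce(function(a, b) merge(a, b, by = "person_id", all.x = TRUE),
                list(per, q_cd4_tab, q_ev_tab, sw_tab))
  if (!"q_cd4" %in% names(per)) per$q_cd4 <- NA_integer_
  if (!"q_ev" %in% names(per)) per$q_ev <- NA_integer_
  if (!"switch_k" %in% names(per)) per$switch_k <- NA_integer_

  Q <- pmin(per$q_cd4, per$q_ev, na.rm = TRUE)
  Q[is.na(per$q_cd4) & is.na(per$q_ev)] <- NA_integer_
  reason <- rep(NA_character_, nrow(per))
  reason[!is.na(per$q_ev) & (is.na(per$q_cd4) | per$q_ev <= per$q_cd4)] <- "event"
  reason[!is.na(per$q_cd4) & (is.na(per$q_ev) | per$q_cd4 < per$q_ev)] <- "cd4"

  sk <- per$switch_k
  cens <- rep(Inf, nrow(per))
  # pre-eligibility switch (or switch with no eligibility): censor at switch
  pre <- !is.na(sk) & (is.na(Q) | sk < Q)
  cens[pre] <- sk[pre]
  # failure to switch by end of grace: censor at entry to Q + m + 1
  late <- !is.na(Q) & (is.na(sk) | sk > Q + m)
  cens[late] <- pmin(cens[late], Q[late] + m + 1L)
  # a switch after the grace period is preceded by grace-expiry censoring,
  # so the switch itself never censors; switch within grace: never censored

  data.table::data.table(person_id = per$person_id,
                         strategy_id = strat$strategy_id,
                         Q = Q, reason = reason, switch_k = sk,
                         censor_from = cens)
}

#' Eligibility interval under a strategy
#'
#' First interval in which one person is eligible to switch under a
#' strategy (`Q_x`), with the triggering reason.
#'
#' @param person_history person-period rows for one person.
#' @param strat a [strategy()].
#' @return list with `Q` (interval index or `NA`) and `reason`
#'   (`"cd4"`, `"event"`, or `NA`).
#' @export
eligibility_interval <- function(person_history, strat) {
  dt <- data.table::as.data.table(person_history)
  data.table::setkey(dt, person_id, k)
  res <- strategy_eligibility(dt, strat)
  list(Q = if (is.na(res$Q[1L])) NA_integer_ else as.integer(res$Q[1L]),
       reason = res$reason[1L])
}

#' Artificial censoring time under a strategy
#'
#' Interval from which one person's data become incompatible with a
#' strategy: the interval of a pre-eligibility switch, or the first interval
#' after the grace period when no switch occurred, or `NA` when follow-up
#' stays compatible.
#'
#' @inheritParams eligibility_interval
#' @return integer interval index or `NA`.
#' @export
censor_time <- function(person_history, strat) {
  dt <- data.table::as.data.table(person_history)
  data.table::setkey(dt, person_id, k)
  res <- strategy_eligibility(dt, strat)
  cens <- res$censor_from[1L]
  # death/LTFU (or administrative end) before the censoring point: the
  # person's follow-up ends naturally and is never artificially censored
  if (is.infinite(cens) || cens > max(dt$k)) NA_integer_ else
    as.integer(cens)
}

#' Expand a cohort into per-strategy clones
#'
#' Creates one clone of each person's person-period data per strategy,
#' annotated with the eligibility interval `Q`, grace offset `r`, the
#' artificial-censoring indicator `Cx` (monotone: once 1, always 1) and the
#' interval censoring starts from.
#'
#' @param cohort person-period `data.table` from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param strategies list of [strategy()] objects with unique ids.
#' @return `data.table` of clone-interval rows.
#' @export
expand_clones <- function(cohort, strategies) {
  if (inherits(strategies, "strategy")) strategies <- list(strategies)
  ids <- vapply(strategies, function(s) s$strategy_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate strategy_id in strategy list", call. = FALSE)
  }
  cohort <- data.table::as.data.table(cohort)
  data.table::setkey(cohort, person_id, k)
  out <- lapply(strategies, function(strat) {
    el <- strategy_eligibility(cohort, strat)
    cl <- merge(cohort, el[, c("person_id", "Q", "switch_k", "censor_from")],
                by = "person_id")
    cl[, c("strategy_id", "Cx", "r") := list(
      strat$strategy_id,
      as.integer(cl$k >= cl$censor_from),
      {
        r <- cl$k - cl$Q
        r[is.na(r) | r < 0L | r > strat$grace_intervals - 1L] <- NA_integer_
        as.integer(r)
      })]
    cl
  })
  res <- data.table::rbindlist(out)
  data.table::setkey(res, strategy_id, person_id, k)
  res[]
}

# last-observation-carried-forward within person groups (groups must be
# contiguous, as in the sorted cohort); values never leak across groups
locf_by <- function(x, group) {
  first <- !duplicated(group)
  last_val_idx <- cummax(ifelse(!is.na(x), seq_along(x), 0L))
  start_idx <- cummax(ifelse(first, seq_along(x), 0L))
  out <- rep(NA, length(x))
  mode(out) <- mode(x)
  ok <- last_val_idx >= start_idx
  out[ok] <- x[last_val_idx[ok]]
  out
}

# cumulative sum within contiguous groups
ave_cumsum <- function(x, group) {
  cs <- cumsum(x)
  first <- !duplicated(group)
  base <- cs - x
  offset <- base[first][cumsum(first)]
  cs - offset
}
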