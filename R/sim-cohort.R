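# Synthetic cohort generation: natural-behavior mode (observational cohort)
# and forced-regime mode (counterfactual ground truth) share the same latent
# mechanism; only the switching rule differs.

expit <- function(x) stats::plogis(x)

# low-CD4 score used by all hazards: 0 above 100 cells/mm3, rising as the
# square root of CD4 falls below 10
low_cd4_score <- function(s) pmax(0, 10 - s)

.event_types <- c("who3", "esoph_candida", "who4_noncandida",
                  "tb_pulmonary", "tb_extrapulmonary")

.draw_events <- function(cfg, s) {
  n <- length(s)
  lc <- low_cd4_score(s)
  out <- matrix(FALSE, n, 5L, dimnames = list(NULL, .event_types))
  for (ev in .event_types) {
    p <- cfg$event_hazards[[ev]]
    out[, ev] <- stats::runif(n) < expit(p[1L] + p[2L] * lc)
  }
  out
}

.death_prob <- function(cfg, s, who4_recent, line) {
  d <- cfg$death_hazard
  expit(d$intercept + d$cd4_slope * low_cd4_score(s) +
          d$who4_recent * who4_recent + d$secondline * (line == 2L))
}

.measure_cd4 <- function(cfg, s) {
  dyn <- cfg$cd4_dynamics
  round(pmax(s + stats::rnorm(length(s), 0, dyn$meas_sd), dyn$sqrt_floor)^2)
}

.latent_step <- function(cfg, s, failing, line) {
  dyn <- cfg$cd4_dynamics
  drift <- ifelse(failing & line == 1L, dyn$drift_failing,
                  ifelse(failing & line == 2L, dyn$drift_secondline,
                         dyn$drift_stable))
  pmin(pmax(s + drift + stats::rnorm(length(s), 0, dyn$noise_sd),
            dyn$sqrt_floor), dyn$sqrt_cap)
}

.draw_baseline <- function(cfg, n) {
  bc <- cfg$baseline_covariates
  s <- pmax(stats::rnorm(n, cfg$baseline_cd4$sqrt_mean,
                         cfg$baseline_cd4$sqrt_sd),
            cfg$cd4_dynamics$sqrt_floor)
  list(
    s = s,
    failing = stats::runif(n) < cfg$failure_fraction,
    arm = ifelse(stats::runif(n) < cfg$arm_fractions[["LCM"]], "LCM", "CDM"),
    center = sample.int(length(bc$center_probs), n, replace = TRUE,
                        prob = bc$center_probs),
    regimen = sample.int(length(bc$regimen_probs), n, replace = TRUE,
                         prob = bc$regimen_probs),
    bmi_low = stats::runif(n) < bc$bmi_low_prob,
    hb_low = stats::runif(n) < bc$hb_low_prob,
    who4_wk24_48 = stats::runif(n) < bc$who4_wk24_48_prob,
    cotrim = stats::runif(n) < bc$cotrim_prob
  )
}

#' Generate a synthetic person-period cohort
#'
#' Simulates a two-arm (laboratory-plus-clinical vs clinically driven
#' monitoring) cohort in 4-weekly person-period form.
#' Interval 0 is the baseline visit (CD4 measured, no events or deaths);
#' CD4 is measured every 12 weeks (intervals 0, 3, 6, ...). LCM clinicians
#' switch predominantly in response to low observed CD4 counts; CDM
#' clinicians never see CD4 results and switch only after clinical events.
#' Rows stop at death, loss to follow-up, or administrative end of
#' follow-up. Generation is bit-reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `data.table` with one row per person-interval; columns include
#'   identifiers (`person_id`, `arm`, `k`), baseline covariates, latent and
#'   observed CD4 (`cd4_true`, `cd4_measured`, `cd4_obs`), treatment-line
#'   state (`on_first_line`, `switched`, `switch_day`), WHO 3/4 event
#'   indicators with within-interval days, `death`, `ltfu`, and substudy
#'   state (`substudy`, `substudy_entry`, `stratum`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_individuals
  K <- cfg$n_intervals
  set.seed(cfg$seed)

  bl <- .draw_baseline(cfg, n)
  s <- bl$s
  cd4_obs0 <- .measure_cd4(cfg, s)
  base_cd4_cat <- cut(cd4_obs0, c(-Inf, 99.5, 199.5, Inf),
                      labels = c("<100", "100-199", ">=200"))
  miss <- cfg$missingness
  sb <- cfg$switch_behavior

  # per-person state
  active <- rep(TRUE, n)
  line <- rep(1L, n)
  switch_k <- rep(NA_integer_, n)
  last_obs <- cd4_obs0
  w4_prev1 <- w4_prev2 <- rep(FALSE, n)   # WHO4-level events, lags 1 and 2
  w3_prev1 <- w3_prev2 <- rep(FALSE, n)
  substudy <- rep("none", n)
  substudy_entry <- rep(NA_integer_, n)

  rows <- vector("list", K)
  blank_day <- rep(NA_integer_, n)
  rows[[1L]] <- data.table::data.table(
    person_id = seq_len(n), k = 0L,
    on_first_line = TRUE, switched = FALSE, switch_day = blank_day,
    cd4_measured = TRUE, cd4_obs = cd4_obs0, cd4_true = round(s^2),
    ev_who3 = FALSE, ev_who3_day = blank_day,
    ev_cand = FALSE, ev_cand_day = blank_day,
    ev_who4 = FALSE, ev_who4_day = blank_day,
    ev_tbp = FALSE, ev_tbp_day = blank_day,
    ev_tbe = FALSE, ev_tbe_day = blank_day,
    miss_visits = FALSE, miss_doses = FALSE,
    death = FALSE, ltfu = FALSE,
    substudy = "none", substudy_entry = blank_day)

  for (k in seq_len(K - 1L)) {
    idx <- which(active)
    if (!length(idx)) break
    m <- length(idx)

    # substudy entry: stratified (center x arm) allocation, 1:1 STI/CT
    if (k == cfg$substudy$entry_interval && cfg$substudy$fraction > 0) {
      strat <- paste(bl$center[idx], bl$arm[idx], sep = ":")
      for (stlab in unique(strat)) {
        members <- idx[strat == stlab]
        n_sub <- round(cfg$substudy$fraction * length(members))
        if (n_sub < 1L) next
        chosen <- if (length(members) == 1L) members else
          sample(members, n_sub)
        n_sti <- floor(length(chosen) / 2)
        sti <- if (length(chosen) == 1L) chosen[seq_len(n_sti)] else
          sample(chosen, n_sti)
        substudy[chosen] <- "CT"
        substudy[sti] <- "STI"
        substudy_entry[chosen] <- k
      }
    }

    s[idx] <- .latent_step(cfg, s[idx], bl$failing[idx], line[idx])
    measured <- (k %% 3L) == 0L
    obs <- rep(NA_integer_, m)
    if (measured) {
      obs <- .measure_cd4(cfg, s[idx])
      last_obs[idx] <- obs
    }

    ev <- .draw_events(cfg, s[idx])
    ev_day <- matrix(NA_integer_, m, 5L)
    n_ev <- sum(ev)
    if (n_ev > 0) ev_day[ev] <- sample(0:27, n_ev, replace = TRUE)

    w4_now <- ev[, "who4_noncandida"] | ev[, "tb_extrapulmonary"]
    w3_now <- ev[, "who3"] | ev[, "esoph_candida"] | ev[, "tb_pulmonary"]
    recent4 <- w4_now | w4_prev1[idx] | w4_prev2[idx]
    recent3 <- w3_now | w3_prev1[idx] | w3_prev2[idx]

    # natural switching behavior
    lcm <- bl$arm[idx] == "LCM"
    lp <- ifelse(lcm,
                 sb$lcm_intercept +
                   sb$lcm_cd4_lt100 * (last_obs[idx] < 100) +
                   sb$lcm_cd4_lt50 * (last_obs[idx] < 50),
                 sb$cdm_intercept) +
      sb$who4_recent * recent4 + sb$who3_recent * recent3
    can_switch <- line[idx] == 1L
    sw <- can_switch & (stats::runif(m) < expit(lp))
    sw_day <- rep(NA_integer_, m)
    if (any(sw)) {
      # switches prompted by a same-interval event happen shortly after it
      last_ev_day <- do.call(pmax, c(lapply(1:5, function(j) ev_day[, j]),
                                     list(na.rm = TRUE)))
      for (i in which(sw)) {
        sw_day[i] <- if (!is.na(last_ev_day[i])) {
          min(27L, last_ev_day[i] + sample(1:6, 1L))
        } else sample(0:27, 1L)
      }
    }

    died <- stats::runif(m) < .death_prob(cfg, s[idx], recent4, line[idx])
    lost <- !died & (stats::runif(m) < cfg$ltfu_hazard)

    rows[[k + 1L]] <- data.table::data.table(
      person_id = idx, k = k,
      on_first_line = line[idx] == 1L,
      switched = sw, switch_day = sw_day,
      cd4_measured = measured, cd4_obs = obs, cd4_true = round(s[idx]^2),
      ev_who3 = ev[, "who3"], ev_who3_day = ev_day[, 1L],
      ev_cand = ev[, "esoph_candida"], ev_cand_day = ev_day[, 2L],
      ev_who4 = ev[, "who4_noncandida"], ev_who4_day = ev_day[, 3L],
      ev_tbp = ev[, "tb_pulmonary"], ev_tbp_day = ev_day[, 4L],
      ev_tbe = ev[, "tb_extrapulmonary"], ev_tbe_day = ev_day[, 5L],
      miss_visits = stats::runif(m) < miss$miss_visits,
      miss_doses = stats::runif(m) < miss$miss_doses,
      death = died, ltfu = lost,
      substudy = substudy[idx], substudy_entry = substudy_entry[idx])

    # state updates for next interval
    line[idx[sw]] <- 2L
    switch_k[idx[sw]] <- k
    active[idx[died | lost]] <- FALSE
    w4_prev2[idx] <- w4_prev1[idx]; w4_prev1[idx] <- w4_now
    w3_prev2[idx] <- w3_prev1[idx]; w3_prev1[idx] <- w3_now
  }

  cohort <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  person <- data.table::data.table(
    person_id = seq_len(n), arm = bl$arm,
    center = bl$center, regimen = bl$regimen,
    base_cd4 = cd4_obs0, base_cd4_cat = as.character(base_cd4_cat),
    bmi_low = bl$bmi_low, hb_low = bl$hb_low,
    who4_wk24_48 = bl$who4_wk24_48, cotrim_prev = bl$cotrim,
    stratum = paste(bl$center, bl$arm, sep = ":"))
  cohort <- person[cohort, on = "person_id"]
  # substudy columns describe final assignment on every row of the person
  cohort[, `:=`(substudy = substudy[.N], substudy_entry = substudy_entry[.N]),
         by = "person_id"]
  data.table::setkey(cohort, person_id, k)
  data.table::setattr(cohort, "n_intervals", K)
  cohort[]
}
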