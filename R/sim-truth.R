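#' Ground-truth counterfactual survival by forced-regime simulation
#'
#' Simulates trajectories from the same latent mechanism as
#' [generate_cohort()] but forces compliance with a strategy: eligibility is
#' evaluated on CD4 counts observed under the strategy's monitoring
#' schedule, the switch interval is drawn uniformly over the grace period,
#' and the switch is executed at the end of that interval (so qualifying
#' events always precede it). Behavioral switching parameters, loss to
#' follow-up and the substudy play no role. The returned curve is the Monte
#' Carlo estimate of survival under the strategy with switching times
#' approximately uniform across the grace period, i.e. the estimand targeted
#' by the clone-censor-weight analysis.
#'
#' @param config a [sim_config()]; only the latent CD4, event and death
#'   mechanisms are used.
#' @param strat a [strategy()].
#' @param n_replicates number of simulated person-trajectories.
#' @param seed seed for this simulation stream (default: a fixed offset of
#'   `config$seed` so truth and cohort draws are independent).
#' @return object of class `true_survival`: list with `strategy_id`,
#'   `survival` (S(k), k = 0..n_intervals-1, S(0) = 1, non-increasing),
#'   `mc_se`, and `n_replicates`.
#' @export
simulate_counterfactual_survival <- function(config, strat,
                                             n_replicates = 1e5,
                                             seed = config$seed + 104729L) {
  validate_sim_config(config)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  cfg <- config
  n <- as.integer(n_replicates)
  K <- cfg$n_intervals
  m <- strat$grace_intervals - 1L
  sched <- schedule_intervals(strat)
  lag <- if (strat$lag_events_4wk) 1L else 0L
  trig_who4 <- "who4" %in% strat$event_triggers
  trig_2w3 <- "two_who3" %in% strat$event_triggers
  tie <- strat$tiebreaker_cd4
  ignore_tie <- strat$who4_ignore_cd4_restriction || is.na(tie)

  set.seed(as.integer(seed %% .Machine$integer.max))
  bl <- .draw_baseline(cfg, n)
  s <- bl$s
  alive <- rep(TRUE, n)
  line <- rep(1L, n)
  Q <- target <- rep(NA_integer_, n)
  last_obs <- rep(NA_real_, n)
  who3_count <- rep(0L, n)
  w4_prev1 <- w4_prev2 <- rep(FALSE, n)

  if (0L %in% sched) last_obs <- .measure_cd4(cfg, s)
  # baseline CD4 can already trigger eligibility in interval 1
  if (!is.na(strat$cd4_threshold) && 0L %in% sched) {
    hit <- !is.na(last_obs) & last_obs < strat$cd4_threshold
    Q[hit] <- 1L
    target[hit] <- 1L + sample.int(m + 1L, sum(hit), replace = TRUE) - 1L
  }

  surv <- numeric(K)
  surv[1L] <- 1
  n_alive <- n

  for (k in seq_len(K - 1L)) {
    idx <- which(alive)
    if (!length(idx)) {
      surv[(k + 1L):K] <- surv[k]
      break
    }
    mm <- length(idx)
    s[idx] <- .latent_step(cfg, s[idx], bl$failing[idx], line[idx])
    if (k %in% sched) {
      obs <- .measure_cd4(cfg, s[idx])
      last_obs[idx] <- obs
      if (!is.na(strat$cd4_threshold)) {
        hit <- idx[is.na(Q[idx]) & obs < strat$cd4_threshold]
        Q[hit] <- k + 1L
        target[hit] <- Q[hit] + sample.int(m + 1L, length(hit),
                                           replace = TRUE) - 1L
      }
    }

    ev <- .draw_events(cfg, s[idx])
    w4_now <- ev[, "who4_noncandida"] |
      (ev[, "tb_extrapulmonary"] & !strat$exclude_extrapulmonary_tb)
    w4_any <- ev[, "who4_noncandida"] | ev[, "tb_extrapulmonary"]
    w3_now <- ev[, "who3"] + ev[, "esoph_candida"] + ev[, "tb_pulmonary"]
    who3_count[idx] <- who3_count[idx] + w3_now

    tie_ok <- ignore_tie | is.na(last_obs[idx]) | last_obs[idx] < tie
    ev_trig <- rep(FALSE, mm)
    if (trig_who4) ev_trig <- ev_trig | (w4_now & tie_ok)
    if (trig_2w3) ev_trig <- ev_trig | (who3_count[idx] >= 2L & w3_now > 0L & tie_ok)
    new_ev <- idx[ev_trig & is.na(Q[idx])]
    if (length(new_ev)) {
      Q[new_ev] <- k + lag
      target[new_ev] <- Q[new_ev] + sample.int(m + 1L, length(new_ev),
                                               replace = TRUE) - 1L
    }

    # forced switch at the end of the target interval (after any events)
    do_sw <- idx[line[idx] == 1L & !is.na(target[idx]) & k >= target[idx]]

    recent4 <- w4_any | w4_prev1[idx] | w4_prev2[idx]
    died <- stats::runif(mm) < .death_prob(cfg, s[idx], recent4, line[idx])
    alive[idx[died]] <- FALSE
    line[do_sw] <- 2L
    w4_prev2[idx] <- w4_prev1[idx]
    w4_prev1[idx] <- w4_any
    n_alive <- n_alive - sum(died)
    surv[k + 1L] <- n_alive / n
  }

  structure(list(strategy_id = strat$strategy_id,
                 survival = surv,
                 mc_se = sqrt(surv * (1 - surv) / n),
                 n_replicates = n),
            class = "true_survival")
}
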