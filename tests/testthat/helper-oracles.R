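# Independent brute-force oracles: slow per-person loops that transcribe
# the eligibility/censoring rules and the nonstabilized weight formula
# term by term, kept deliberately separate from the vectorized package
# implementation.

# rule-trace eligibility: returns list(Q, reason) for one person's rows
oracle_eligibility <- function(rows, strat) {
  rows <- rows[order(rows$k), ]
  sched <- if (length(strat$monitoring_weeks)) {
    as.integer(strat$monitoring_weeks / 4)
  } else integer(0)
  lag <- if (isTRUE(strat$lag_events_4wk)) 1L else 0L
  last_obs <- NA_real_
  who3_count <- 0L
  q_cd4 <- q_ev <- NA_integer_
  for (i in seq_len(nrow(rows))) {
    k <- rows$k[i]
    if (rows$cd4_measured[i] && k %in% sched) {
      last_obs <- as.numeric(rows$cd4_obs[i])
      if (!is.na(strat$cd4_threshold) && is.na(q_cd4) &&
          last_obs < strat$cd4_threshold) {
        q_cd4 <- k + 1L
      }
    }
    tie_ok <- isTRUE(strat$who4_ignore_cd4_restriction) ||
      is.na(strat$tiebreaker_cd4) ||
      is.na(last_obs) || last_obs < strat$tiebreaker_cd4
    swd <- rows$switch_day[i]
    ok_day <- function(flag, day) {
      isTRUE(flag) && (is.na(swd) || (!is.na(day) && day < swd))
    }
    if ("who4" %in% strat$event_triggers && is.na(q_ev) && tie_ok) {
      hit <- ok_day(rows$ev_who4[i], rows$ev_who4_day[i]) ||
        (!isTRUE(strat$exclude_extrapulmonary_tb) &&
           ok_day(rows$ev_tbe[i], rows$ev_tbe_day[i]))
      if (hit) q_ev <- k + lag
    }
    n3 <- ok_day(rows$ev_who3[i], rows$ev_who3_day[i]) +
      ok_day(rows$ev_cand[i], rows$ev_cand_day[i]) +
      ok_day(rows$ev_tbp[i], rows$ev_tbp_day[i])
    if ("two_who3" %in% strat$event_triggers) {
      if (is.na(q_ev) && tie_ok && n3 > 0L && who3_count + n3 >= 2L) {
        q_ev <- k + lag
      }
    }
    who3_count <- who3_count + n3
  }
  if (is.na(q_cd4) && is.na(q_ev)) return(list(Q = NA_integer_,
                                               reason = NA_character_))
  Q <- min(q_cd4, q_ev, na.rm = TRUE)
  reason <- if (!is.na(q_ev) && (is.na(q_cd4) || q_ev <= q_cd4)) "event"
  else "cd4"
  list(Q = Q, reason = reason)
}

# censoring point from Q, the switch interval, and grace m (Inf = never)
oracle_censor <- function(Q, switch_k, m) {
  if (!is.na(switch_k) && (is.na(Q) || switch_k < Q)) return(switch_k)
  if (!is.na(Q) && (is.na(switch_k) || switch_k > Q + m)) return(Q + m + 1L)
  Inf
}

# literal term-by-term evaluation of the nonstabilized weight formula for
# one person; pA_tab maps interval k -> probability of not switching
oracle_weight_series <- function(rows, strat, pA_tab) {
  rows <- rows[order(rows$k), ]
  m <- strat$grace_intervals - 1L
  el <- oracle_eligibility(rows, strat)
  Q <- el$Q
  sk <- if (any(rows$switched)) min(rows$k[rows$switched]) else NA_integer_
  cens <- oracle_censor(Q, sk, m)
  pA <- function(j) pA_tab$p_A[pA_tab$k == j]
  W <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    kk <- rows$k[i]
    if (kk >= cens) { W[i] <- 0; next }
    prod <- 1
    for (j in rows$k[rows$k >= 1L & rows$k <= kk]) {
      if (is.na(Q) || j < Q) {
        prod <- prod / pA(j)
      } else if (j <= Q + m) {
        r <- j - Q
        if (!is.na(sk) && sk == j) {
          prod <- prod * (1 / (m + 1 - r)) / (1 - pA(j))
        } else if (is.na(sk) || sk > j) {
          prod <- prod * (1 - 1 / (m + 1 - r)) / pA(j)
        }
        # switched earlier within the grace period: factor 1
      }
      # past the grace period (still uncensored => switched in grace): 1
    }
    W[i] <- prod
  }
  W
}

# independent restricted-truncated-power-basis evaluation
oracle_rcs <- function(x, knots) {
  K <- length(knots)
  tk <- knots[K]; tk1 <- knots[K - 1L]
  scl <- (knots[K] - knots[1L])^2
  pp <- function(u) ifelse(u > 0, u^3, 0)
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- x
  for (j in 1:(K - 2L)) {
    out[, j + 1L] <- (pp(x - knots[j]) -
                        pp(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                        pp(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / scl
  }
  out
}
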