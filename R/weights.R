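# Nonstabilized strategy weights with a uniform-over-grace-period
# numerator, substudy upweights, loss-to-follow-up weights, and their
# truncated product.

.positivity_eps <- 1e-6

positivity_error <- function(what, person, k) {
  stop(structure(class = c("dynmsm_positivity_error", "error", "condition"),
                 list(message = paste0(
                   "positivity violation: ", what, " below ",
                   .positivity_eps, " for person ", person,
                   " at interval ", k),
                   call = NULL)))
}

#' Strategy (artificial-censoring) weight series
#'
#' Computes the nonstabilized inverse-probability weight `W_x(k)` for every
#' clone-interval. With `p_A(k)` the probability of *not* switching in
#' interval `k` given history, each pre-eligibility interval contributes a
#' factor `1/p_A(j)`; a grace-period interval at offset `r` contributes
#' `(1 - 1/(m+1-r))/p_A` when the clone did not switch and
#' `(1/(m+1-r))/(1 - p_A)` when it did (the numerators spread switching
#' times uniformly across the grace period); all later intervals contribute
#' 1. `W_x(k)` is the running product, and is 0 from the interval of
#' artificial censoring (and at the final grace interval of a clone that
#' never switched, whose uniform-numerator mass is exhausted).
#'
#' @param clones clone-interval table from [expand_clones()] (any subset of
#'   strategies).
#' @param p_A `data.table` with columns `person_id`, `k`, `p_A`: the
#'   probability of remaining on first-line ART in interval `k`, from the
#'   switch model fitted to the full (unexpanded) cohort with all measured
#'   CD4 counts.
#' @param grace_intervals grace-period length (intervals); `m` is this
#'   minus 1.
#' @return the clone table with columns `w_factor` (per-interval factor)
#'   and `strategy_weight` (`W_x(k)`) appended.
#' @export
strategy_weight_series <- function(clones, p_A, grace_intervals = 3L) {
  m <- grace_intervals - 1L
  cl <- data.table::as.data.table(clones)
  data.table::setkey(cl, strategy_id, person_id, k)
  cl <- merge(cl, p_A, by = c("person_id", "k"), all.x = TRUE, sort = FALSE)
  data.table::setkey(cl, strategy_id, person_id, k)

  k <- cl$k; Q <- cl$Q; sk <- cl$switch_k; pa <- cl$p_A
  uncens <- k < cl$censor_from
  pre <- uncens & k >= 1L & (is.na(Q) | k < Q)
  r <- k - Q
  in_grace <- uncens & !is.na(Q) & r >= 0L & r <= m
  g_switch <- in_grace & !is.na(sk) & sk == k
  g_wait <- in_grace & (is.na(sk) | sk > k)

  need_pa <- pre | g_wait
  bad <- need_pa & (is.na(pa) | pa < .positivity_eps)
  if (any(bad)) {
    i <- which(bad)[1L]
    positivity_error("probability of not switching, p_A(k),",
                     cl$person_id[i], k[i])
  }
  bad2 <- g_switch & (is.na(pa) | (1 - pa) < .positivity_eps)
  if (any(bad2)) {
    i <- which(bad2)[1L]
    positivity_error("switch probability, 1 - p_A(k),",
                     cl$person_id[i], k[i])
  }

  logfac <- numeric(nrow(cl))
  logfac[pre] <- -log(pa[pre])
  logfac[g_wait] <- log(1 - 1 / (m + 1 - r[g_wait])) - log(pa[g_wait])
  logfac[g_switch] <- log(1 / (m + 1 - r[g_switch])) -
    log(1 - pa[g_switch])

  grp <- paste(cl$strategy_id, cl$person_id, sep = "\r")
  # a zero factor (exhausted numerator mass at the last grace interval)
  # zeroes the weight from that interval on; kept out of the log cumsum
  zero_row <- is.infinite(logfac)
  fac <- exp(logfac)
  logfac[zero_row] <- 0
  zero_cum <- ave_cumsum(as.numeric(zero_row), grp) > 0
  W <- exp(ave_cumsum(logfac, grp)) * as.numeric(uncens & !zero_cum)
  cl[, c("w_factor", "strategy_weight") := list(fac, W)]
  cl$p_A <- NULL
  cl[]
}

#' Substudy censoring weights
#'
#' Participants randomized to structured treatment interruptions (STI) are
#' censored (weight 0) from their substudy entry interval; participants
#' randomized to continuous therapy are upweighted from entry by
#' `(n_STI + n_CT) / n_CT` within their center-by-arm stratum, so they
#' represent the censored STI participants in addition to themselves
#' (weights are approximately 2 under 1:1 allocation). Everyone else has
#' weight 1.
#'
#' @param cohort person-period `data.table`.
#' @return `data.table` with `person_id`, `k`, `substudy_weight`.
#' @export
substudy_weights <- function(cohort) {
  dt <- data.table::as.data.table(cohort)
  out <- dt[, c("person_id", "k", "substudy", "substudy_entry", "stratum")]
  out$substudy_weight <- 1
  if (!any(dt$substudy != "none")) {
    return(out[, c("person_id", "k", "substudy_weight")])
  }
  members <- unique(dt[dt$substudy != "none",
                       c("person_id", "substudy", "stratum")])
  counts <- members[, list(n_sti = sum(substudy == "STI"),
                           n_ct = sum(substudy == "CT")), by = "stratum"]
  bad <- counts$n_ct == 0 & counts$n_sti > 0
  if (any(bad)) {
    positivity_error("continuous-therapy count in substudy stratum",
                     counts$stratum[bad][1L], NA)
  }
  counts$ct_weight <- (counts$n_sti + counts$n_ct) / counts$n_ct
  out <- merge(out, counts[, c("stratum", "ct_weight")], by = "stratum",
               all.x = TRUE, sort = FALSE)
  after <- !is.na(out$substudy_entry) & out$k >= out$substudy_entry
  out$substudy_weight[after & out$substudy == "STI"] <- 0
  ct <- after & out$substudy == "CT"
  out$substudy_weight[ct] <- out$ct_weight[ct]
  data.table::setkey(out, person_id, k)
  out[, c("person_id", "k", "substudy_weight")]
}

#' Loss-to-follow-up weights
#'
#' Inverse-probability-of-censoring weights for dropout: a pooled logistic
#' model of loss to follow-up on the switch-model covariates plus an
#' indicator of any previous switch to second-line ART. The weight at
#' interval `k` is the cumulative product of `1 / P(remain in follow-up)`
#' over intervals up to `k`. When the cohort contains no losses the weights
#' are exactly 1 (no model is fitted).
#'
#' @param cohort person-period `data.table`.
#' @param design optional precomputed [build_switch_design()] output.
#' @return `data.table` with `person_id`, `k`, `ltfu_weight` and the fitted
#'   per-interval dropout probability `p_ltfu`; attribute `fit` carries the
#'   model when one was fitted.
#' @export
ltfu_weight_series <- function(cohort, design = NULL) {
  dt <- data.table::as.data.table(cohort)
  data.table::setkey(dt, person_id, k)
  base <- dt[, c("person_id", "k")]
  if (!any(dt$ltfu)) {
    base$p_ltfu <- 0
    base$ltfu_weight <- 1
    return(base[])
  }
  d <- design %||% build_switch_design(dt)
  X <- cbind(d$X, prior_switch = d$prior_switch)
  f <- fit_pooled_logit(X, d$y_ltfu, label = "LTFU model")
  if (!f$converged) {
    stop("LTFU model did not converge (possible separation)", call. = FALSE)
  }
  p <- as.numeric(expit(X %*% f$coef))
  if (any(1 - p < .positivity_eps)) {
    i <- which(1 - p < .positivity_eps)[1L]
    positivity_error("probability of remaining in follow-up",
                     d$person_id[i], d$k[i])
  }
  tab <- data.table::data.table(person_id = d$person_id, k = d$k,
                                p_ltfu = p)
  out <- merge(base, tab, by = c("person_id", "k"), all.x = TRUE,
               sort = FALSE)
  data.table::setkey(out, person_id, k)
  out$p_ltfu[is.na(out$p_ltfu)] <- 0   # interval 0: no dropout possible
  out$ltfu_weight <- exp(ave_cumsum(-log(1 - out$p_ltfu), out$person_id))
  data.table::setattr(out, "fit", f)
  out[]
}

#' Combine and truncate weight components
#'
#' Elementwise product of strategy, substudy and loss-to-follow-up weights,
#' truncated at `cap` (default 10). The raw product is retained for
#' sensitivity analyses with untruncated weights.
#'
#' @param strategy_w output of [strategy_weight_series()].
#' @param substudy_w output of [substudy_weights()].
#' @param ltfu_w output of [ltfu_weight_series()].
#' @param cap truncation point (use `Inf` for raw weights).
#' @return the clone table with `raw_weight` and `truncated_weight`
#'   appended.
#' @export
combine_truncate <- function(strategy_w, substudy_w, ltfu_w, cap = 10) {
  cl <- data.table::as.data.table(strategy_w)
  n0 <- nrow(cl)
  cl <- merge(cl, substudy_w, by = c("person_id", "k"), sort = FALSE)
  cl <- merge(cl, ltfu_w[, c("person_id", "k", "ltfu_weight")],
              by = c("person_id", "k"), sort = FALSE)
  if (nrow(cl) != n0) {
    stop("data error: weight series are misaligned across components",
         call. = FALSE)
  }
  cl$raw_weight <- cl$strategy_weight * cl$substudy_weight * cl$ltfu_weight
  cl$truncated_weight <- pmin(cl$raw_weight, cap)
  data.table::setkey(cl, strategy_id, person_id, k)
  cl[]
}

#' Implied switch-time distribution over the grace period
#'
#' The uniform-numerator factors of the strategy weights assign probability
#' mass to switching at each grace offset `r`; this helper returns that
#' distribution, which sums to exactly 1 for any grace length.
#'
#' @param grace_intervals grace-period length in intervals.
#' @return numeric vector of length `grace_intervals` summing to 1.
#' @export
grace_switch_distribution <- function(grace_intervals = 3L) {
  m <- grace_intervals - 1L
  mass <- numeric(m + 1L)
  stay <- 1
  for (r in 0:m) {
    mass[r + 1L] <- stay * (1 / (m + 1 - r))
    stay <- stay * (1 - 1 / (m + 1 - r))
  }
  mass
}
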