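# End-to-end clone-censor-weight estimation. A precomputed "context" holds
# everything that does not change across bootstrap replicates (design
# matrices, eligibility, censoring, outcome risk rows); resampling
# individuals is then equivalent to refitting with per-person multiplicity
# weights, which makes the 500-replicate nonparametric bootstrap tractable.

# cumulative sum resetting at group starts (groups contiguous)
.cumsum_reset <- function(x, first) {
  cs <- cumsum(x)
  base <- cs - x
  cs - base[first][cumsum(first)]
}

msm_context <- function(cohort, strategies, encoding = "hg", cap = 10,
                        outcome = "death", h_form = "linear",
                        horizon = NULL) {
  if (inherits(strategies, "strategy")) strategies <- list(strategies)
  ids <- vapply(strategies, function(s) s$strategy_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate strategy_id in strategy list", call. = FALSE)
  }
  cohort <- data.table::as.data.table(cohort)
  data.table::setkey(cohort, person_id, k)
  persons <- unique(cohort$person_id)
  n_persons <- length(persons)
  pidx_coh <- match(cohort$person_id, persons)
  first_coh <- !duplicated(pidx_coh)
  ncoh <- nrow(cohort)

  d <- build_switch_design(cohort)
  idx_design <- which(cohort$k >= 1L)    # design rows in cohort order
  pidx_des <- pidx_coh[idx_design]
  zero_switch <- sum(d$y_switch[d$risk_switch]) == 0
  zero_ltfu <- !any(d$y_ltfu > 0)
  X_ltfu <- cbind(d$X, prior_switch = d$prior_switch)

  # person-level substudy info
  per <- cohort[first_coh, c("person_id", "substudy", "substudy_entry",
                             "stratum")]
  sub_entry_coh <- cohort$substudy_entry
  sub_after <- !is.na(sub_entry_coh) & cohort$k >= sub_entry_coh
  sub_code <- integer(ncoh)                       # 0 none, 1 STI, 2 CT
  sub_code[sub_after & cohort$substudy == "STI"] <- 1L
  sub_code[sub_after & cohort$substudy == "CT"] <- 2L
  strat_of_coh <- match(cohort$stratum, sort(unique(cohort$stratum)))
  strata <- sort(unique(cohort$stratum))

  if (is.character(encoding)) {
    encoding <- strategy_encoding(strategies, encoding, h_form)
  }

  m_g <- vapply(strategies, function(s) s$grace_intervals - 1L, integer(1))

  # per-strategy static structures
  strat_static <- lapply(seq_along(strategies), function(si) {
    strat <- strategies[[si]]
    m <- m_g[si]
    el <- strategy_eligibility(cohort, strat)
    Qp <- el$Q[match(persons, el$person_id)]
    skp <- el$switch_k[match(persons, el$person_id)]
    censp <- el$censor_from[match(persons, el$person_id)]
    Q <- Qp[pidx_coh]; sk <- skp[pidx_coh]; cens <- censp[pidx_coh]
    k <- cohort$k
    uncens <- k < cens
    pre <- uncens & k >= 1L & (is.na(Q) | k < Q)
    r <- k - Q
    in_grace <- uncens & !is.na(Q) & !is.na(r) & r >= 0L & r <= m
    g_switch <- in_grace & !is.na(sk) & sk == k
    g_wait <- in_grace & (is.na(sk) | sk > k)
    type <- integer(ncoh)
    type[pre | g_wait] <- 1L                      # needs 1/p_A
    type[g_switch] <- 2L                          # needs 1/(1 - p_A)
    log_c <- numeric(ncoh)
    log_c[g_wait] <- log(1 - 1 / (m + 1 - r[g_wait]))
    log_c[g_switch] <- -log(m + 1 - r[g_switch])

    # outcome risk rows (static): indexes into cohort rows
    last_idx <- cumsum(tabulate(pidx_coh))      # last row of each person
    T_last <- cohort$k[last_idx][pidx_coh]
    lastrow_death <- cohort$death[last_idx][pidx_coh]
    lastrow_ltfu <- cohort$ltfu[last_idx][pidx_coh]
    if (outcome == "death") {
      end_k <- ifelse(lastrow_ltfu, T_last - 2L, T_last - 1L)
      y <- as.numeric(lastrow_death & k + 1L == T_last)
    } else {
      end_k <- T_last - 1L
      y <- as.numeric((lastrow_death | lastrow_ltfu) & k + 1L == T_last)
    }
    sti_end <- ifelse(cohort$substudy == "STI" & !is.na(sub_entry_coh),
                      sub_entry_coh - 2L, Inf)
    out_keep <- which(k <= pmin(end_k, sti_end) & uncens)
    death_p <- cohort$death[last_idx]
    Tl_p <- cohort$k[last_idx]
    list(strat = strat, Q = Qp, sk = skp, cens = censp,
         type = type, log_c = log_c, uncens = uncens,
         out_rows = out_keep, out_y = y[out_keep],
         n_deaths_compat = sum(death_p & Tl_p < censp))
  })

  out_k <- unlist(lapply(strat_static, function(s) cohort$k[s$out_rows]))
  out_sid <- unlist(lapply(seq_along(strategies), function(si)
    rep(ids[si], length(strat_static[[si]]$out_rows))))
  k_knots_out <- unique(as.numeric(stats::quantile(out_k, c(0.1, 0.5, 0.9),
                                                   type = 1)))
  if (length(k_knots_out) < 3L) {
    k_knots_out <- seq(min(out_k), max(out_k), length.out = 3L)
  }
  X_out <- outcome_design(out_k, out_sid, encoding, k_knots_out)
  y_out <- unlist(lapply(strat_static, function(s) s$out_y))
  max_k <- max(out_k)
  if (is.null(horizon)) horizon <- min(60L, max_k + 1L)
  if (horizon - 1L > max_k) {
    stop("extrapolation error: horizon ", horizon,
         " exceeds observed risk intervals (max ", max_k, ")",
         call. = FALSE)
  }
  X_pred <- lapply(ids, function(id)
    outcome_design(0:(horizon - 1L), rep(id, horizon), encoding,
                   k_knots_out))

  # drop aliased columns once; replicate refits then use plain Newton steps
  risk_rows <- which(d$risk_switch)
  sw_cols <- if (zero_switch) integer(0) else
    nonaliased_cols(d$X[risk_rows, , drop = FALSE])
  Xsw_risk <- d$X[risk_rows, sw_cols, drop = FALSE]
  X_des_sw <- d$X[, sw_cols, drop = FALSE]
  ltfu_cols <- if (zero_ltfu) integer(0) else nonaliased_cols(X_ltfu)
  Xlt <- X_ltfu[, ltfu_cols, drop = FALSE]
  out_cols <- nonaliased_cols(X_out)
  X_out_sub <- X_out[, out_cols, drop = FALSE]
  X_pred_sub <- lapply(X_pred, function(Xp) Xp[, out_cols, drop = FALSE])

  list(cohort = cohort, strategies = strategies, ids = ids,
       encoding = encoding, cap = cap, outcome = outcome,
       persons = persons, n_persons = n_persons,
       pidx_coh = pidx_coh, first_coh = first_coh, ncoh = ncoh,
       design = d, idx_design = idx_design, pidx_des = pidx_des,
       zero_switch = zero_switch, zero_ltfu = zero_ltfu,
       X_ltfu = X_ltfu,
       risk_rows = risk_rows, sw_cols = sw_cols, Xsw_risk = Xsw_risk,
       X_des_sw = X_des_sw, y_sw_risk = d$y_switch[risk_rows],
       pidx_sw_risk = pidx_coh[idx_design][risk_rows],
       ltfu_cols = ltfu_cols, Xlt = Xlt,
       out_cols = out_cols, X_out_sub = X_out_sub,
       X_pred_sub = X_pred_sub,
       per_substudy = per, sub_code = sub_code,
       strat_of_coh = strat_of_coh, strata = strata,
       strat_static = strat_static,
       out_pidx = unlist(lapply(strat_static, function(s)
         pidx_coh[s$out_rows])),
       y_out = y_out, out_k = out_k,
       k_knots_out = k_knots_out,
       horizon = horizon, max_k = max_k)
}

# run one estimation pass with per-person multiplicities `mult`
# (rep(1, n) gives the point estimate); returns survival matrix and,
# optionally, diagnostics. `warm` carries coefficient starting values from
# the point estimate to speed up bootstrap refits.
.estimate_pass <- function(ctx, mult, details = FALSE, warm = NULL,
                           eps = 1e-10, hess_stride = 1L) {
  d <- ctx$design
  w_des <- mult[ctx$pidx_des]
  betas <- list()

  if (ctx$zero_switch) {
    pA_coh <- rep(1, ctx$ncoh)
    switch_coef <- NULL
  } else {
    f <- fast_logit(ctx$Xsw_risk, ctx$y_sw_risk,
                    w = mult[ctx$pidx_sw_risk], beta = warm$sw, eps = eps,
                    hess_stride = hess_stride)
    if (!f$converged) {
      stop("switch model did not converge (possible separation)",
           call. = FALSE)
    }
    betas$sw <- f$coef
    p_switch <- as.numeric(expit(ctx$X_des_sw %*% f$coef))
    pA_coh <- rep(1, ctx$ncoh)
    pA_coh[ctx$idx_design] <- 1 - p_switch
    switch_coef <- stats::setNames(f$coef, colnames(ctx$Xsw_risk))
  }

  if (ctx$zero_ltfu || ctx$outcome == "death_or_ltfu") {
    lw_coh <- rep(1, ctx$ncoh)
    p_ltfu_coh <- rep(0, ctx$ncoh)
  } else {
    f <- fast_logit(ctx$Xlt, d$y_ltfu, w = w_des, beta = warm$ltfu,
                    eps = eps, hess_stride = hess_stride)
    if (!f$converged) {
      stop("LTFU model did not converge (possible separation)",
           call. = FALSE)
    }
    betas$ltfu <- f$coef
    p_l <- as.numeric(expit(ctx$Xlt %*% f$coef))
    if (any(1 - p_l < .positivity_eps)) {
      i <- which(1 - p_l < .positivity_eps)[1L]
      positivity_error("probability of remaining in follow-up",
                       d$person_id[i], d$k[i])
    }
    p_ltfu_coh <- rep(0, ctx$ncoh)
    p_ltfu_coh[ctx$idx_design] <- p_l
    lw_coh <- exp(.cumsum_reset(-log(1 - p_ltfu_coh), ctx$first_coh))
  }

  # substudy weights under this resample
  sub_w <- rep(1, ctx$ncoh)
  if (any(ctx$sub_code > 0L)) {
    per <- ctx$per_substudy
    pm <- mult
    st_idx <- match(per$stratum, ctx$strata)
    n_sti <- n_ct <- numeric(length(ctx$strata))
    sti <- per$substudy == "STI"; ct <- per$substudy == "CT"
    for (j in seq_along(ctx$strata)) {
      n_sti[j] <- sum(pm[st_idx == j & sti])
      n_ct[j] <- sum(pm[st_idx == j & ct])
    }
    if (any(n_ct == 0 & n_sti > 0)) {
      positivity_error("continuous-therapy count in substudy stratum",
                       ctx$strata[which(n_ct == 0 & n_sti > 0)[1L]], NA)
    }
    ct_w <- ifelse(n_ct > 0, (n_sti + n_ct) / n_ct, 1)
    sub_w[ctx$sub_code == 1L] <- 0
    i2 <- ctx$sub_code == 2L
    sub_w[i2] <- ct_w[ctx$strat_of_coh[i2]]
  }

  log_pa <- log(pA_coh)
  log_ps <- log1p(-pA_coh)
  trunc_w_all <- numeric(0)
  raw_w_all <- numeric(0)
  for (si in seq_along(ctx$strat_static)) {
    ss <- ctx$strat_static[[si]]
    bad <- (ss$type == 1L & pA_coh < .positivity_eps) |
      (ss$type == 2L & (1 - pA_coh) < .positivity_eps)
    if (any(bad)) {
      i <- which(bad)[1L]
      positivity_error("switch-model denominator",
                       ctx$cohort$person_id[i], ctx$cohort$k[i])
    }
    logfac <- ss$log_c -
      ifelse(ss$type == 1L, log_pa, 0) -
      ifelse(ss$type == 2L, log_ps, 0)
    # structural zeros (exhausted uniform-numerator mass at the last grace
    # interval) are tracked separately so -Inf cannot poison the cumsum
    zero_row <- is.infinite(logfac)
    logfac[zero_row] <- 0
    zero_cum <- .cumsum_reset(as.numeric(zero_row), ctx$first_coh) > 0
    W <- exp(.cumsum_reset(logfac, ctx$first_coh))
    W[zero_cum | !ss$uncens] <- 0
    raw <- W[ss$out_rows] * sub_w[ss$out_rows] * lw_coh[ss$out_rows]
    raw_w_all <- c(raw_w_all, raw)
    trunc_w_all <- c(trunc_w_all, pmin(raw, ctx$cap))
  }

  w_fit <- trunc_w_all * mult[ctx$out_pidx]
  f_out <- fast_logit(ctx$X_out_sub, ctx$y_out, w = w_fit,
                      beta = warm$out, eps = eps)
  if (!f_out$converged) {
    stop("outcome model did not converge", call. = FALSE)
  }
  betas$out <- f_out$coef
  S <- vapply(ctx$X_pred_sub, function(Xp) {
    haz <- as.numeric(expit(Xp %*% f_out$coef))
    c(1, cumprod(1 - haz))
  }, numeric(ctx$horizon + 1L))

  out <- list(S = S, betas = betas)
  if (details) {
    out$switch_coef <- switch_coef
    out$outcome_coef <- stats::setNames(f_out$coef,
                                        colnames(ctx$X_out_sub))
    out$raw_weights <- raw_w_all
    out$trunc_weights <- trunc_w_all
    out$pA_coh <- pA_coh
    out$ltfu_weight_coh <- lw_coh
    out$substudy_weight_coh <- sub_w
  }
  out
}

#' Estimate counterfactual survival under switching strategies
#'
#' Full clone-censor-weight analysis: fits the pooled logistic switch model
#' (and, when the cohort has losses, the LTFU model) on the unexpanded
#' cohort, expands the cohort into per-strategy clones, computes
#' nonstabilized strategy weights with uniform-over-grace numerators,
#' multiplies in substudy and LTFU weights, truncates, fits the weighted
#' pooled logistic outcome model, and predicts per-strategy survival
#' curves, optionally with nonparametric bootstrap confidence bands
#' (resampling individuals, ignoring randomized arm).
#'
#' @param cohort person-period `data.table`.
#' @param strategies list of [strategy()] objects.
#' @param encoding outcome-model strategy encoding mode (`"hg"`, `"f"`,
#'   `"none"`) or a [strategy_encoding()].
#' @param horizon survival horizon in intervals (default: 60, i.e. 240
#'   weeks, capped at the observed risk range).
#' @param B bootstrap replicates (0 = point estimates only).
#' @param seed seed for the bootstrap resampling.
#' @param cap weight truncation point (default 10; `Inf` for raw weights).
#' @param outcome `"death"` or `"death_or_ltfu"`.
#' @param h_form form of the CD4-threshold term `h(X)` under `"hg"`
#'   encoding.
#' @return object of class `msm_estimate`: per-strategy `survival_curve`s
#'   (with percentile bands and replicate stores when `B > 0`), model
#'   coefficients, weight diagnostics, and per-strategy compliance counts.
#' @export
estimate_survival <- function(cohort, strategies, encoding = "hg",
                              horizon = NULL, B = 0L, seed = 1L, cap = 10,
                              outcome = c("death", "death_or_ltfu"),
                              h_form = "linear") {
  outcome <- match.arg(outcome)
  if (B < 0) stop("B must be >= 0", call. = FALSE)
  ctx <- msm_context(cohort, strategies, encoding, cap = cap,
                     outcome = outcome, h_form = h_form, horizon = horizon)
  point <- .estimate_pass(ctx, rep(1, ctx$n_persons), details = TRUE)

  curves <- lapply(seq_along(ctx$ids), function(si) {
    structure(list(strategy_id = ctx$ids[si], S = point$S[, si],
                   hazard = NULL, lower = NULL, upper = NULL,
                   B = 0L, replicates = NULL),
              class = "survival_curve")
  })
  names(curves) <- ctx$ids

  n_failed <- 0L
  if (B > 0) {
    set.seed(as.integer(seed))
    reps <- array(NA_real_, c(B, ctx$horizon + 1L, length(ctx$ids)))
    for (b in seq_len(B)) {
      mult <- tabulate(sample.int(ctx$n_persons, ctx$n_persons,
                                  replace = TRUE), ctx$n_persons)
      res <- tryCatch(suppressMessages(
        .estimate_pass(ctx, mult, warm = point$betas, eps = 1e-4,
                       hess_stride = 3L)),
        error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        message("bootstrap replicate ", b, " failed: ",
                conditionMessage(res))
        next
      }
      reps[b, , ] <- res$S
    }
    for (si in seq_along(ctx$ids)) {
      R <- matrix(reps[, , si], nrow = B)
      ok <- !is.na(R[, 1L])
      band <- apply(R[ok, , drop = FALSE], 2L, stats::quantile,
                    probs = c(0.025, 0.975), names = FALSE, type = 7)
      curves[[si]]$lower <- band[1L, ]
      curves[[si]]$upper <- band[2L, ]
      curves[[si]]$B <- sum(ok)
      curves[[si]]$replicates <- R[ok, , drop = FALSE]
    }
  }

  wpos <- point$trunc_weights[point$trunc_weights > 0]
  diag <- list(mean_weight = mean(wpos),
               p99_weight = stats::quantile(wpos, 0.99, names = FALSE),
               max_weight = max(wpos),
               pct_truncated = 100 * mean(point$raw_weights > ctx$cap))

  compliance <- data.table::rbindlist(lapply(ctx$strat_static, function(ss) {
    elig <- !is.na(ss$Q)
    m <- ss$strat$grace_intervals - 1L
    in_grace <- elig & !is.na(ss$sk) & ss$sk >= ss$Q & ss$sk <= ss$Q + m
    data.table::data.table(
      strategy_id = ss$strat$strategy_id,
      n_eligible = sum(elig),
      n_switched_in_grace = sum(in_grace),
      pct_switched_in_grace = 100 * sum(in_grace) / max(1L, sum(elig)),
      n_censored = sum(is.finite(ss$cens)),
      n_deaths_compatible = ss$n_deaths_compat)
  }))

  structure(list(curves = curves, horizon = ctx$horizon,
                 encoding = ctx$encoding,
                 switch_coef = point$switch_coef,
                 outcome_coef = point$outcome_coef,
                 weight_diagnostics = diag,
                 compliance = compliance,
                 B = B, n_failed_replicates = n_failed,
                 seed = seed, cap = cap),
            class = "msm_estimate")
}

#' @export
print.msm_estimate <- function(x, ...) {
  cat("<msm_estimate>", length(x$curves), "strategies, horizon",
      x$horizon, "intervals (", 4 * x$horizon, "weeks )\n")
  K <- x$horizon
  for (cv in x$curves) {
    ci <- if (!is.null(cv$lower)) {
      sprintf(" (95%% CI: %.3f, %.3f)", cv$lower[K + 1L], cv$upper[K + 1L])
    } else ""
    cat(sprintf("  %-28s S(%d wk) = %.3f%s\n", cv$strategy_id, 4 * K,
                cv$S[K + 1L], ci))
  }
  cat("  weights: mean", round(x$weight_diagnostics$mean_weight, 3),
      " p99", round(x$weight_diagnostics$p99_weight, 2),
      " truncated", sprintf("%.2f%%", x$weight_diagnostics$pct_truncated),
      "\n")
  invisible(x)
}

#' Nonparametric bootstrap confidence bands
#'
#' Resamples individuals with replacement (ignoring randomized arm),
#' re-runs the entire pipeline (switch model, LTFU model, substudy
#' weights, clone expansion, strategy weights, outcome model) per
#' replicate, and returns percentile 2.5/97.5 bands. Failed replicates are
#' logged and skipped.
#'
#' @inheritParams estimate_survival
#' @return an `msm_estimate` with bootstrap bands and replicate stores.
#' @export
bootstrap_cis <- function(cohort, strategies, B = 500L, seed = 1L,
                          encoding = "hg", horizon = NULL, cap = 10,
                          outcome = c("death", "death_or_ltfu")) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  estimate_survival(cohort, strategies, encoding = encoding,
                    horizon = horizon, B = B, seed = seed, cap = cap,
                    outcome = match.arg(outcome))
}
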