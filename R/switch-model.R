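# Time-dependent design matrix for the pooled logistic switch model (also
# reused, plus a prior-switch indicator, by the loss-to-follow-up model).

.cd4_knots <- c(15, 50, 100, 200)

# effective event indicator for design purposes: events in the interval of
# a switch count only when they occurred strictly before the switch; in all
# other intervals every event counts
.eff_event <- function(flag, day, switched, switch_day) {
  flag & (!switched | (!is.na(day) & day < switch_day))
}

# five-category event history with the highest level dominant
.event_history_5cat <- function(recent4, distal4, recent3, distal3) {
  out <- rep("none", length(recent4))
  out[distal3] <- "who3_distal"
  out[recent3] <- "who3_recent"
  out[distal4] <- "who4_distal"
  out[recent4] <- "who4_recent"
  out
}

.hist_dummies <- function(cat5, prefix) {
  lev <- c("who3_distal", "who3_recent", "who4_distal", "who4_recent")
  out <- vapply(lev, function(l) as.numeric(cat5 == l),
                numeric(length(cat5)))
  colnames(out) <- paste0(prefix, "_", lev)
  out
}

#' Build the switch-model design matrix for a cohort
#'
#' Assembles, for every person-interval, the covariates of the pooled
#' logistic model for switching to second-line ART: a restricted cubic
#' spline in interval index (knots at the 10th/50th/90th percentiles of the
#' at-risk interval distribution), baseline covariates (center-by-regimen,
#' baseline CD4 category, low BMI, low hemoglobin, WHO4 event during weeks
#' 24-48 on ART), current CD4 (LOCF over all 12-weekly measurements,
#' restricted cubic spline with knots 15/50/100/200), cotrimoxazole use in
#' the previous interval during the first 72 weeks on ART, missed visits
#' and missed doses, five-category WHO 3/4 and tuberculosis event histories
#' (recent = intervals k-2..k, distal = k-5..k-3, highest level dominant),
#' and the interaction of a recent non-Candida WHO4 event with current
#' CD4 < 100. Events in the interval of a switch enter only when they
#' occurred strictly before the switch.
#'
#' @param cohort person-period `data.table`.
#' @param k_knots interval-spline knots; computed from the at-risk
#'   distribution when `NULL`.
#' @return list with the design matrix `X` (all rows with `k >= 1`), row
#'   metadata, outcome vectors `y_switch` and `y_ltfu`, the switch-model
#'   risk-set indicator `risk_switch` (on first-line ART), `prior_switch`,
#'   and the spline knots used.
#' @export
build_switch_design <- function(cohort, k_knots = NULL) {
  dt <- data.table::as.data.table(cohort)
  data.table::setkey(dt, person_id, k)
  pid <- dt$person_id

  cd4_locf <- locf_by(ifelse(dt$cd4_measured, as.numeric(dt$cd4_obs),
                             NA_real_), pid)
  if (anyNA(cd4_locf)) {
    stop("design error: person-intervals with no CD4 ever measured ",
         "(a baseline CD4 is required)", call. = FALSE)
  }

  e_w3 <- .eff_event(dt$ev_who3, dt$ev_who3_day, dt$switched, dt$switch_day)
  e_ca <- .eff_event(dt$ev_cand, dt$ev_cand_day, dt$switched, dt$switch_day)
  e_w4 <- .eff_event(dt$ev_who4, dt$ev_who4_day, dt$switched, dt$switch_day)
  e_tp <- .eff_event(dt$ev_tbp, dt$ev_tbp_day, dt$switched, dt$switch_day)
  e_te <- .eff_event(dt$ev_tbe, dt$ev_tbe_day, dt$switched, dt$switch_day)

  # lags computed once per source flag via data.table grouping (fast path)
  lag_mat <- function(raw) {
    tmp <- data.table::data.table(pid = pid, x = raw)
    as.matrix(tmp[, data.table::shift(x, 1:5, fill = FALSE), by = pid][, -1])
  }
  w3raw <- dt$ev_who3 | dt$ev_cand
  w4raw <- dt$ev_who4
  t3raw <- dt$ev_tbp
  t4raw <- dt$ev_tbe
  L3 <- lag_mat(w3raw); L4 <- lag_mat(w4raw)
  T3 <- lag_mat(t3raw); T4 <- lag_mat(t4raw)

  rec3 <- (e_w3 | e_ca) | L3[, 1L] | L3[, 2L]
  dis3 <- L3[, 3L] | L3[, 4L] | L3[, 5L]
  rec4 <- e_w4 | L4[, 1L] | L4[, 2L]
  dis4 <- L4[, 3L] | L4[, 4L] | L4[, 5L]
  trec3 <- e_tp | T3[, 1L] | T3[, 2L]
  tdis3 <- T3[, 3L] | T3[, 4L] | T3[, 5L]
  trec4 <- e_te | T4[, 1L] | T4[, 2L]
  tdis4 <- T4[, 3L] | T4[, 4L] | T4[, 5L]

  who5 <- .event_history_5cat(rec4, dis4, rec3, dis3)
  tb5 <- .event_history_5cat(trec4, tdis4, trec3, tdis3)

  keep <- dt$k >= 1L
  sel <- function(x) x[keep]

  if (is.null(k_knots)) {
    at_risk_k <- dt$k[keep & dt$on_first_line]
    k_knots <- unique(as.numeric(stats::quantile(at_risk_k, c(0.1, 0.5, 0.9),
                                                 type = 1)))
    if (length(k_knots) < 3L) {
      k_knots <- seq(min(at_risk_k), max(at_risk_k), length.out = 3L)
    }
    if (any(diff(k_knots) <= 0)) {
      stop("cannot place distinct interval-spline knots; cohort follow-up ",
           "too short", call. = FALSE)
    }
  }

  cr <- factor(paste0("c", dt$center, "r", dt$regimen))
  cr_dum <- if (nlevels(cr) > 1L) {
    stats::model.matrix(~ cr)[, -1L, drop = FALSE]
  } else {
    matrix(numeric(0), nrow = length(cr), ncol = 0L)
  }
  if (ncol(cr_dum)) {
    colnames(cr_dum) <- sub("^cr", "center_regimen:", colnames(cr_dum))
  }

  X <- cbind(
    `(Intercept)` = 1,
    rcs_basis(sel(dt$k), rcs_spec(k_knots, "k")),
    cr_dum[keep, , drop = FALSE],
    base_cd4_100_199 = as.numeric(sel(dt$base_cd4_cat) == "100-199"),
    base_cd4_ge200 = as.numeric(sel(dt$base_cd4_cat) == ">=200"),
    bmi_low = as.numeric(sel(dt$bmi_low)),
    hb_low = as.numeric(sel(dt$hb_low)),
    who4_wk24_48 = as.numeric(sel(dt$who4_wk24_48)),
    rcs_basis(sel(cd4_locf), rcs_spec(.cd4_knots, "cd4")),
    cotrim_72wk = as.numeric(sel(dt$cotrim_prev) * (sel(dt$k) < 6L)),
    miss_visits = as.numeric(sel(dt$miss_visits)),
    miss_doses = as.numeric(sel(dt$miss_doses)),
    .hist_dummies(sel(who5), "who")[, , drop = FALSE],
    .hist_dummies(sel(tb5), "tb")[, , drop = FALSE],
    who4_recent_x_cd4lt100 = as.numeric(sel(rec4) * (sel(cd4_locf) < 100))
  )

  list(X = X,
       person_id = sel(pid),
       k = sel(dt$k),
       y_switch = as.numeric(sel(dt$switched)),
       y_ltfu = as.numeric(sel(dt$ltfu)),
       risk_switch = sel(dt$on_first_line),
       prior_switch = as.numeric(!sel(dt$on_first_line)),
       cd4_locf = sel(cd4_locf),
       who5 = sel(who5), tb5 = sel(tb5),
       k_knots = k_knots, cd4_knots = .cd4_knots)
}

#' Design covariates for one person-interval
#'
#' Row-level view of [build_switch_design()]: the switch-model covariates
#' for one person at interval `k`, computed from that person's history up
#' to `k`.
#'
#' @param person_history person-period rows for one person.
#' @param at_k interval index.
#' @param k_knots interval-spline knots (defaults to percentile knots of
#'   the supplied history).
#' @return list with the numeric design vector `x` and the derived
#'   categorical summaries (`who_event_history_5cat`, `tb_history_5cat`,
#'   `cd4_locf`).
#' @export
build_design_row <- function(person_history, at_k, k_knots = NULL) {
  d <- build_switch_design(data.table::as.data.table(person_history),
                           k_knots = k_knots)
  i <- which(d$k == at_k)
  if (!length(i)) stop("no row at interval ", at_k, call. = FALSE)
  list(x = d$X[i, ],
       who_event_history_5cat = d$who5[i],
       tb_history_5cat = d$tb5[i],
       cd4_locf = d$cd4_locf[i])
}

# column indices spanning the column space of X (drops aliased columns);
# rank detected on the cheap Gram matrix
nonaliased_cols <- function(X, w = NULL) {
  cp <- if (is.null(w)) crossprod(X) else crossprod(X * sqrt(w))
  qq <- qr(cp)
  sort(qq$pivot[seq_len(qq$rank)])
}

# weighted logistic ML by Newton-Raphson with step-halving; crossprod-based
# so refits (bootstrap replicates, warm-started) cost a few matrix
# products. A tiny L2 penalty (`lambda`, never on the intercept, assumed
# to be column 1) keeps the optimum finite and Newton quadratically
# convergent when a rare covariate cell separates; at lambda = 1e-4 its
# effect on estimates is far below sampling noise.
fast_logit <- function(X, y, w = NULL, beta = NULL, eps = 1e-10,
                       maxit = 50L, lambda = 1e-4,
                       reuse_hessian = FALSE, hess_stride = 1L) {
  if (is.null(w)) w <- rep(1, length(y))
  p <- ncol(X)
  pen <- rep(lambda, p)
  if (colnames(X)[1L] == "(Intercept)") pen[1L] <- 0
  if (is.null(beta)) beta <- numeric(p)
  objf <- function(mu, b) {
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -2 * sum(w * (y * log(mu) + (1 - y) * log1p(-mu))) + sum(pen * b^2)
  }
  mu <- expit(drop(X %*% beta))
  obj <- objf(mu, beta)
  conv <- FALSE
  # curvature may be estimated on a row subsample (exact gradient keeps the
  # fixed point exact; step-halving guards the step quality)
  hsub <- hess_stride > 1L && nrow(X) > 10L * hess_stride
  if (hsub) {
    hidx <- seq(1L, nrow(X), by = hess_stride)
    Xh <- X[hidx, , drop = FALSE]
  }
  Hfact <- NULL
  # with a warm start the curvature barely moves: exact Newton for the
  # first steps, then reuse the factorization (refreshed on any stall)
  fresh_until <- if (reuse_hessian) 2L else maxit
  for (it in seq_len(maxit)) {
    g <- drop(crossprod(X, w * (y - mu))) - pen * beta
    if (is.null(Hfact) || it <= fresh_until) {
      if (hsub) {
        wwh <- pmax((w * mu * (1 - mu))[hidx], 1e-12)
        H <- hess_stride * crossprod(Xh * sqrt(wwh))
      } else {
        ww <- pmax(w * mu * (1 - mu), 1e-12)
        H <- crossprod(X * sqrt(ww))
      }
      diag(H) <- diag(H) + pen + 1e-10 * (mean(diag(H)) + 1)
      Hfact <- tryCatch(chol(H), error = function(e) {
        diag(H) <- diag(H) + 1e-6 * (mean(diag(H)) + 1)
        chol(H)
      })
    }
    step <- drop(backsolve(Hfact, backsolve(Hfact, g, transpose = TRUE)))
    eta_step <- drop(X %*% step)    # one matvec serves all halvings
    if (it == 1L) eta <- drop(X %*% beta)
    improved <- FALSE
    for (h in 0:10) {
      cand <- beta + step / 2^h
      eta_c <- eta + eta_step / 2^h
      mu_c <- expit(eta_c)
      obj_c <- objf(mu_c, cand)
      if (is.finite(obj_c) && obj_c <= obj + 1e-10) {
        moved <- abs(obj - obj_c)
        beta <- cand; mu <- mu_c; obj <- obj_c; eta <- eta_c
        improved <- TRUE
        break
      }
    }
    if (improved && moved < eps * (abs(obj) + 0.1)) { conv <- TRUE; break }
    if (!improved || h > 0L) {
      if (it > fresh_until) {
        fresh_until <- it + 2L   # stale curvature: refresh and retry
        Hfact <- NULL
        if (!improved) next
      } else if (!improved) {
        conv <- TRUE             # stalled at numerical precision
        break
      }
    }
  }
  list(coef = beta, converged = conv, deviance = obj, iterations = it)
}

# ML fit of a logistic model on a design matrix; aliased (collinear or
# empty) columns are dropped with a message, reported, and given zero
# coefficients so predictions can use the full design
fit_pooled_logit <- function(X, y, weights = NULL, label = "model") {
  if (is.null(weights)) weights <- rep(1, length(y))
  keep_cols <- nonaliased_cols(X[weights > 0, , drop = FALSE])
  aliased <- setdiff(colnames(X), colnames(X)[keep_cols])
  if (length(aliased)) {
    message(label, ": dropped ", length(aliased),
            " aliased/empty column(s): ", paste(aliased, collapse = ", "))
  }
  fit <- fast_logit(X[, keep_cols, drop = FALSE], y, w = weights)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[keep_cols] <- fit$coef
  list(coef = beta, converged = fit$converged, aliased = aliased,
       deviance = fit$deviance)
}

#' Fit the pooled logistic switch model
#'
#' Maximum-likelihood fit of the discrete-time (pooled logistic) model for
#' the probability of switching to second-line ART in interval `k`, on the
#' risk set of person-intervals alive and still on first-line ART.
#' Randomized group is never included.
#'
#' @param cohort person-period `data.table`.
#' @param design optional precomputed [build_switch_design()] output.
#' @return object of class `switch_fit` with the coefficient vector, spline
#'   knots, convergence diagnostics, number of switch events and
#'   person-intervals at risk.
#' @export
fit_switch_model <- function(cohort, design = NULL) {
  d <- design %||% build_switch_design(cohort)
  r <- d$risk_switch
  n_events <- sum(d$y_switch[r])
  if (n_events == 0) {
    stop("cannot fit switch model: no switches to second-line ART ",
         "in the cohort", call. = FALSE)
  }
  f <- fit_pooled_logit(d$X[r, , drop = FALSE], d$y_switch[r],
                        label = "switch model")
  if (!f$converged) {
    stop("switch model did not converge (possible separation)",
         call. = FALSE)
  }
  structure(list(coef = f$coef, k_knots = d$k_knots,
                 cd4_knots = d$cd4_knots, aliased = f$aliased,
                 converged = f$converged,
                 n_events = n_events, n_person_intervals = sum(r)),
            class = "switch_fit")
}

#' @export
print.switch_fit <- function(x, ...) {
  cat("<switch_fit> pooled logistic model for second-line switch\n")
  cat("  ", x$n_events, "switches /", x$n_person_intervals,
      "person-intervals at risk\n")
  cat("  ", length(x$coef), "coefficients; converged:", x$converged, "\n")
  invisible(x)
}

#' Predicted switch probability
#'
#' @param fit a `switch_fit`.
#' @param X design matrix (or single row) with the fit's columns.
#' @return vector of probabilities `P(switch in k)`, strictly inside (0,1);
#'   `1 - p` is the `p_A(k)` entering the strategy weights.
#' @export
predict_switch_prob <- function(fit, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, names(fit$coef)))
  if (!all(names(fit$coef) %in% colnames(X))) {
    stop("design error: row lacks columns required by the fit",
         call. = FALSE)
  }
  as.numeric(expit(X[, names(fit$coef), drop = FALSE] %*% fit$coef))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
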