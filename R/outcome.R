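# Weighted pooled logistic mortality model on the expanded (cloned) data,
# strategy encodings, survival prediction and contrasts.

#' Strategy encoding for the outcome model
#'
#' Maps strategies to the regression terms of the outcome model. Mode
#' `"hg"` encodes CD4-based switching strategies by their threshold as a
#' linear term `h` (0 for event-only strategies) plus one dummy `g` per
#' event-only strategy; mode `"f"` encodes monitoring-frequency strategies
#' as a categorical variable (first strategy = reference); mode `"none"`
#' fits a single strategy with interval terms only. Every encoding term is
#' interacted with the late-follow-up indicator `k_m` (interval begins more
#' than 96 weeks after baseline).
#'
#' @param strategies list of [strategy()] objects.
#' @param mode `"hg"`, `"f"`, or `"none"`.
#' @param h_form `"linear"` (threshold in cells/mm3, default),
#'   `"categorical"`, or `"spline"` (sensitivity variants for `h`).
#' @return object of class `strategy_encoding`: per-strategy rows of
#'   encoding columns.
#' @export
strategy_encoding <- function(strategies, mode = c("hg", "f", "none"),
                              h_form = c("linear", "categorical", "spline")) {
  mode <- match.arg(mode)
  h_form <- match.arg(h_form)
  if (inherits(strategies, "strategy")) strategies <- list(strategies)
  ids <- vapply(strategies, function(s) s$strategy_id, character(1))
  S <- length(strategies)
  if (mode == "none") {
    if (S != 1L) {
      stop("encoding mode 'none' requires exactly one strategy",
           call. = FALSE)
    }
    enc <- matrix(0, 1L, 0L)
  } else if (mode == "hg") {
    thr <- vapply(strategies, function(s) s$cd4_threshold, numeric(1))
    h <- ifelse(is.na(thr), 0, thr)
    ev_only <- which(is.na(thr))
    if (h_form == "linear") {
      enc <- cbind(h = h)
    } else if (h_form == "categorical") {
      lev <- sort(unique(h[h > 0]))
      enc <- vapply(lev, function(l) as.numeric(h == l), numeric(S))
      colnames(enc) <- paste0("h_", lev)
    } else {
      hk <- sort(unique(h[h > 0]))
      if (length(hk) < 3L) {
        stop("spline h(X) needs at least 3 distinct thresholds",
             call. = FALSE)
      }
      enc <- rcs_basis(h, rcs_spec(hk, "h"))
      enc[is.na(thr), ] <- 0
    }
    for (j in ev_only) {
      enc <- cbind(enc, as.numeric(seq_len(S) == j))
      colnames(enc)[ncol(enc)] <- paste0("g_", ids[j])
    }
  } else {
    enc <- if (S == 1L) matrix(0, 1L, 0L) else
      vapply(2:S, function(j) as.numeric(seq_len(S) == j),
             numeric(S))
    if (S > 1L) colnames(enc) <- paste0("f_", ids[-1L])
  }
  rownames(enc) <- ids
  structure(list(mode = mode, ids = ids, enc = enc),
            class = "strategy_encoding")
}

# late-follow-up indicator: interval j begins more than 96 weeks (672 days)
# after baseline; the row at risk interval k predicts death in j = k + 1
.km_of_outcome_interval <- function(k) as.numeric(28 * (k + 1L) > 672)

# outcome risk rows from an annotated clone table: alive through k,
# uncensored by the strategy through k, not censored by LTFU/STI through
# k + 1, with the death-in-(k+1) outcome
outcome_rows <- function(clones_w, outcome = c("death", "death_or_ltfu")) {
  outcome <- match.arg(outcome)
  cl <- data.table::as.data.table(clones_w)
  data.table::setkey(cl, strategy_id, person_id, k)
  last <- cl[, list(T_last = max(k), death_last = death[.N],
                    ltfu_last = ltfu[.N]),
             by = c("strategy_id", "person_id")]
  cl <- merge(cl, last, by = c("strategy_id", "person_id"), sort = FALSE)
  if (outcome == "death") {
    end_k <- ifelse(cl$ltfu_last, cl$T_last - 2L, cl$T_last - 1L)
    y <- as.numeric(cl$death_last & cl$k + 1L == cl$T_last)
  } else {
    end_k <- cl$T_last - 1L
    y <- as.numeric((cl$death_last | cl$ltfu_last) &
                      cl$k + 1L == cl$T_last)
  }
  # STI substudy participants are censored from their entry interval
  sti_end <- ifelse(cl$substudy == "STI" & !is.na(cl$substudy_entry),
                    cl$substudy_entry - 2L, Inf)
  keep <- cl$k <= pmin(end_k, sti_end) & cl$k < cl$censor_from
  cl$y_death <- y
  cl[keep]
}

#' Fit the weighted pooled logistic outcome model
#'
#' Fits, on the expanded clone data, the discrete-time mortality model:
#' logit P(death in k+1 | alive and uncensored through k) = interval spline
#' + strategy encoding + encoding-by-late-follow-up interactions, weighted
#' by the truncated cumulative weight through interval `k`. Risk rows with
#' zero weight are excluded. Randomized group is never included.
#'
#' @param clones_w clone table with weights, from [combine_truncate()].
#' @param strategies the strategy list used to expand the clones.
#' @param encoding a [strategy_encoding()] (or a mode string).
#' @param k_knots interval-spline knots (percentiles of the at-risk
#'   distribution when `NULL`).
#' @param outcome `"death"` (default) or `"death_or_ltfu"` (sensitivity
#'   re-definition; LTFU weights should be 1 in that case).
#' @return object of class `outcome_fit`.
#' @export
fit_outcome_model <- function(clones_w, strategies, encoding = "hg",
                              k_knots = NULL,
                              outcome = c("death", "death_or_ltfu")) {
  outcome <- match.arg(outcome)
  if (is.character(encoding)) {
    encoding <- strategy_encoding(strategies, encoding)
  }
  rows <- outcome_rows(clones_w, outcome)
  w <- rows$truncated_weight
  rows <- rows[w > 0]
  w <- w[w > 0]
  if (sum(rows$y_death) == 0) {
    stop("cannot fit outcome model: no deaths in the uncensored ",
         "clone-intervals", call. = FALSE)
  }
  if (is.null(k_knots)) {
    k_knots <- unique(as.numeric(stats::quantile(rows$k, c(0.1, 0.5, 0.9),
                                                 type = 1)))
    if (length(k_knots) < 3L) {
      k_knots <- seq(min(rows$k), max(rows$k), length.out = 3L)
    }
  }
  X <- outcome_design(rows$k, rows$strategy_id, encoding, k_knots)
  f <- fit_pooled_logit(X, rows$y_death, weights = w,
                        label = "outcome model")
  structure(list(coef = f$coef, k_knots = k_knots, encoding = encoding,
                 aliased = f$aliased, converged = f$converged,
                 n_deaths = sum(rows$y_death),
                 n_rows = nrow(rows), max_k = max(rows$k)),
            class = "outcome_fit")
}

# design matrix of the outcome model for given risk intervals and strategy
# membership
outcome_design <- function(k, strategy_id, encoding, k_knots) {
  km <- .km_of_outcome_interval(k)
  base <- cbind(`(Intercept)` = 1, rcs_basis(k, rcs_spec(k_knots, "k")))
  P <- ncol(encoding$enc)
  if (P == 0L) return(base)
  si <- match(strategy_id, encoding$ids)
  E <- encoding$enc[si, , drop = FALSE]
  Ekm <- E * km
  colnames(Ekm) <- paste0(colnames(E), ":km")
  cbind(base, E, Ekm)
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("<outcome_fit> weighted pooled logistic mortality model\n")
  cat("  encoding:", x$encoding$mode, " deaths:", x$n_deaths,
      " clone-intervals:", x$n_rows, "\n")
  invisible(x)
}

#' Predict a counterfactual survival curve
#'
#' Survival under one strategy from the fitted outcome model:
#' `S(K) = prod_{k < K} (1 - expit(linear predictor at k))`.
#'
#' @param fit an `outcome_fit`.
#' @param strategy_id id of a strategy in the fit's encoding.
#' @param horizon number of intervals (requires `horizon - 1 <=` the
#'   largest fitted risk interval).
#' @return object of class `survival_curve` with `S` over intervals
#'   `0..horizon`.
#' @export
predict_survival_curve <- function(fit, strategy_id, horizon) {
  if (!strategy_id %in% fit$encoding$ids) {
    stop("strategy '", strategy_id, "' not in the fitted encoding",
         call. = FALSE)
  }
  if (horizon - 1L > fit$max_k) {
    stop("extrapolation error: horizon ", horizon,
         " exceeds fitted interval range (max risk interval ",
         fit$max_k, ")", call. = FALSE)
  }
  kk <- 0:(horizon - 1L)
  X <- outcome_design(kk, rep(strategy_id, length(kk)), fit$encoding,
                      fit$k_knots)
  haz <- as.numeric(expit(X[, names(fit$coef), drop = FALSE] %*% fit$coef))
  structure(list(strategy_id = strategy_id,
                 S = c(1, cumprod(1 - haz)),
                 hazard = haz,
                 lower = NULL, upper = NULL, B = 0L, replicates = NULL),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  K <- length(x$S) - 1L
  cat("<survival_curve>", x$strategy_id, "\n")
  show <- unique(pmin(c(12, 24, 48, 60, K), K))
  for (k in show) {
    ci <- if (!is.null(x$lower)) {
      sprintf(" (95%% CI: %.3f, %.3f)", x$lower[k + 1L], x$upper[k + 1L])
    } else ""
    cat(sprintf("  S(%d wk) = %.3f%s\n", 4 * k, x$S[k + 1L], ci))
  }
  invisible(x)
}

#' Survival difference between two strategies
#'
#' `S_A(K) - S_B(K)` with a percentile confidence interval from paired
#' bootstrap replicate differences when both curves carry replicates.
#'
#' @param curve_a,curve_b `survival_curve` objects (from the same fit or
#'   bootstrap run).
#' @param at_interval horizon `K` in intervals.
#' @return list with `difference`, and `lower`/`upper` when replicates are
#'   available.
#' @export
survival_contrast <- function(curve_a, curve_b, at_interval) {
  i <- at_interval + 1L
  if (i > length(curve_a$S) || i > length(curve_b$S)) {
    stop("at_interval beyond curve horizon", call. = FALSE)
  }
  out <- list(strategy_a = curve_a$strategy_id,
              strategy_b = curve_b$strategy_id,
              at_interval = at_interval,
              difference = curve_a$S[i] - curve_b$S[i])
  if (!is.null(curve_a$replicates) || !is.null(curve_b$replicates)) {
    if (is.null(curve_a$replicates) || is.null(curve_b$replicates) ||
        nrow(curve_a$replicates) != nrow(curve_b$replicates)) {
      stop("data error: curves carry mismatched bootstrap replicates",
           call. = FALSE)
    }
    d <- curve_a$replicates[, i] - curve_b$replicates[, i]
    qs <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
    out$lower <- qs[1L]
    out$upper <- qs[2L]
  }
  out
}
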