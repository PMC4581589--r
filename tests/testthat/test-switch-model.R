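test_that("event-history categories use highest-level dominance", {
  # WHO3 at k-1 and non-Candida WHO4 at k-4: the distal WHO4 dominates
  h <- person_history(12L, events = list(
    list(type = "who3", k = 7L, day = 3L),
    list(type = "who4", k = 4L, day = 10L)))
  row <- build_design_row(h, at_k = 8L)
  expect_equal(row$who_event_history_5cat, "who4_distal")
  # only the recent WHO3 at k-1
  h2 <- person_history(15L, events = list(list(type = "who3", k = 7L,
                                               day = 3L)))
  expect_equal(build_design_row(h2, 8L)$who_event_history_5cat,
               "who3_recent")
  expect_equal(build_design_row(h2, 11L)$who_event_history_5cat,
               "who3_distal")
  # nothing within the 6-interval window
  expect_equal(build_design_row(h2, 13L)$who_event_history_5cat, "none")
  # tuberculosis is tracked separately
  h3 <- person_history(12L, events = list(list(type = "tbe", k = 7L,
                                               day = 3L)))
  r3 <- build_design_row(h3, 8L)
  expect_equal(r3$tb_history_5cat, "who4_recent")
  expect_equal(r3$who_event_history_5cat, "none")
})

test_that("current CD4 is carried forward from the last measurement", {
  h <- person_history(12L, cd4 = c(300L, 250L, 180L, 120L))
  expect_equal(build_design_row(h, 6L)$cd4_locf, 180)
  expect_equal(build_design_row(h, 8L)$cd4_locf, 180)
  expect_equal(build_design_row(h, 9L)$cd4_locf, 120)
})

test_that("cotrimoxazole term is zero outside the first 72 weeks on ART", {
  h <- person_history(12L)
  h$cotrim_prev <- TRUE
  # interval 5 starts 48 + 20 = 68 weeks after ART start: inside the window
  expect_equal(unname(build_design_row(h, 5L)$x["cotrim_72wk"]), 1)
  # interval 8 starts 80 weeks after ART start: outside
  expect_equal(unname(build_design_row(h, 8L)$x["cotrim_72wk"]), 0)
})

test_that("same-interval events count only when they precede the switch", {
  ev <- list(list(type = "who4", k = 5L, day = 20L))
  before <- person_history(12L, events = ev, switch_k = 5L, switch_day = 25L)
  after <- person_history(12L, events = ev, switch_k = 5L, switch_day = 10L)
  expect_equal(build_design_row(before, 5L)$who_event_history_5cat,
               "who4_recent")
  expect_equal(build_design_row(after, 5L)$who_event_history_5cat, "none")
})

test_that("switch model fit is sane and satisfies the score equation", {
  coh <- fixture_cohort()
  fit <- suppressMessages(fit_switch_model(coh))
  expect_s3_class(fit, "switch_fit")
  expect_true(fit$converged)
  expect_equal(fit$n_events, sum(coh$switched))
  d <- build_switch_design(coh, k_knots = fit$k_knots)
  p <- predict_switch_prob(fit, d$X[d$risk_switch, , drop = FALSE])
  expect_true(all(p > 0 & p < 1))
  # unpenalized intercept: predicted switches sum to observed switches
  expect_lt(abs(sum(p) - fit$n_events) / fit$n_events, 1e-6)
})

test_that("prediction equals the direct dot-product oracle", {
  coh <- fixture_cohort()
  fit <- suppressMessages(fit_switch_model(coh))
  d <- build_switch_design(coh, k_knots = fit$k_knots)
  i <- which(d$risk_switch)[5L]
  p <- predict_switch_prob(fit, d$X[i, ])
  oracle <- 1 / (1 + exp(-sum(d$X[i, names(fit$coef)] * fit$coef)))
  expect_lt(abs(p - oracle), 1e-10)
})

test_that("fit is invariant to person ordering", {
  coh <- generate_cohort(sim_config(n_individuals = 150L, n_intervals = 20L,
                                    seed = 61L))
  fit1 <- suppressMessages(fit_switch_model(coh))
  shuffled <- coh[sample(nrow(coh))]
  fit2 <- suppressMessages(fit_switch_model(shuffled))
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-6)
})

test_that("a cohort with no switches fails informatively", {
  coh <- fixture_cohort()
  ns <- data.table::copy(coh)
  ns$switched <- FALSE
  ns$switch_day <- NA_integer_
  ns$on_first_line <- TRUE
  expect_error(fit_switch_model(ns), "no switches")
})

test_that("the fitter matches stats::glm on a plain logistic problem", {
  set.seed(42)
  n <- 4000
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.3))
  eta <- -2 + 0.8 * X[, 2] - 0.5 * X[, 3]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  f <- dynmsm:::fast_logit(X, y)
  g <- stats::glm.fit(X, y, family = stats::binomial(),
                      control = list(epsilon = 1e-12))
  expect_equal(unname(f$coef), unname(g$coefficients), tolerance = 1e-4)
})

test_that("switch model recovers a known event-driven mechanism", {
  # mechanism: logit P(switch) = a + b * I(WHO4-level event in k-2..k),
  # identical across arms, no CD4 response, no TB events; the design's
  # recent-WHO4 dummy then spans the truth
  b_true <- 2.5
  hits <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      n_individuals = 2000L, n_intervals = 40L,
      switch_behavior = list(lcm_intercept = -5.5, cdm_intercept = -5.5,
                             lcm_cd4_lt100 = 0, lcm_cd4_lt50 = 0,
                             who4_recent = b_true, who3_recent = 0),
      event_hazards = list(who3 = c(-5.4, 0.3), esoph_candida = c(-6.7, 0.35),
                           who4_noncandida = c(-4.6, 0.4),
                           tb_pulmonary = c(-30, 0), tb_extrapulmonary = c(-30, 0)),
      seed = 700L + r)
    coh <- generate_cohort(cfg)
    fit <- suppressMessages(fit_switch_model(coh))
    est <- fit$coef[["who_who4_recent"]]
    d <- build_switch_design(coh, k_knots = fit$k_knots)
    # rough 95% CI from the observed information (non-aliased columns)
    p <- predict_switch_prob(fit, d$X[d$risk_switch, , drop = FALSE])
    keep <- setdiff(names(fit$coef), fit$aliased)
    X <- d$X[d$risk_switch, keep, drop = FALSE]
    H <- crossprod(X * sqrt(p * (1 - p)))
    se <- sqrt(diag(solve(H)))[which(keep == "who_who4_recent")]
    if (abs(est - b_true) <= 1.96 * se) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 2L)
})
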