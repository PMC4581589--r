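# shared small setup: fitted switch probabilities on the fixture cohort
.weights_setup <- function() {
  if (is.null(.fix_env$wsetup)) {
    coh <- fixture_cohort()
    fit <- suppressMessages(fit_switch_model(coh))
    d <- build_switch_design(coh, k_knots = fit$k_knots)
    p_A <- data.table::data.table(
      person_id = d$person_id[d$risk_switch],
      k = d$k[d$risk_switch],
      p_A = 1 - predict_switch_prob(fit, d$X[d$risk_switch, , drop = FALSE]))
    .fix_env$wsetup <- list(cohort = coh, fit = fit, p_A = p_A)
  }
  .fix_env$wsetup
}

test_that("grace-period weight factors follow the printed arithmetic", {
  # one person, eligible at 4, never switches: factors at r = 0, 1, 2
  h <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L))
  cl <- expand_clones(h, list(strategy("s", cd4_threshold = 100)))
  p_A <- data.table::data.table(person_id = 1L, k = 1:11, p_A = 0.9)
  w <- strategy_weight_series(cl, p_A)
  # pre-eligibility intervals 1..3: 1/0.9 each
  expect_equal(w$w_factor[w$k %in% 1:3], rep(1 / 0.9, 3))
  # r = 0, no switch: (1 - 1/3)/0.9
  expect_equal(w$w_factor[w$k == 4L], (1 - 1 / 3) / 0.9)
  expect_equal(w$strategy_weight[w$k == 4L],
               (1 / 0.9)^3 * (1 - 1 / 3) / 0.9)
  # r = 1, no switch: (1 - 1/2)/0.9
  expect_equal(w$w_factor[w$k == 5L], (1 - 1 / 2) / 0.9)
  # r = 2, no switch: numerator exhausted, weight 0 from here
  expect_equal(w$strategy_weight[w$k == 6L], 0)
  # censored rows carry weight 0
  expect_true(all(w$strategy_weight[w$k >= 7L] == 0))

  # switching at r = 1 contributes (1/2)/(1 - p_A) and then stays flat
  h2 <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L), switch_k = 5L)
  cl2 <- expand_clones(h2, list(strategy("s", cd4_threshold = 100)))
  w2 <- strategy_weight_series(cl2, p_A)
  expect_equal(w2$w_factor[w2$k == 5L], (1 / 2) / (1 - 0.9))
  expect_equal(w2$strategy_weight[w2$k == 11L],
               (1 / 0.9)^3 * ((1 - 1 / 3) / 0.9) * (1 / 2) / (1 - 0.9))
})

test_that("weight series equals the brute-force formula oracle", {
  ws <- .weights_setup()
  strats <- list(strategy("a", cd4_threshold = 100), strategy("b"))
  cl <- expand_clones(ws$cohort, strats)
  w <- strategy_weight_series(cl, ws$p_A)
  for (st in strats) {
    sub <- w[w$strategy_id == st$strategy_id]
    for (pid in sample(unique(sub$person_id), 40L)) {
      rows <- as.data.frame(ws$cohort[ws$cohort$person_id == pid])
      ora <- oracle_weight_series(rows, st,
                                  ws$p_A[ws$p_A$person_id == pid])
      got <- sub$strategy_weight[sub$person_id == pid]
      expect_lt(max(abs(got - ora)), 1e-12)
    }
  }
})

test_that("positivity violations raise errors instead of huge weights", {
  h <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L))
  cl <- expand_clones(h, list(strategy("s", cd4_threshold = 100)))
  bad <- data.table::data.table(person_id = 1L, k = 1:11,
                                p_A = c(1e-9, rep(0.9, 10)))
  expect_error(strategy_weight_series(cl, bad),
               class = "dynmsm_positivity_error")
  h2 <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L), switch_k = 4L)
  cl2 <- expand_clones(h2, list(strategy("s", cd4_threshold = 100)))
  bad2 <- data.table::data.table(person_id = 1L, k = 1:11,
                                 p_A = c(rep(0.9, 3), 1 - 1e-9,
                                         rep(0.9, 7)))
  expect_error(strategy_weight_series(cl2, bad2),
               class = "dynmsm_positivity_error")
})

test_that("substudy upweights follow the stratum formula", {
  coh <- fixture_cohort()
  sw <- substudy_weights(coh)
  merged <- merge(sw, coh[, c("person_id", "k", "substudy",
                              "substudy_entry", "stratum")],
                  by = c("person_id", "k"))
  # STI: 0 from entry; before entry: 1
  sti <- merged[merged$substudy == "STI"]
  expect_true(all(sti$substudy_weight[sti$k >= sti$substudy_entry] == 0))
  expect_true(all(sti$substudy_weight[sti$k < sti$substudy_entry] == 1))
  # CT weight equals (n_STI + n_CT)/n_CT in the stratum
  per <- unique(coh[coh$substudy != "none",
                    c("person_id", "substudy", "stratum")])
  for (stv in unique(per$stratum)) {
    n_sti <- sum(per$substudy == "STI" & per$stratum == stv)
    n_ct <- sum(per$substudy == "CT" & per$stratum == stv)
    ct_rows <- merged[merged$substudy == "CT" & merged$stratum == stv &
                        merged$k >= merged$substudy_entry]
    expect_equal(unique(ct_rows$substudy_weight), (n_sti + n_ct) / n_ct)
    expect_lt(abs(unique(ct_rows$substudy_weight) - 2), 0.5)
  }
  # everyone else: 1
  expect_true(all(merged$substudy_weight[merged$substudy == "none"] == 1))

  # no substudy at all: weights identically 1
  cfg <- sim_config(n_individuals = 30L, n_intervals = 10L,
                    substudy = list(fraction = 0, entry_interval = 1L),
                    seed = 71L)
  expect_true(all(substudy_weights(generate_cohort(cfg))$substudy_weight == 1))
})

test_that("an STI stratum with no continuous-therapy persons is a positivity error", {
  coh <- data.table::copy(fixture_cohort())
  # force one stratum to lose its CT members
  target <- coh$stratum == coh$stratum[coh$substudy == "STI"][1L]
  coh$substudy[target & coh$substudy == "CT"] <- "STI"
  expect_error(substudy_weights(coh), class = "dynmsm_positivity_error")
})

test_that("LTFU weights are exactly 1 when no one is lost", {
  cfg <- sim_config(n_individuals = 60L, n_intervals = 15L,
                    ltfu_hazard = 0, seed = 81L)
  lw <- ltfu_weight_series(generate_cohort(cfg))
  expect_true(all(lw$ltfu_weight == 1))
})

test_that("LTFU weights are the cumulative product of inverse retention", {
  coh <- fixture_cohort()
  lw <- suppressMessages(ltfu_weight_series(coh))
  # non-decreasing within person
  mono <- lw[, list(ok = all(diff(ltfu_weight) >= 0)), by = "person_id"]
  expect_true(all(mono$ok))
  # closed-form check against the fitted per-interval probabilities
  for (pid in sample(unique(lw$person_id), 30L)) {
    rows <- lw[lw$person_id == pid]
    expect_lt(max(abs(rows$ltfu_weight - cumprod(1 / (1 - rows$p_ltfu)))),
              1e-8)
  }
})

test_that("combining truncates the product at the cap", {
  ws <- .weights_setup()
  st <- list(strategy("a", cd4_threshold = 100))
  cl <- expand_clones(ws$cohort, st)
  w <- strategy_weight_series(cl, ws$p_A)
  sub <- substudy_weights(ws$cohort)
  lw <- suppressMessages(ltfu_weight_series(ws$cohort))
  comb <- combine_truncate(w, sub, lw, cap = 10)
  expect_true(all(comb$truncated_weight <= 10))
  expect_equal(comb$truncated_weight, pmin(comb$raw_weight, 10))
  expect_equal(comb$raw_weight,
               comb$strategy_weight * comb$substudy_weight * comb$ltfu_weight)
  # cap = Inf keeps the raw product
  raw <- combine_truncate(w, sub, lw, cap = Inf)
  expect_equal(raw$truncated_weight, raw$raw_weight)
  # synthetic spot values for the truncation rule itself
  expect_equal(pmin(c(37.2, 2.5), 10), c(10, 2.5))
})

test_that("the uniform grace numerator distributes switch mass that sums to 1", {
  expect_equal(grace_switch_distribution(3L), rep(1 / 3, 3))
  expect_equal(sum(grace_switch_distribution(5L)), 1)
  expect_equal(grace_switch_distribution(1L), 1)
})

test_that("weighted at-risk mass tracks the source-cohort at-risk count", {
  coh <- generate_cohort(sim_config(seed = 31337L))
  st <- list(strategy("cd4_lt100", cd4_threshold = 100))
  fit <- suppressMessages(fit_switch_model(coh))
  d <- build_switch_design(coh, k_knots = fit$k_knots)
  pA_tab <- data.table::data.table(
    person_id = d$person_id[d$risk_switch], k = d$k[d$risk_switch],
    p_A = 1 - predict_switch_prob(fit, d$X[d$risk_switch, , drop = FALSE]))
  w <- combine_truncate(
    strategy_weight_series(expand_clones(coh, st), pA_tab),
    substudy_weights(coh), suppressMessages(ltfu_weight_series(coh)))
  for (kk in c(6L, 12L, 24L, 40L)) {
    rows <- coh[coh$k == kk]
    at_risk <- sum(rows$substudy != "STI" | kk < rows$substudy_entry)
    mass <- sum(w$truncated_weight[w$k == kk])
    expect_lt(abs(mass / at_risk - 1), 0.15)
  }
})
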