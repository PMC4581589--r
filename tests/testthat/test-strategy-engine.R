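test_that("strategy construction validates its fields", {
  expect_error(strategy("s", cd4_threshold = 300), "\\(0, 250\\)")
  expect_error(strategy("s", event_triggers = "who5"), "subset")
  expect_error(strategy("s", grace_intervals = 0), "grace")
  expect_error(strategy("s", monitoring_weeks = c(0, 6)), "multiples of 4")
})

test_that("observed CD4 series honors the monitoring schedule", {
  h <- person_history(27L, cd4 = c(300L, 280L, 260L, 240L, 220L, 200L,
                                   180L, 160L, 140L))
  full <- observed_cd4_series(h, seq(0, 96, by = 12))
  expect_equal(full$k, seq(0L, 24L, by = 3L))
  expect_equal(full$cd4_obs, h$cd4_obs[h$cd4_measured])
  base <- observed_cd4_series(h, 0)
  expect_equal(nrow(base), 1L)
  expect_equal(base$k, 0L)
  none <- observed_cd4_series(h, numeric(0))
  expect_equal(nrow(none), 0L)
  s48 <- observed_cd4_series(h, c(0, 48, 96))
  expect_equal(s48$k, c(0L, 12L, 24L))
  expect_error(observed_cd4_series(h, c(0, 16)), "12-weekly")
})

test_that("CD4 eligibility starts the interval after the low measurement", {
  # week 0: 150, week 12 (interval 3): 90 -> eligible from interval 4
  h <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L))
  el <- eligibility_interval(h, strategy("s", cd4_threshold = 100))
  expect_equal(el$Q, 4L)
  expect_equal(el$reason, "cd4")
})

test_that("tie-breaker blocks WHO4 triggers at high CD4", {
  h <- person_history(12L, cd4 = rep(300L, 4),
                      events = list(list(type = "who4", k = 7L, day = 5L)))
  st <- strategy("s")
  expect_true(is.na(eligibility_interval(h, st)$Q))
  # ignoring the restriction restores the trigger in the event interval
  st2 <- strategy("s2", who4_ignore_cd4_restriction = TRUE)
  el <- eligibility_interval(h, st2)
  expect_equal(el$Q, 7L)
  expect_equal(el$reason, "event")
  # with no CD4 ever observed the restriction is vacuously satisfied
  st3 <- strategy("s3", monitoring_weeks = numeric(0))
  expect_equal(eligibility_interval(h, st3)$Q, 7L)
})

test_that("no qualifying trigger means never eligible", {
  h <- person_history(12L, cd4 = rep(300L, 4))
  expect_true(is.na(eligibility_interval(h, strategy("s",
                                                     cd4_threshold = 100))$Q))
})

test_that("two-WHO3 trigger needs a second WHO3-level event", {
  st <- strategy("s", event_triggers = "two_who3", tiebreaker_cd4 = NA)
  h1 <- person_history(12L, events = list(list(type = "who3", k = 3L,
                                               day = 2L)))
  expect_true(is.na(eligibility_interval(h1, st)$Q))
  h2 <- person_history(12L, events = list(
    list(type = "who3", k = 3L, day = 2L),
    list(type = "cand", k = 6L, day = 9L)))
  expect_equal(eligibility_interval(h2, st)$Q, 6L)
})

test_that("lagged-events variant shifts event eligibility one interval", {
  h <- person_history(12L, cd4 = rep(200L, 4),
                      events = list(list(type = "who4", k = 5L, day = 3L)))
  expect_equal(eligibility_interval(h, strategy("s"))$Q, 5L)
  expect_equal(eligibility_interval(h, strategy("s", lag_events_4wk = TRUE))$Q,
               6L)
})

test_that("extrapulmonary TB exclusion removes that trigger", {
  h <- person_history(12L, cd4 = rep(200L, 4),
                      events = list(list(type = "tbe", k = 4L, day = 8L)))
  expect_equal(eligibility_interval(h, strategy("s"))$Q, 4L)
  expect_true(is.na(eligibility_interval(
    h, strategy("s", exclude_extrapulmonary_tb = TRUE))$Q))
})

test_that("censoring follows the grace-period rules", {
  st <- strategy("s", cd4_threshold = 100)
  # eligible at 4 (week-12 CD4 of 90), switch at 5 -> compatible
  h <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L), switch_k = 5L)
  expect_true(is.na(censor_time(h, st)))
  # never switches and survives -> censored at entry to Q + 3 = 7
  h2 <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L))
  expect_equal(censor_time(h2, st), 7L)
  # pre-eligibility switch -> censored at the switch interval
  h3 <- person_history(12L, cd4 = rep(300L, 4), switch_k = 2L)
  expect_equal(censor_time(h3, st), 2L)
  # death before the would-be censoring point -> natural end, no censoring
  h4 <- person_history(12L, cd4 = c(150L, 90L, 90L, 90L), death_k = 5L)
  expect_true(is.na(censor_time(h4, st)))
  # same-interval event after the switch does not qualify; censored at switch
  h5 <- person_history(12L, cd4 = rep(200L, 4), switch_k = 5L,
                       switch_day = 10L,
                       events = list(list(type = "who4", k = 5L, day = 20L)))
  expect_equal(censor_time(h5, strategy("ev")), 5L)
})

test_that("clone expansion copies rows and flags censoring monotonically", {
  coh <- fixture_cohort()
  strats <- list(strategy("a", cd4_threshold = 100),
                 strategy("b", cd4_threshold = 50),
                 strategy("c"))
  cl <- expand_clones(coh, strats)
  expect_equal(length(unique(paste(cl$strategy_id, cl$person_id))),
               3L * length(unique(coh$person_id)))
  expect_equal(nrow(cl), 3L * nrow(coh))
  # clone rows equal source rows field-by-field before censoring
  a <- cl[cl$strategy_id == "a"]
  shared <- intersect(names(coh), names(a))
  expect_equal(as.data.frame(a[a$Cx == 0L, shared, with = FALSE]),
               as.data.frame(merge(coh, unique(a[a$Cx == 0L,
                                                 c("person_id", "k")]),
                                   by = c("person_id", "k"))[, shared,
                                                             with = FALSE]),
               ignore_attr = TRUE)
  # Cx monotone within clone
  mono <- cl[, list(ok = all(diff(Cx) >= 0)), by = c("strategy_id",
                                                     "person_id")]
  expect_true(all(mono$ok))
  expect_error(expand_clones(coh, list(strategy("a"), strategy("a"))),
               "duplicate")
})

test_that("eligibility matches the rule-trace oracle across the fixture", {
  coh <- fixture_cohort()
  strats <- list(strategy("a", cd4_threshold = 100),
                 strategy("b", cd4_threshold = 50),
                 strategy("c"),
                 strategy("d", event_triggers = c("who4", "two_who3")),
                 strategy("e", cd4_threshold = 100, monitoring_weeks = 0))
  for (st in strats) {
    el <- dynmsm:::strategy_eligibility(coh, st)
    pids <- sample(el$person_id, 60L)
    for (pid in pids) {
      rows <- as.data.frame(coh[coh$person_id == pid])
      o <- oracle_eligibility(rows, st)
      got <- el$Q[el$person_id == pid]
      expect_equal(got, o$Q,
                   info = sprintf("person %d strategy %s", pid,
                                  st$strategy_id))
      sk <- el$switch_k[el$person_id == pid]
      expect_equal(el$censor_from[el$person_id == pid],
                   oracle_censor(o$Q, sk, st$grace_intervals - 1L))
    }
  }
})

test_that("threshold and monitoring monotonicity of eligibility", {
  coh <- fixture_cohort()
  el100 <- dynmsm:::strategy_eligibility(coh, strategy("a", cd4_threshold = 100))
  el50 <- dynmsm:::strategy_eligibility(coh, strategy("b", cd4_threshold = 50))
  m <- merge(el100[, c("person_id", "Q")], el50[, c("person_id", "Q")],
             by = "person_id")
  both <- !is.na(m$Q.x) & !is.na(m$Q.y)
  # lowering the threshold never makes eligibility earlier
  expect_true(all(m$Q.y[both] >= m$Q.x[both]))
  expect_true(all(is.na(m$Q.y[is.na(m$Q.x)])))

  # coarsening the schedule never makes a CD4-triggered Q earlier
  cd4_only <- function(weeks) strategy(paste0("w", length(weeks)),
                                       cd4_threshold = 100,
                                       event_triggers = character(0),
                                       monitoring_weeks = weeks)
  fine <- dynmsm:::strategy_eligibility(coh, cd4_only(seq(0, 116, by = 12)))
  coarse <- dynmsm:::strategy_eligibility(coh, cd4_only(seq(0, 116, by = 24)))
  m2 <- merge(fine[, c("person_id", "Q")], coarse[, c("person_id", "Q")],
              by = "person_id")
  both2 <- !is.na(m2$Q.x) & !is.na(m2$Q.y)
  expect_true(all(m2$Q.y[both2] >= m2$Q.x[both2]))
})
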