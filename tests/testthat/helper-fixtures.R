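# shared fixtures, generated once per test run

.fix_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fix_env$cohort)) .fix_env$cohort <- dynmsm::fixture_cohort()
  .fix_env$cohort
}

# hand-built single-person history for rule-trace tests; CD4 measured
# 12-weekly, events/switches injected via arguments
person_history <- function(n_intervals = 12L,
                           cd4 = rep(300L, ceiling(n_intervals / 3)),
                           events = list(), switch_k = NA_integer_,
                           switch_day = 27L, death_k = NA_integer_,
                           ltfu_k = NA_integer_) {
  ks <- 0:(n_intervals - 1L)
  end <- min(death_k, ltfu_k, n_intervals - 1L, na.rm = TRUE)
  ks <- ks[ks <= end]
  n <- length(ks)
  meas <- ks %% 3L == 0L
  cd4v <- rep(NA_integer_, n)
  cd4v[meas] <- cd4[seq_len(sum(meas))]
  dt <- data.table::data.table(
    person_id = 1L, arm = "LCM", k = ks, center = 1L, regimen = 1L,
    base_cd4 = cd4[1L], base_cd4_cat = if (cd4[1L] < 100) "<100" else
      if (cd4[1L] < 200) "100-199" else ">=200",
    bmi_low = FALSE, hb_low = FALSE, who4_wk24_48 = FALSE,
    cotrim_prev = FALSE, stratum = "1:LCM",
    on_first_line = is.na(switch_k) | ks <= switch_k,
    switched = !is.na(switch_k) & ks == switch_k,
    switch_day = ifelse(!is.na(switch_k) & ks == switch_k, switch_day,
                        NA_integer_),
    cd4_measured = meas, cd4_obs = cd4v, cd4_true = NA_integer_,
    ev_who3 = FALSE, ev_who3_day = NA_integer_,
    ev_cand = FALSE, ev_cand_day = NA_integer_,
    ev_who4 = FALSE, ev_who4_day = NA_integer_,
    ev_tbp = FALSE, ev_tbp_day = NA_integer_,
    ev_tbe = FALSE, ev_tbe_day = NA_integer_,
    miss_visits = FALSE, miss_doses = FALSE,
    death = !is.na(death_k) & ks == death_k,
    ltfu = !is.na(ltfu_k) & ks == ltfu_k,
    substudy = "none", substudy_entry = NA_integer_)
  for (ev in events) {
    col <- paste0("ev_", ev$type)
    i <- which(dt$k == ev$k)
    data.table::set(dt, i, col, TRUE)
    data.table::set(dt, i, paste0(col, "_day"), as.integer(ev$day))
  }
  data.table::setkey(dt, person_id, k)
  dt
}
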