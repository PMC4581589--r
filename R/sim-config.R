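#' Configuration for the synthetic person-period cohort generator
#'
#' Parameters of the data-generating mechanism for a two-arm (LCM/CDM)
#' HIV cohort followed in 4-weekly intervals after 48 weeks of first-line
#' antiretroviral therapy. Latent true CD4 evolves on the square-root scale
#' by a drifted autoregressive walk; observed CD4 adds measurement noise on
#' the same scale and is recorded at 12-weekly measurement intervals. WHO
#' stage 3/4 clinical events, death and loss to follow-up are drawn each
#' interval from logistic hazards that are non-increasing in current true
#' CD4 by construction. Switching behavior is arm-specific: LCM clinicians
#' react to low observed CD4 counts and clinical events, CDM clinicians
#' (who never see CD4 results) only to clinical events.
#'
#' All hazard linear predictors use the low-CD4 score
#' `pmax(0, 10 - sqrt(cd4_true))`, so a positive slope means hazard rises as
#' CD4 falls and is flat above 100 cells/mm3.
#'
#' @param n_individuals cohort size.
#' @param n_intervals number of 4-week intervals of administrative follow-up
#'   (interval `k` covers days `[28k, 28k+28)`; interval 0 is the baseline
#'   visit, at which no events, switches or deaths occur).
#' @param arm_fractions named proportions for the `LCM` and `CDM` arms.
#' @param baseline_cd4 list: `sqrt_mean`, `sqrt_sd` of latent baseline CD4 on
#'   the square-root scale; defaults give a right-skewed distribution with
#'   median near 201 cells/mm3 and roughly 11% below 100.
#' @param cd4_dynamics list: per-interval drift on the square-root scale for
#'   stable patients (`drift_stable`), patients failing first-line therapy
#'   (`drift_failing`), and failing patients after switch to second line
#'   (`drift_secondline`); innovation `noise_sd`; measurement noise
#'   `meas_sd`; bounds `sqrt_floor`, `sqrt_cap`.
#' @param failure_fraction proportion of the cohort with ongoing first-line
#'   virological failure (declining CD4 until switch).
#' @param event_hazards per-event-type `c(intercept, slope)` on the logit
#'   scale for WHO3, esophageal candidiasis, non-Candida WHO4, pulmonary TB
#'   and extrapulmonary TB.
#' @param death_hazard list: logit `intercept`, `cd4_slope` on the low-CD4
#'   score, `who4_recent` added when a WHO4-level event occurred in the
#'   current or two previous intervals, and `secondline` added while on
#'   second-line ART (a direct protective effect when negative).
#' @param switch_behavior list of logit terms for the natural switching
#'   propensity: `lcm_intercept`, `cdm_intercept`, `lcm_cd4_lt100`,
#'   `lcm_cd4_lt50` (react to last observed CD4), `who4_recent`,
#'   `who3_recent` (both arms react to events in intervals `k-2..k`).
#' @param ltfu_hazard per-interval probability of dropout.
#' @param substudy list: `fraction` of the cohort entering the structured
#'   treatment interruption substudy at `entry_interval`, allocated 1:1 to
#'   STI and continuous therapy within center-by-arm strata.
#' @param missingness list: per-interval probabilities `miss_visits`
#'   (>=3 of last 6 nurse visits missed) and `miss_doses` (self-reported
#'   missed ART doses).
#' @param baseline_covariates list of marginal probabilities for study
#'   center, first-line regimen, low BMI, low hemoglobin, WHO4 event during
#'   weeks 24-48 on ART, and cotrimoxazole use.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return a validated `sim_config` object (a list).
#' @export
sim_config <- function(n_individuals = 2946L,
                       n_intervals = 65L,
                       arm_fractions = c(LCM = 0.5, CDM = 0.5),
                       baseline_cd4 = list(sqrt_mean = 14.2, sqrt_sd = 3.42),
                       cd4_dynamics = list(drift_stable = 0.04,
                                           drift_failing = -0.16,
                                           drift_secondline = 0.30,
                                           noise_sd = 0.35,
                                           meas_sd = 0.8,
                                           sqrt_floor = 1,
                                           sqrt_cap = 18),
                       failure_fraction = 0.18,
                       event_hazards = list(
                         who3 = c(-5.4, 0.30),
                         esoph_candida = c(-6.7, 0.35),
                         who4_noncandida = c(-7.0, 0.55),
                         tb_pulmonary = c(-6.3, 0.25),
                         tb_extrapulmonary = c(-7.4, 0.45)),
                       death_hazard = list(intercept = -7.72,
                                           cd4_slope = 0.62,
                                           who4_recent = 1.3,
                                           secondline = -0.35),
                       switch_behavior = list(lcm_intercept = -7.8,
                                              cdm_intercept = -6.6,
                                              lcm_cd4_lt100 = 3.8,
                                              lcm_cd4_lt50 = 1.0,
                                              who4_recent = 5.0,
                                              who3_recent = 3.0),
                       ltfu_hazard = 0.0011,
                       substudy = list(fraction = 0.27, entry_interval = 1L),
                       missingness = list(miss_visits = 0.02,
                                          miss_doses = 0.08),
                       baseline_covariates = list(
                         center_probs = c(0.45, 0.35, 0.20),
                         regimen_probs = c(0.73, 0.17, 0.10),
                         bmi_low_prob = 0.15,
                         hb_low_prob = 0.06,
                         who4_wk24_48_prob = 0.05,
                         cotrim_prob = 0.70),
                       seed = 20201L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_intervals = as.integer(n_intervals),
              arm_fractions = arm_fractions,
              baseline_cd4 = baseline_cd4,
              cd4_dynamics = cd4_dynamics,
              failure_fraction = failure_fraction,
              event_hazards = event_hazards,
              death_hazard = death_hazard,
              switch_behavior = switch_behavior,
              ltfu_hazard = ltfu_hazard,
              substudy = substudy,
              missingness = missingness,
              baseline_covariates = baseline_covariates,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (is.na(cfg$n_individuals) || cfg$n_individuals < 1L) {
    stop_cfg("n_individuals must be >= 1")
  }
  if (is.na(cfg$n_intervals) || cfg$n_intervals < 1L) {
    stop_cfg("n_intervals must be >= 1")
  }
  probs <- c(cfg$arm_fractions, cfg$failure_fraction, cfg$ltfu_hazard,
             cfg$substudy$fraction,
             cfg$missingness$miss_visits, cfg$missingness$miss_doses,
             cfg$baseline_covariates$center_probs,
             cfg$baseline_covariates$regimen_probs,
             cfg$baseline_covariates$bmi_low_prob,
             cfg$baseline_covariates$hb_low_prob,
             cfg$baseline_covariates$who4_wk24_48_prob,
             cfg$baseline_covariates$cotrim_prob)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop_cfg("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$arm_fractions) - 1) > 1e-8) {
    stop_cfg("arm_fractions must sum to 1")
  }
  slopes <- vapply(cfg$event_hazards, function(p) p[2L], numeric(1))
  if (any(slopes < 0) || cfg$death_hazard$cd4_slope < 0) {
    stop_cfg("hazard slopes on the low-CD4 score must be >= 0 so hazards are non-increasing in CD4")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  n_individuals:", x$n_individuals,
      " n_intervals:", x$n_intervals, "\n")
  cat("  arms:", paste(sprintf("%s=%.2f", names(x$arm_fractions),
                               x$arm_fractions), collapse = ", "), "\n")
  cat("  failure_fraction:", x$failure_fraction,
      " ltfu_hazard:", x$ltfu_hazard, "\n")
  cat("  substudy fraction:", x$substudy$fraction,
      " seed:", x$seed, "\n")
  invisible(x)
}
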