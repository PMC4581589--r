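---
title: "Clone-censor-weight estimation of ART switching strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-censor-weight estimation of ART switching strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimand and the identification strategy

`dynmsm` estimates counterfactual survival curves $S_X(k)$ under dynamic
treatment strategies $X$ of the form "switch from first-line to
second-line ART in the first 4-week interval after the observed CD4 count
drops below $x$ cells/mm³, or in the interval of the first qualifying WHO
stage 3/4 event, whichever comes first, with switching times spread
approximately uniformly over a 3-interval grace period". A strategy also
fixes a CD4 *monitoring schedule*: eligibility is evaluated only on the
CD4 measurements the schedule would make available to the clinician, so
"12-weekly monitoring" and "a single baseline CD4 count" are different
strategies even with the same threshold.

Identification uses the standard sequential-exchangeability argument for
marginal structural models: conditional on measured history (current and
past CD4, WHO 3/4 and tuberculosis event histories, anthropometric and
laboratory baseline covariates, visit attendance, reported adherence),
the decision to switch is assumed independent of counterfactual survival.
The two randomized monitoring arms (LCM, with CD4 results returned to
clinicians; CDM, without) are pooled, which additionally assumes the arm
affects mortality only through switching; consistent with that
assumption, randomized arm is deliberately excluded from every model.

The estimator is clone-censor-weight:

1. **Clone** the cohort once per strategy.
2. **Censor** a clone when its data become incompatible with the
   strategy: a switch before eligibility censors at the switch; failure
   to switch by the end of the grace period censors at entry to
   $Q + m + 1$ (so the last grace interval still contributes to risk
   sets; $m = 2$ is the grace length minus one).
3. **Weight** uncensored clone-intervals by nonstabilized
   inverse-probability weights
   $$W_X(k) = I[C_X(k) = 0] \prod_{j \le k} w_j, \qquad
     w_j = \begin{cases}
       1/p_A(j) & j < Q\\[2pt]
       \dfrac{1 - 1/(m+1-r)}{p_A(j)} & j = Q + r,\ \text{no switch}\\[6pt]
       \dfrac{1/(m+1-r)}{1 - p_A(j)} & j = Q + r,\ \text{switch}\\[2pt]
       1 & \text{after switch or grace,}
     \end{cases}$$
   where $p_A(j)$ is the fitted probability of *not* switching in
   interval $j$. The numerators distribute the implied switching times
   uniformly over the grace period (each offset receives mass 1/3;
   `grace_switch_distribution()` exposes this), and a clone that reaches
   the last grace interval without switching receives weight zero there,
   which is exactly the censoring-at-$Q+m+1$ rule seen from the weights'
   side.

Substudy weights censor participants randomized to structured treatment
interruptions (weight 0 from entry) and upweight their continuous-therapy
counterparts by $(n_{STI} + n_{CT})/n_{CT}$ within center-by-arm strata
(≈2 under 1:1 allocation). Loss-to-follow-up weights are the cumulative
inverse of the fitted retention probability from a pooled logistic model
that reuses the switch-model covariates plus a prior-switch indicator.
The three components multiply, and the *product* is truncated at 10 (the
raw product is kept for sensitivity runs); truncating the product rather
than each component is our reading of a procedure that forms "the
time-dependent product" first.

## The two fitted models

**Switch model.** Pooled logistic regression of switching on the
unexpanded cohort, risk set = person-intervals alive and on first-line
ART. Covariates: restricted cubic spline in interval index (knots at the
10th/50th/90th percentiles of the at-risk person-interval distribution —
the reference distribution is a deliberate choice, since percentiles over
persons would also be defensible), every center-by-regimen combination,
baseline CD4 category (<100/100–199/≥200), low BMI (≤18.5), low
hemoglobin (<8 g/dL), WHO4 event during weeks 24–48 on ART, current CD4
as a restricted cubic spline with knots 15/50/100/200 cells/mm³ (LOCF
over all 12-weekly measurements), cotrimoxazole use in the previous
interval during the first 72 weeks on ART, ≥3 of 6 nurse visits missed,
reported missed doses, five-category WHO 3/4 and tuberculosis event
histories (recent = $k{-}2..k$, distal = $k{-}5..k{-}3$, highest level
dominant), and a recent-WHO4 × CD4<100 interaction. Only CD4 gets a
spline; the other continuous variables are categorized, which keeps
predicted probabilities away from 0/1 and so protects positivity. Events
in the interval of a switch count only when they occurred strictly before
the switch. Weights for *reduced-monitoring* strategies still come from
this model fitted with **all** measured CD4 counts — confounding control
must use the data the clinicians' decisions actually depended on, not the
strategy-filtered series; the engine enforces this by construction
(weights are computed before any schedule filtering) and the test suite
asserts the consequences (regime identities).

**Outcome model.** Weighted pooled logistic regression on the expanded
data: risk rows are clone-intervals alive through $k$, uncensored by the
strategy through $k$ and by dropout/substudy through $k{+}1$; the outcome
is death in $k{+}1$, weighted by the truncated weight *through* $k$ (a
person not yet switched in $k$ has the same interval-$k$ risk whether or
not they switch during $k$). Strategy enters as $h(X)$ — the threshold in
cells/mm³, linear, 0 for event-only strategies — plus one dummy $g(X)$
per event-only strategy, or as a categorical $f(X)$ for
monitoring-frequency comparisons; each term is interacted with the
late-follow-up indicator $k_m$ ($=1$ when the outcome interval begins
strictly more than 96 weeks after baseline, i.e. start day > 672).
Categorical and spline forms of $h(X)$ are available via `h_form`.
Survival is $S(K) = \prod_{k<K}(1 - \hat h_k)$, and 95% bands come from a
percentile bootstrap over individuals (percentile rather than normal
because it needs no variance formula and respects the [0, 1] scale); the
whole pipeline — switch model, LTFU model, substudy weights, expansion,
outcome model — is re-estimated in every replicate.

## What the synthetic cohort emulates

The generator (`sim_config()`, `generate_cohort()`) produces a two-arm
cohort of (by default) 2,946 adults entering after 48 weeks of first-line
ART, followed for 65 four-week intervals:

* **Baseline CD4**: latent square-root-scale normal (mean 14.2, SD 3.42)
  plus measurement noise (SD 0.8 on the same scale), giving a
  right-skewed distribution with median ≈201 cells/mm³ and ≈11% below
  100 — the published marginal structure of the target cohort.
* **CD4 dynamics**: AR-style drifted random walk on the square-root
  scale. A `failure_fraction` (default 18%) of patients fail first-line
  therapy and drift down 0.16/interval until switched, then recover at
  +0.30/interval; everyone else drifts up slowly. This is a pragmatic
  parameterization chosen for realism of shape, not a biological claim.
* **Events and death**: per-interval logistic hazards that are flat above
  100 cells/mm³ and rise linearly in $\max(0, 10 - \sqrt{CD4})$, by
  construction non-increasing in CD4. Death additionally responds to a
  recent WHO4-level event and carries a modest direct second-line benefit.
  Default intercepts/slopes were calibrated once against the published
  cohort margins (≈180 deaths, ≈625 switches with an LCM/CDM split of
  roughly 55/45, ≈190 lost to follow-up, ≈390 persons with a WHO4-level
  event) and then frozen.
* **Behavior**: LCM clinicians switch in response to the last observed
  CD4 (<100, <50) and recent events; CDM clinicians never see CD4 and
  respond to events only — so the two arms provide the variation in
  switching that makes the monitoring-frequency strategies identifiable,
  exactly the design feature the method exploits.
* **Dropout, substudy, missingness**: constant dropout hazard
  (≈6% cumulative), an optional STI/continuous-therapy substudy entered
  at a fixed interval with 1:1 stratified allocation (makes the ≈2
  upweight exact in expectation), and small probabilities of missed
  visits/doses.

Within an interval the generator draws events first (with a day), then
the switch decision (switches prompted by a same-interval event occur
after it, making the before-switch flag well defined), then death, then
dropout. Interval 0 is the baseline visit: CD4 is measured but no events,
switches or deaths occur there, so all model products start at $j = 1$.

What it does **not** emulate: time-varying BMI/hemoglobin (carried
constant), covariate-dependent dropout (the default dropout is
noninformative, though the LTFU weights are estimated regardless),
seasonal or center-level event variation, confirmatory repeat CD4 counts
(excluded from strategies on purpose), and any unmeasured confounding —
the generator satisfies sequential exchangeability by construction, since
behavior depends only on observed history. Passing validation therefore
demonstrates that the estimator correctly undoes *measured* time-varying
confounding at realistic scale; it cannot speak to unmeasured
confounding in real data.

**Ground truth.** `simulate_counterfactual_survival()` re-runs the same
latent mechanism while forcing compliance: eligibility is tracked on the
strategy's observed CD4 series, the switch interval is drawn uniformly
from the grace period, and behavioral parameters, dropout and substudy
are inert. This is a direct Monte-Carlo evaluation of the estimand, so
estimator and truth can be compared without any shared modeling code.

## Numerical choices

* **Fitting.** All pooled logistic models are fitted by a Newton
  solver with step-halving on the deviance plus a tiny L2 penalty
  (λ = 1e-4, never on the intercept). The penalty's only purpose is to
  keep the optimum finite when a rare covariate cell (e.g. a distal-TB
  history level in a small or resampled cohort) separates; its effect on
  coefficients is orders of magnitude below sampling noise, and the
  unpenalized intercept preserves the logistic score equation (predicted
  events = observed events, asserted in tests to 1e-6 relative).
  Aliased/empty design columns are detected by rank of the Gram matrix,
  dropped with a message, and reported with zero coefficients.
* **Bootstrap mechanics.** Resampling individuals is implemented as
  per-person multiplicity weights on a precomputed context (design
  matrices, eligibility, censoring and outcome risk rows never change
  across replicates), with warm starts from the point estimate, a relaxed
  convergence tolerance (1e-4 relative deviance change; bands agree with
  1e-8 fits to ~1e-4) and curvature estimated on a one-in-three row
  subsample (the gradient stays exact, so the fixed point is exact).
  Failed replicates (e.g. positivity violations in a resample) are
  logged, skipped and counted. Given the seed, results are
  bit-reproducible.
* **Positivity.** Any required weight denominator below 1e-6 raises a
  classed error (`dynmsm_positivity_error`) naming the person and
  interval — never a silent extreme weight.
* **Degenerate inputs.** A cohort with zero switches makes
  `fit_switch_model()` fail informatively, while the estimation pipeline
  treats it analytically as $p_A \equiv 1$ (mirroring the analytic
  all-ones LTFU weights of a cohort with no dropout); a cohort with zero
  deaths fails informatively in the outcome model; fewer than three
  distinct interval-spline knots fall back to an equispaced rule and then
  error if still degenerate; horizons beyond the fitted risk range raise
  an extrapolation error.
* **Tie-breaks and edge rules.** When CD4 and event triggers give the
  same eligibility interval, the recorded reason is the event (reporting
  only). When a strategy observes no CD4 at all, the 250 cells/mm³
  tie-breaker is vacuously satisfied — this makes an empty-schedule
  CD4 strategy reduce exactly to the corresponding event-only strategy,
  which the tests assert bit-for-bit. The tie-breaker is evaluated on the
  strategy's observed series (not all measurements), keeping the regime
  definition internally consistent under reduced monitoring. An event in
  the same interval as, but after, a pre-eligibility switch does not
  rescue the clone: it is censored at the switch.

## Validation design and problem sizes

The validation suite runs at sizes chosen to exercise the full mechanism
while keeping a complete test run within tens of minutes on one CPU:
weight-formula equivalence against a brute-force oracle on a 200-person,
30-interval fixture; identity reductions and regime identities at small
scale; parameter recovery at n = 5,000 (25 cohort replicates against
forced-regime truth from 100,000 trajectories, ±1.5 percentage points at
240 weeks); qualitative strategy orderings at the full n = 2,946 with
B = 100 bootstrap replicates; and bootstrap coverage at n = 1,000 with
B = 100 over 50 simulation replicates. The coverage study uses a
simplified no-dropout, no-substudy variant of the generator — dropout and
substudy weighting are already validated against truth in the recovery
and ordering studies — which keeps its runtime proportionate without
touching the estimator itself.

## Known limitations

* The grace period is global; clinically, tuberculosis diagnoses argue
  for event-specific grace periods, which the engine does not support.
* Confirmatory (repeat) CD4 measurements cannot be part of a strategy.
* Only nonstabilized weights are implemented (with the uniform-over-grace
  numerator); stabilized-weight and doubly robust variants are out of
  scope.
* The h/g outcome encoding pools strategies through a linear threshold
  term; with only two strategies the $g$ dummy is collinear with
  $h$ and the intercept, and is dropped automatically (the fit is then
  saturated in strategy, so predictions are unaffected).
* Synthetic validation bounds what can be claimed about real data: the
  generator has no unmeasured confounding, so agreement with truth
  validates the estimator's mechanics, not the causal assumptions.
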