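---
title: "Methods: trial-based economic evaluation of a rural stroke-care program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based economic evaluation of a rural stroke-care program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The problem

`strokecea` implements the economic evaluation of a cluster-randomized,
mHealth-supported stroke secondary-prevention program delivered by village
doctors in rural China: 50 villages in 5 township strata randomized 1:1 to a
1-year intervention or usual care, roughly 1,299 participants with prior
stroke, and an observational follow-up extending to about six years after
baseline. Three analyses sit on top of the trial data:

1. a **within-trial cost-effectiveness analysis** (incremental cost per mmHg
   of systolic blood pressure (SBP) reduction and per quality-adjusted life
   year (QALY) gained over the trial year),
2. a **post-trial cost-effectiveness analysis** over the follow-up window,
   with discounting, and
3. a **national budget-impact analysis** of scaling the program up, either
   standalone or folded into the national basic public health (NBPH)
   service program.

Because the individual-level trial data are not publicly deposited, the
package ships a synthetic-trial generator with the same design and
calibrated moments, so every stage of the pipeline is exercised end to end
on data whose ground truth is known.

## Costing

All amounts are expressed in reference-year (2023) US dollars.
`adjust_currency()` inflates historical amounts with a user-supplied rural
consumer price index table and, for local-currency amounts, converts once
at the reference-year exchange rate. The order — inflate in local currency,
then convert — is a unit-coherence choice; both factors are configuration,
and items whose currency-year differs from the reference year are rejected
at aggregation time rather than silently summed.

Cost components per participant:

* **Inpatient care** arrives as itemized episodes in three cause
  categories (stroke, cardiovascular non-stroke, other).
* **Medications** (antiplatelet, statin, antihypertensive) are valued as
  quantity × unit price × adherence, with adherence a precomputed fraction
  in [0, 1] (`medication_cost()`).
* **Outpatient visits** are a flat per-participant literature value
  (default 45.5 USD/year within trial; 124.2 USD over the post-trial
  window) because trial outpatient records do not exist.
* **Program delivery** costs come from an itemized ledger
  (`program_ledger()`) amortized over the intervention participants.

Post-trial hospitalization costs are not observed; they are estimated as
self-reported episode counts times the within-trial mean cost per episode
of the matching cause (`estimate_posttrial_inpatient()`).

## Utilities and QALYs

EQ-5D-5L profiles convert to a utility index through an additive-decrement
value set supplied by the user; the value-set coefficients are an external
input, and the file shipped under `inst/extdata/` is a *synthetic* stand-in
with the right structure (anchor 1.0 at full health, floor −0.391), not a
published country tariff.

QALYs are the area under the piecewise-linear utility trajectory
(`build_trajectory()`, `qaly_auc()`):

* observed waves are interpolated linearly, which is also how interior
  missing waves are imputed;
* from the date of death onward the utility is 0; between the last
  observation and death the default is a linear decline to 0 (a
  last-value-carried-forward variant is available via `death_method`),
  since only the value *from* death onward is pinned by convention;
* survivors are never extrapolated past their last observed wave;
* annual summation pro-rates fractional first/last years by the trapezoid.

Discounting (`discount_stream()`) applies only to the post-trial period, at
5%/year by default (3–8% is the usual sensitivity range), anchored at the
end of the within-trial year: the stream element `t` whole years after the
anchor is divided by `(1 + r)^t`.

## Arm contrasts

`adjusted_difference()` fits the trial's primary analysis model to each
per-participant quantity: a linear mixed model with an arm indicator,
township fixed effects (the stratification factor), the baseline value of
the outcome, age and sex, and a village random intercept, by REML
(`lme4`). Analysis is intention-to-treat and complete-case: participants
missing an outcome are dropped from that outcome's model, and no multiple
imputation is attempted. When the random-intercept variance is estimated on
the boundary the function falls back to the same fixed-effects model with a
cluster-robust (village) covariance — at 25 clusters per arm this
degeneracy is a real possibility on resampled data. Costs are adjusted with
the same model without a baseline term; whether to adjust costs at all is
ambiguous in trial-based practice, so `unadjusted_difference()` (raw means,
cluster-robust SE) is kept alongside and the adjusted contrast is the
default ICER input.

## Uncertainty

`cluster_bootstrap()` resamples **villages with replacement within
township × arm strata**: the village is the randomization unit, and the
stratification is part of the design, so both are respected in the
resampling. An individual-level option exists for comparison. Within each
replication the arm contrasts are re-estimated with the fixed-effects
version of the adjusted model: the resampling itself carries the
within-village correlation, and refitting REML 5,000 times would cost
minutes for no change in the replicate means; `method = "reml"` refits the
mixed model per replicate for users who want it, falling back to the
fixed-effects estimate on non-convergence.

From the draws the package computes the cost-effectiveness plane quadrant
shares, percentile 95% intervals, the CEAC
(`p_ce(λ) = P(λ·Δe − Δc ≥ 0)`; default grid 0 to twice the
willingness-to-pay threshold of 18,766 USD/QALY in 100 steps), and a
percentile interval for the ICER over the draws with positive incremental
effect, reported together with that interpretable fraction — ratio
intervals are ill-defined across quadrants, so the restriction is made
explicit rather than hidden.

ICER conventions (`icer()`): the effect is oriented so benefit is positive
(SBP reduction in positive mmHg), the southeast quadrant is dominant, the
northwest dominated, and a non-positive incremental effect flags the ratio
non-interpretable instead of raising an error.

`one_way_dsa()` varies one parameter at a time between user-supplied
bounds (±50% of base for cost components, 95% CI bounds for effects, by
convention) through a deterministic evaluator and returns rows in tornado
order.

## The synthetic trial

`sim_config()` defaults encode the study conditions: 5 townships × 10
villages × ~26 participants (1,299 total), 1:1 allocation within township,
baseline SBP ~ N(145.9, 22.4) mmHg, baseline utility mean 0.80 (SD 0.20,
truncated to [−0.391, 1]), age ~ N(65.6, 8.2). Change outcomes at one year
use village random intercepts with ICC 0.05 and within-village SDs of 12
mmHg (SBP) and 0.12 (utility); the implied standard errors of the arm
contrasts (≈1.0 mmHg, ≈0.010 utility) match the published interval widths.
True arm effects default to −2.8 mmHg and +0.06 utility; first-year
mortality is 2% with a truncated-exponential (constant-hazard) death time,
and 3.3% of survivors miss the closing wave.

Costs: inpatient episodes are zero-inflated gamma per cause (control-arm
annual probabilities 0.12/0.08/0.20, mean episode costs 300/250/230 USD,
shape 0.9), medication uptake is higher under intervention
(e.g. antiplatelet 0.85 vs 0.60), and every intervention participant
carries the 50.8 USD program cost. The intervention-arm hospitalization
probability is solved internally so that the **expected total incremental
cost equals the configured target (23.3 USD)** — the published category
rows are mutually inconsistent at the printed precision, so the generator
calibrates the total and keeps the components plausible. The implied
per-trial dispersion (SE of the incremental cost ≈ 10 USD) is a deliberate
moderate-noise choice: the published confidence interval of the total-cost
difference implies a heavier tail than the category means alone support,
and the package's bootstrap intervals are correspondingly narrower than
the published ones.

Post-trial, survivors get waves at 5.3 and 5.9 years, arm-specific
cumulative mortality (17.3% vs 20.4% among one-year survivors), Poisson
episode counts per cause, and medication items scaled by each
participant's time alive.

Two generator properties worth knowing:

* **Ceiling attenuation.** Utility changes are truncated at 1.0, so the
  realized arm contrast in utility change is ~0.051 for a configured
  +0.06 (and the QALY contrast ~0.025 for an implied 0.03). This is a
  property of any bounded-scale simulation with a realistic baseline
  distribution, not an estimator bias; the SBP and cost truths are
  unaffected, and the tests pin the attenuated range.
* **What passing tests do not show.** The generator draws normal residuals
  and a correctly specified random-intercept structure — exactly the
  analysis model's assumptions. Parameter recovery and coverage results
  therefore validate the pipeline's correctness, not its robustness to
  skewed utilities, informative missingness, or misspecified correlation
  in real data.

## Budget impact

`bia_params()` carries the published rates (stroke prevalence 2.58%, rural
share 52.9%, incidence 8.26%/year, population growth 1%/year, death rate
0.16%/year) and the published anchors for the eligible population
(11,676,010 in year 1; 11,695,170 in year 5) and national population. The
default projection is **calibrated**: it applies the constant net annual
rate the two anchors imply (≈4.1 × 10⁻⁴/year), because no combination of
the three printed component rates reproduces the printed trajectory; the
`stated_rates` mode is retained as an exploratory path. The base
population behind the eligible count is never printed and is back-solved
(≈855.5 million).

Per-participant costs follow a component schedule (visits, voice messages,
system maintenance, medications recurring; development, training and
supervision in year 1 only). Scenario B charges the NBPH-covered fraction
(61%) only the components NBPH does not already fund (visit delivery,
training, supervision are assumed funded). The default component values
reproduce the published per-participant costs (16.93/6.68 USD scenario A,
9.90/3.98 USD scenario B) but the split itself is an assumption, supplied
as configuration rather than constants. Outputs are nominal (undiscounted)
per-year totals and per-capita amounts, total budget divided by total
population.

## Numerical and design choices

* Seeds: every stochastic entry point takes an explicit integer seed;
  sub-seeds are derived with one `sample.int` call and stay below 2³¹.
* The acceptance computation reports the **Monte-Carlo expectation of the
  pipeline's ICER over 800 replicate trials** (ratio of the mean
  incremental cost to the mean SBP reduction). A single simulated trial's
  point ICER has sampling SD of roughly 4–5 USD/mmHg under the calibrated
  dispersion — reporting one trial would measure the seed, not the
  pipeline. 800 replicates put the Monte-Carlo SE near 0.18 USD/mmHg at
  about three minutes of runtime; the in-suite check uses 400 replicates
  for the same reason at half the cost.
* Simulation-heavy tests use reduced designs (12 villages, 240
  participants) where cluster structure rather than scale is under test,
  and the full 1,299-participant design where published magnitudes are.
* Percentile intervals are order statistics (`stats::quantile` defaults);
  tie-breaks in CEAC use a non-strict inequality (`NMB ≥ 0` counts as
  cost-effective).
* Degenerate inputs fail loudly and early: unknown config keys, mixed
  currency-years, townships with a single arm, value-set profiles outside
  1..5, negative discount rates, and a cost-increment target the cost
  model cannot attain are all errors at validation time.

## Limitations

* The value set shipped is synthetic; substantive QALY numbers require a
  published country tariff as input.
* Post-trial costs inherit the within-trial per-episode means; real
  cost drift over six years is not modeled.
* The BIA is a point projection; no uncertainty is propagated there.
* No Markov or state-transition extrapolation: the post-trial analysis is
  driven entirely by observed (simulated) follow-up, and no EVPI-style
  value-of-information quantities are computed.
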