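---
title: "A decision-analytic model of ABI screening for peripheral arterial disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model of ABI screening for peripheral arterial disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`padscreen` evaluates whether one-time ankle-brachial-index (ABI) screening
of a high-risk cohort aged 55, followed by lifelong antiplatelet prevention
(low dose aspirin, or clopidogrel in a scenario) in everyone who tests
positive, is cost-effective compared with usual care, in which peripheral
arterial disease (PAD) is treated only once it is incidentally diagnosed or
becomes symptomatic. This vignette documents the model structure, every
tunable parameter and default, the structural choices that were genuinely
open, and what the test suite does and does not establish.

## Decision tree

Screening allocates the cohort by PAD prevalence $p$ and test accuracy
(sensitivity $Se$, specificity $Sp$):

| segment | fraction | PAD | treated |
|---|---|---|---|
| true positive | $p \cdot Se$ | yes | yes |
| false negative | $p(1 - Se)$ | yes | no |
| false positive | $(1-p)(1-Sp)$ | no | yes |
| true negative | $(1-p)\,Sp$ | no | no |

Without screening, the symptomatic fraction $s$ of prevalent PAD
($p \cdot s$) is incidentally diagnosed and treated; $p(1-s)$ remains
undetected and untreated; $1-p$ is disease-free. Fractions sum to one by
construction and the allocation is monotone in prevalence and sensitivity
(property-tested).

Every screened person is charged a one-time overhead at cycle 0. Only the
ABI test price (74 EUR) is tabulated in the evidence base; travel,
GP-session and productivity-loss components are configurable and default to
0 with a warning, because no defensible point values are published — we do
not invent numbers.

## Markov model

Eight states: no PAD, asymptomatic PAD, symptomatic (diagnosed) PAD, post
amputation, post myocardial infarction (MI), post stroke, post bleed, dead.
One-year cycles from age 55 until certain death (age 110). Conventions:

* **At most one transition per cycle** — the standard annual-cycle cohort
  assumption.
* **Post-amputation/MI/stroke states are terminal apart from death**, each
  with its own annual mortality (0.155, 0.028, 0.031). The evidence base
  provides per-state mortalities only, so richer cross-event pathways would
  not be identifiable.
* **The symptomatic state is treated by definition** (diagnosis implies
  antiplatelet prescription), in every segment and both arms: its event and
  PAD-mortality probabilities carry the drug's relative risk (RR) and it
  carries the bleeding risk.
* **Treated segments** apply the RR to the asymptomatic PAD row as well;
  treated no-PAD rows (false positives) incur the bleeding risk but *no* RR
  benefit — the published risk reduction is estimated in PAD patients.
* **Post bleed** means a major bleed on treatment: treatment stops, so the
  state faces untreated event risks of its underlying PAD status and no
  further bleeding risk. In the false-positive segment post-bleed occupants
  carry no-PAD risks; everywhere else bleeds can only arise from treated PAD
  states.
* **Incident PAD** (annual incidence by age band: 0.005 / 0.007 / 0.008 /
  0.010 for 55–64 / 65–74 / 75–84 / 85+) splits at onset into symptomatic
  (diagnosed, treated) and asymptomatic with probability 0.3 / 0.7, in both
  arms.
* **Competing risks**: background (other-cause) mortality $q(a)$ is an
  independent hazard: each alive row's death probability is
  $1-(1-p_{\text{death}})(1-q)$ and all other mass is scaled by $(1-q)$. If
  a row's modelled probabilities alone exceed 1 the model stops with an
  error naming the row rather than renormalising silently.
* **No half-cycle correction**; state membership is counted at cycle end,
  so cycle 0 accrues nothing. This choice is isolated in `accumulate()` and
  the analytic-toy oracle pins it down exactly.

### Detection semantics — the decisive structural choice

The annual PAD-care cost (2,369 EUR) and the PAD utility decrement (0.652)
attach to the *symptomatic/diagnosed* state only. Screen-detected
asymptomatic PAD remains in the asymptomatic state: such patients receive
the antiplatelet drug (10 or 19 EUR/year) and its risk reduction, but not
claudication-level care costs or quality-of-life loss, because preclinical
disease found by a vascular screen is not claudication. The unscreened
arm's incidentally treated fraction *is* the clinically manifest stock and
occupies the symptomatic state. This is what makes early detection
economically meaningful: the alternative reading (every diagnosed patient
accrues the PAD-state cost and utility) charges screening ~0.11 of the
cohort with 2,369 EUR/year and a 0.35 utility decrement for being
diagnosed, and makes screening strictly dominated — incompatible with the
comparison the model exists to make.

### Background mortality

The model adds its cardiovascular mortalities on top of a background
hazard, so that hazard must cover *other* causes only; feeding in a full
all-cause population table would count cardiovascular deaths twice.
`calibrated_life_table()` therefore root-finds the level of a Gompertz
hazard (slope 0.095/year, death certain at 110) such that the whole
unscreened cohort — modelled mortalities included — attains a total
undiscounted life expectancy of 27 years at age 55, the Dutch unisex
population value around 2012. The resulting background-only expectancy is
33.8 years. Any life table can be substituted via
`run_config(life_table = read_life_table("my_table.csv"))`.

### Background utility

QALY weights for the no-PAD and undetected-asymptomatic states use
age-banded population norms (0.81 / 0.78 / 0.74 / 0.70 for 55–64 / 65–74 /
75–84 / 85+), in the spirit of the US EQ-5D population catalogue from which
the tabulated state utilities are drawn. Setting these states to utility
1.0 instead would make the cohort's QALY/LY ratio ≈ 0.95, far above the
≈ 0.75 implied by every published pair of outcome figures this model is
benchmarked against. The bands are a `run_config()` argument
(`baseline_utility`).

## Parameters and distributions

The packaged table (`default_parameter_table()`) carries one row per
parameter: point value, distribution family, two moments. Families:

* **Beta(α, β)** for probabilities, utilities and the relative risks;
* **Gamma(shape, scale)** for costs — interpreted as shape·scale because
  that product reproduces every tabulated cost's point value;
* **Beta-PERT(min, mode, max)** with the canonical λ = 4 for the ABI test
  cost, test accuracy and the amputation cost; the mode equals the point
  value;
* **fixed** for drug prices and discount rates.

Four Beta rows (the age-band incidences and the clopidogrel RR) have no
published moments; they are back-solved so that the mean equals the point
value at an effective sample size of 100 and are labelled *synthetic
moments* in the table's source column. A consistency screen
(`mean_consistency_flags()`) reports rows whose distribution mean deviates
from the point value by more than 5%: exactly three tabulated rows do
(amputation and MI probabilities without PAD, post-amputation mortality),
and the PAD utility Beta(0.8, 0.4) — mean 0.667 vs point value 0.652 —
stays just inside. Deterministic analyses use point values; the PSA uses
the distributions as printed.

## Economic accumulation

Discounting is $(1+r)^{-t}$ with $r$ = 4%/year for costs and 1.5%/year for
effects. Per cycle, costs are annual state costs on occupancy plus one-time
event costs on the mass newly entering an event state; the first year in
the post-MI and post-stroke states is charged the (larger) first-year cost
*instead of* the subsequent-year annual cost. Drug cost accrues in every
alive treated cycle and stops at post-bleed and death; in untreated
segments only the symptomatic state (treated by definition) pays it.
Cardiovascular-death costs are not tabulated in the evidence base and enter
as 0.

Incremental results classify as dominant (cheaper, more effective),
dominated, an ICER, or degenerate labels when QALYs tie. The
cost-effectiveness acceptability curve (CEAC) reports, per willingness to
pay (WTP), the fraction of PSA iterations with strictly positive
incremental net monetary benefit $\mathrm{NMB} = \mathrm{WTP}\cdot\Delta Q
- \Delta C$; ties count as not cost-effective. CE-plane boundary points are
assigned to the favourable quadrant. The WTP grid default, 0–80,000 EUR in
steps of 1,000, brackets the 11,000 and 40,000 EUR thresholds at which the
acceptability results are usually quoted.

## Probabilistic and deterministic sensitivity analysis

Each of the 1,000 PSA iterations draws one parameter set and evaluates
*both* strategies on it (common random numbers), so increments are paired
and their Monte Carlo variance is reduced. Per-iteration seeds are spawned
from the master seed through a single `sample.int()` stream; a run is
bit-reproducible given (table, config, n, seed). Draws that violate model
consistency would be counted and reported, never silently dropped (none
occur with the packaged table, whose event probabilities sum to ≈ 0.11 per
row).

One-way analysis moves each non-fixed parameter to the 2.5% and 97.5%
quantiles of its PSA distribution, others fixed at point values, and ranks
parameters by the absolute range of the incremental QALYs (and of
incremental cost). Two-way analysis sweeps prevalence 0.05–0.35 against
RR 0.6–1.0 by default.

## Synthetic tables and the analytic toy

`generate_parameter_table()` draws complete random tables with the same row
names, roles and families as the packaged table, values inside each role's
domain and per-row event mass capped below 0.9, so every pipeline stage is
property-testable on inputs it has never seen; toggles force clearly
dominant or clearly dominated configurations (checked end-to-end) and a
zero-event limit in which the whole model collapses to background mortality
alone. Synthetic tables emulate *structural* validity only: they carry no
between-parameter correlation and no resemblance to real registry evidence,
so passing property tests demonstrates engine correctness, not clinical
realism. `generate_analytic_toy()` supplies the two-state chain whose
geometric-series life expectancy the engine must reproduce to 1e-9.

## Numerical choices and problem sizes

Row-stochasticity is enforced to 1e-10 at construction and at every cycle;
segment fractions to 1e-12. Root finding (life-table calibration, quantile
inversion in tests) uses `uniroot` at tolerances 1e-6–1e-12. A full run is
small: 1,000 iterations × 2 arms × ≤ 7 segments × 55 annual cycles of 8×8
matrix-vector products — about a minute on one core; the deterministic base
case runs in well under a second.

## Known limitations

* Decision-uncertainty levels hinge on the PAD-utility Beta(0.8, 0.4),
  whose 95% interval spans 0.03–0.9999; its draw essentially determines the
  sign of the incremental QALYs (correlation ≈ −0.94), so the probability
  of cost-effectiveness at 40,000 EUR/QALY is much more pessimistic than a
  tighter utility prior would give.
* Societal cost components that are cited to external costing manuals but
  never tabulated (screening travel/GP/productivity overhead,
  cardiovascular-death cost) default to 0, which biases both arms' costs
  downward and narrows the cost difference between them.
* Full screening and treatment compliance is assumed; repeat screening
  rounds, statins, antihypertensives and exercise therapy are out of scope.
* Whether antiplatelet therapy reduces amputation risk is an assumption
  (included in the RR) the underlying trial evidence does not settle.
* False negatives can be incidentally diagnosed later only through the
  incident-PAD pathway; prevalent missed cases stay untreated for life.
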