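# padscreen

Cost-effectiveness of one-time ankle-brachial-index (ABI) screening for
peripheral arterial disease (PAD).

Asymptomatic PAD marks systemic atherosclerosis and sharply raises the risk
of myocardial infarction, stroke and cardiovascular death, yet it mostly
goes undiagnosed — and with it the chance to start cheap antiplatelet
prevention. `padscreen` implements a decision-analytic model, for health
economists and HTA analysts, that asks: should a high-risk cohort aged 55
be ABI-screened once, with every test-positive person put on low dose
aspirin (or clopidogrel) for life, rather than treating only those whose
PAD surfaces clinically?

The model couples

* a **screening decision tree** — the cohort splits into true/false
  positives/negatives by prevalence $p$, sensitivity $Se$ and specificity
  $Sp$ (e.g. $P(\mathrm{TP}) = p\,Se$), against a no-screening arm in which
  only the symptomatic fraction of prevalent PAD is treated;
* an **annual-cycle Markov cohort model** over eight states (no PAD,
  asymptomatic PAD, symptomatic PAD, post amputation, post MI, post stroke,
  post bleed, dead), run from age 55 to death with age-banded PAD
  incidence, treatment relative risks, bleeding risk, and background
  other-cause mortality as an independent competing hazard;
* **economic accumulation** — discounted (4% costs, 1.5% effects) and
  undiscounted lifetime costs, life years and QALYs per strategy, the
  incremental comparison with dominance classification and ICER
  $\Delta C / \Delta Q$;
* **uncertainty analysis** — probabilistic sensitivity analysis over the
  tabulated Beta/Gamma/Beta-PERT parameter distributions with common random
  numbers across arms, cost-effectiveness acceptability curves from the
  incremental net monetary benefit $\mathrm{WTP}\cdot\Delta Q - \Delta C$,
  CE-plane quadrant summaries, and one-way/two-way deterministic
  sensitivity analyses.

All model inputs ship as a plain-CSV evidence table
(`inst/extdata/table1_params.csv`); see the methods vignette
(`vignettes/pad-screening-model.Rmd`) for the model's structural choices
and their rationale.

## Worked example

```r
library(padscreen)

bc <- run_base_case()                      # point-estimate evaluation
bc$incremental$classification
#> [1] "dominant"
round(bc$screening$discounted, 1)
#>    cost      ly    qaly
#> 24104.5    21.3    15.6
round(c(bc$incremental$delta_cost, bc$incremental$delta_qaly), 3)
#> [1] -962.996    0.109

psa <- run_psa(default_parameter_table(), run_config(), n = 1000, seed = 1)
round(psa$summary[c("cost_screen", "cost_noscreen", "d_cost", "d_qaly")], 2)
#>   cost_screen cost_noscreen        d_cost        d_qaly
#>      23772.75      24708.99       -936.25          0.09

ceac(psa, c(11000, 40000))
#>     wtp probability
#> 1 11000       0.910
#> 2 40000       0.712
```

Screening is *dominant*: it saves about 960 EUR per person over a lifetime
(the unscreened arm's symptomatic PAD care outweighs the test and drug
costs plus the extra costs of living longer) while gaining about 0.11
QALYs. The acceptability probabilities fall with the threshold because a
minority of parameter draws — mostly extreme PAD-utility values — flip the
sign of the QALY gain while the cost saving persists.

The numbered scripts under `analysis/` run the full study (deterministic
base case, 1000-iteration PSA, CEAC/CE-plane, tornado and two-way
sensitivity analyses, clopidogrel scenario) and write their tables under
`results/`:

```sh
Rscript analysis/01_base_case.R
Rscript analysis/02_psa.R
# ... through 05_scenario_clopidogrel.R
```

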