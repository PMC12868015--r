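# cryocea

Markov cohort cost-effectiveness analysis of ultrasound-guided breast
cryoablation (BCA) versus breast-conserving surgery (BCS) for early-stage,
low-risk breast cancer, from a US payer perspective over a five-year
horizon.

Minimally invasive cryoablation is an emerging alternative to surgery for
small (≤ 1.5 cm), node-negative, hormone-receptor-positive/HER2-negative,
ultrasound-visible tumours.  It avoids the operating room and general
anaesthesia, so its procedure cost is a fraction of surgery's, but its
oncologic track record is shorter.  This package implements the full
decision model that weighs that trade-off, for health-economics and
outcomes researchers who want to reproduce, probe, or extend the analysis.

## The model

A cohort starts disease-free after treatment and moves among four states
in one-year cycles:

```
disease_free → local_recurrence → (absorbing until death)
disease_free → distant_recurrence
disease_free, local_recurrence, distant_recurrence → dead (absorbing)
```

For each strategy *s* with annual local-recurrence, distant-recurrence and
mortality probabilities (p_L, p_D, p_M), the disease-free row of the
transition matrix is `[1 − p_L − p_D − p_M, p_L, p_D, p_M]`.  Over H = 5
cycles the cohort accrues discounted costs and quality-adjusted life years
(QALYs):

- one-time costs at cycle 0: procedure cost + complication probability ×
  complication cost;
- per-cycle costs: routine surveillance ($36,351/yr) while disease-free, a
  one-time salvage cost ($36,351) on local recurrence, ongoing
  advanced-disease cost ($153,049/yr) with distant recurrence;
- utilities: 0.696 in the first year (minus treatment and
  probability-weighted complication disutilities), 0.779 thereafter,
  0.779 with local and 0.685 with distant recurrence, 0 when dead;
- discounting at 3%/yr, cycle 0 undiscounted.

Strategies are compared by net monetary benefit, `NMB = λ·QALY − cost`, at
a willingness-to-pay λ = $100,000/QALY ($50,000 as a subgroup analysis),
with the incremental cost-effectiveness ratio (ICER) and dominance
classification reported alongside.  Every uncertain parameter carries a
Beta (probabilities), Gamma (costs) or Normal (utilities) distribution for
probabilistic sensitivity analysis; deterministic one-way, two-way,
tornado, and bisection break-even analyses operate on the same scenario
objects.

Because the published state diagram leaves cost timing and mortality
routing open, the engine exposes them as structural `variant_flags()`, and
`calibrate_variant()` documents the search that fixed the shipped default
(see the methods vignette `vignettes/cryocea-methods.Rmd`).

## Worked example

```r
library(cryocea)

scn <- paper_scenarios()$low_risk   # all published parameters, validated
run_base_case(scn)
#> <cea_comparison> low_risk at WTP $100,000/QALY
#>   bca: cost $175,370, QALY 3.4913   bcs: cost $191,705, QALY 3.4623
#>   delta cost $-16,335, delta QALY 0.0289 (dominant); preferred: bca

run_psa(scn, n = 10000, seed = 1)
#> <psa_result> low_risk: 10000 iterations (seed 1), BCA preferred in 99.8% at WTP $100,000
#> # A tibble: 2 × 5
#>   strategy mean_cost sd_cost mean_qaly sd_qaly
#>   <chr>        <dbl>   <dbl>     <dbl>   <dbl>
#> 1 bca        175340.  20358.      3.49   0.139
#> 2 bcs        191678.  20873.      3.46   0.142

find_threshold(scn, "bca.procedure_cost", c(0, 60000))
#> <threshold_result> bca.procedure_cost: 21729.76 (status found, bracket [0, 60000])
```

Read: at base values cryoablation costs $16,335 less per patient and
yields 0.029 more QALYs than surgery, so it *dominates* (cheaper and more
effective); sampling every parameter from its distribution, it keeps the
higher net monetary benefit in 99.8% of 10,000 cohorts; and it would stay
preferred up to a procedure cost of about $21,730 (its base cost is
$2,501).

Results are tibble-friendly: `tidy()` gives per-draw, per-cycle, or
per-strategy tables, `glance()` one-row summaries, and `autoplot()` draws
the cost-effectiveness plane, acceptability curve, sweep curves, two-way
preference maps, and tornado diagrams.  Scenario configurations round-trip
through YAML/JSON (`read_scenario()`, `write_scenario()`); the two
published scenarios ship in `inst/extdata/` with a per-parameter
provenance manifest, and `generate_synthetic_scenario()` produces
randomized valid scenarios for property testing.  A command-line front
end, `inst/cli/cea.R`, wraps the same functions
(`base | psa | owsa | twsa | tornado | threshold | fixtures`).

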