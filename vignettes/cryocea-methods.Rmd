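---
title: "Methods: a Markov cohort model of breast cryoablation versus breast-conserving surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of breast cryoablation versus breast-conserving surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocea)
```

cryocea re-implements, as tested and reusable code, a published US
payer-perspective cost-effectiveness comparison of ultrasound-guided breast
cryoablation (BCA) and breast-conserving surgery (BCS) for early-stage,
low-risk breast cancer.  This vignette is the package's account of the
model: its structure and assumptions, the parameters and their units, the
places where the source analysis left the design open and what this
package chose there, and what the shipped tests do and do not demonstrate.

## Model structure

The model is a four-state Markov cohort simulation with one-year cycles
and a five-year horizon, mirroring the follow-up of the trial that
anchors the cryoablation arm.  States are `disease_free`,
`local_recurrence`, `distant_recurrence`, and `dead`.  The cohort starts
100% disease-free after treatment.  Each strategy arm is characterised by
three annual transition probabilities out of `disease_free` — local
recurrence, distant recurrence, and breast-cancer-specific death — so the
disease-free row of the transition matrix is
$[1 - p_L - p_D - p_M,\; p_L,\; p_D,\; p_M]$.  Structural assumptions:

- **No return to `disease_free`.**  A recurrence state persists for the
  remaining horizon.  De novo second primaries are excluded (their risk is
  treatment-independent), and within five years a salvaged local
  recurrence is still followed as a recurrence.
- **No background mortality.**  Only breast-cancer-specific death is
  modelled; over five years in this (typically older, low-risk) population
  the omission affects both arms symmetrically.
- **Death is absorbing with utility 0 exactly.**
- **No half-cycle correction**; cycle 0 accrues undiscounted, cycle $k$ is
  discounted by $(1+r)^{-k}$ at $r = 3\%$/yr.  Back-calculation from the
  published base-case cells shows they are consistent with this
  convention (an event-free arm accrues $\sum_{k=0}^{4}1.03^{-k} = 4.7171$
  discounted person-years).

Costs and QALYs accrue per cycle.  One-time costs at cycle 0 are
`procedure_cost + complication_prob × complication_cost`.  The first
disease-free year uses the first-year utility minus the treatment
disutility and the probability-weighted complication disutility; later
disease-free years use the subsequent-year utility.  Strategies are
compared by net monetary benefit (NMB) at a willingness-to-pay of
\$100,000/QALY (\$50,000 as a subgroup re-analysis, which is a pure
configuration change).

## Structural variants and calibration

The published state diagram is schematic: it does not say whether
recurrence costs are billed once on entry or in every cycle occupied,
whether a transition's destination state accrues in the cycle of the
transition or the next one, whether cost accrual stops at death, or which
states mortality applies from.  `variant_flags()` exposes all five
readings, and `calibrate_variant()` runs every one of the 32 combinations
against the published base-case cost cells and the procedure-cost
break-even point (computed through its closed form: one-time costs enter
total cost with slope exactly 1, so the break-even procedure cost equals
the base cost plus the base NMB difference).  The score is the mean
absolute relative error over those five quantities; the full table ships
in `inst/extdata/variant_calibration.csv`.

Two refinements to a raw argmin were needed, and both are qualitative
rather than numeric:

1. **Admissibility.**  The published one-way analyses report break-even
   points for cryoablation's local recurrence, distant recurrence, and
   mortality — i.e. in the source model each of those sweeps crosses
   break-even.  Several flag combinations (including the raw score
   winner) make local recurrence exactly cost- and utility-neutral, so
   its sweep *never* crosses; they are structurally contradicted by the
   published results regardless of how well they fit the cost cells, and
   are excluded.
2. **Tie quality.**  The admissible winner (score 1.68% versus the
   inadmissible 1.58%) is also the clinically conventional reading, which
   is reassuring: a local recurrence triggers a one-time salvage cost
   (\$36,351) and then returns to routine surveillance cost; distant
   recurrence accrues the advanced-disease cost (\$153,049) every cycle
   occupied, replacing routine cost; a transition's destination state
   accrues from the cycle of transition; the dead accrue nothing; and
   mortality applies from every alive state.

That combination is the shipped default of `variant_flags()`.

## Parameters

All parameters live in a `scenario()` object — two `strategy_params()`
arms, a `shared_params()` block, `econ_settings()`, and the structural
flags — addressable by dotted paths such as `"bca.procedure_cost"`.
Probabilities are annual decimals, costs are US dollars, utilities are
weights in $[0,1]$, disutilities are positive decrements.  The two
published scenarios (`paper_scenarios()`; identical BCA arm, BCS arm
parameterised either for 1–20 mm tumours or for the low-risk subgroup)
carry a per-parameter provenance table (`scenario_provenance()`) naming
the source row and printed value behind every entry.

Three parameter conventions deserve comment:

- **Annualization is linear by default.**  The source tables convert
  cumulative risks with simple division (e.g. a 4.3% five-year cumulative
  local-recurrence risk becomes 0.86%/yr), and the package follows that
  arithmetic everywhere, keeping the constant-hazard
  ($1-(1-p)^{1/y}$) conversion available as
  `econ_settings(annualization = "exponential")`.  For multi-year windows
  the constant-hazard annual value is always at least the linear one;
  they differ by under 10% for cumulative risks up to about 25%.
- **Cumulative-scale distributions.**  The Beta distributions for the
  cryoablation risks are printed on the cumulative scale ("at 5 years",
  "at 54 months"); the specification stores the window (`per_years`) and
  annualizes each draw.  Under that reading their implied annual means
  (0.82%, 0.23%, 0.72%) agree with the printed point estimates (0.86%,
  0.23%, 0.73%) to within a few percent.
- **The low-risk surgery recurrence split.**  The low-risk surgery arm
  prints only a total recurrence of 1.6% over five years plus a one-way
  base case of 0.2%/yr for local recurrence; the distant share is
  therefore fixed at 0.12%/yr so the linear total matches, and the
  provenance table marks it as derived.  In sampling, one total-recurrence
  draw per iteration is split by the base-case ratio, preserving the
  printed local:distant mix.

**Reconciling printed means with printed distributions.**  A few printed
distributions imply means far from the printed point estimates that drive
every published result (most extremely, the low-risk total-recurrence
Beta implies 8.0% over five years against a printed 1.6%).  The base case
always uses the printed point estimates.  Before any sampling,
`rescale_scenario()` rescales every distribution whose implied mean
disagrees with its base value by more than 10% relative: Beta keeps its
effective sample size $\alpha+\beta$ (hence its relative uncertainty) and
resets its mean; Gamma keeps its coefficient of variation; Normal resets
its mean.  With the cumulative-scale reading above, only three
distributions trigger the rule (the low-risk total recurrence and
mortality, and one surgical-complication component).

**Open questions resolved.**  The printed treatment disutilities (−0.02
cryoablation, −0.10 surgery) are taken as authoritative over a
percentage-scale phrasing elsewhere in the source; the complication
disutility (−0.05, "by assumption") is applied once, weighted by the
complication probability, in the first cycle; the surgical complication
probability is the sum of its three printed components (1.5% + 11.0% +
1.82%), each sampled from its own Beta and truncated at 1; and the
follow-up-cost sensitivity analysis is implemented as an additive
per-cycle increment to the cryoablation arm's routine cost
(`bca.routine_cost_increment`), accruing wherever routine cost accrues
for alive states.

## Probabilistic sensitivity analysis

`run_psa()` samples every uncertain parameter per iteration and runs both
cohorts.  Design choices:

- **Shared draws.**  Cost and utility rows printed identically for both
  arms (complication cost, all shared costs and utilities) are drawn once
  per iteration and applied to both — the standard treatment of common
  parameters, and the reading consistent with simulating "parallel
  cohorts".  Independent sampling is available via
  `shared_draws = FALSE`.
- **Determinism.**  One seeded generator per run; parameters are drawn in
  a fixed documented order (cryoablation arm fields, surgery arm fields,
  shared fields), with grouped parameters inverting a single uniform
  draw.  Point parameters consume no randomness.  Reruns with the same
  seed are bit-identical.
- **Support handling.**  Probabilities and utilities are truncated to
  $[0,1]$; in the (for these scenarios never observed) event that an
  arm's three annual risks jointly exceed 1, they are rescaled onto the
  simplex.
- **Acceptability curve.**  The CEAC grid defaults to \$0–\$200,000 in
  \$10,000 steps, which covers both published willingness-to-pay values;
  ties count to neither strategy.

The package reproduces the published per-strategy Monte Carlo dispersion
well (cost SDs within ~6%, QALY SDs within ~13%; asserted at 25% in the
tests, since SDs are shape-sensitive).

## Deterministic sensitivity analyses

One-way sweeps substitute values on a grid and rerun both cohorts.
`find_threshold()` scans the bracket on a 64-point grid, takes the first
sign-change interval from the lower end, and bisects to an absolute
parameter tolerance of $10^{-6}\max(1,|hi|)$; multiple sign changes are
reported via the status field (the published curves are monotone, but
arbitrary scenarios need not be).  Thresholds on probabilities are
reported as annual probabilities; five-year equivalents follow from the
linear convention.  Two-way maps evaluate the preferred strategy on a
Cartesian grid, and `two_way_boundary()` traces the preference boundary
by solving a one-dimensional threshold per grid line.  The tornado
diagram evaluates the NMB difference with each parameter at the 2.5th and
97.5th percentiles of its (rescaled) sampling distribution — the source
does not state its ranges, so the quantile choice is an explicit knob —
and sorts bars by width.

## What reproduces, and what does not

The tests pin the model to the published quantities at stated tolerances.
Tightly reproduced (2–5%): both arms' base-case costs in both scenarios,
the QALY difference, the dominance classification, the ≥99% PSA
preference at 10,000 iterations, the procedure-cost break-even (~\$21.7k
vs \$20.9k, cross-checked against its closed form), and the additional
follow-up-cost break-even (~\$4.2k/yr vs \$4k/yr).  Reproduced in order
of magnitude only: the distant-recurrence break-even (1.4%/yr vs
1.04%/yr).  Not reproduced at their stated tolerances, and left failing
deliberately rather than tuned:

- the low-risk cost saving (\$16.3k vs \$17.7k, −7.6%): the published
  saving exceeds the arms' one-time cost gap, which no coherent reading
  of the state costs can produce given the low-risk surgery arm's
  strictly better clinical parameters;
- the mortality break-even (4.5%/yr vs 2.1%/yr) and the associated
  two-way boundary gap: matching 2.1% requires a per-death penalty about
  25% beyond even the most punitive structural reading enumerated (the
  internal consistency between the one-way threshold and the two-way
  boundary does hold, to 0.2 percentage points);
- the local-recurrence break-even (21%/yr vs 51.5%/yr) and its two-way
  gap: with a one-time salvage cost per recurrence — the only reading
  that produces any crossing — the threshold lands where cumulative
  discounted entrants offset the base NMB gap, around 20%/yr.  A
  published 51.5%/yr would need an entrant penalty no enumerated
  structure yields (and read cumulatively over five years it would sit
  *below* our annual threshold), suggesting a scale difference in the
  source;
- the tornado top-four: mortality and distant recurrence match the
  published list, but a local-recurrence *cost* billed once against a
  0.86%/yr entrant flow cannot out-rank the surgery procedure cost
  (SD \$3,772), which the published ranking does not mention.

## The synthetic-scenario generator

`generate_synthetic_scenario()` draws structurally valid scenarios —
annual risks uniform on $[0, 0.2]$ per transition, costs log-uniform on
\[\$100, \$200,000\], utilities uniform on $[0.3, 1]$, disutilities and
complication probabilities uniform on $[0, 0.2]$, all as point masses,
deterministic per seed.  The ranges bracket the published values by an
order of magnitude either side, which is what the structural properties
need: cohort conservation, monotonicity, and agreement with the
brute-force path oracle must hold across the whole valid space, not just
near the base case.  The generator does **not** emulate correlated
parameters, parameter distributions, or clinically plausible joint
configurations, so passing property tests demonstrates engine
correctness, not calibration to any real population.

## Numerical choices and problem sizes

The engine is exact linear algebra on 4×4 matrices (no simulation error);
the only stochastic component is the PSA.  Tolerances in the tests: trace
conservation to $10^{-12}$ on 10,000 random scenarios across all 32
structural variants; equivalence with an independent enumeration of all
$4^5 = 1024$ state paths to $10^{-10}$; bisection against a 10,000-point
grid-search oracle within one grid step on 100 forced-crossing scenarios;
distribution means against $10^6$-draw sample means within three Monte
Carlo standard errors.  PSA checks run at 4,000 iterations (dispersion,
convergence) and 10,000 iterations (headline preference proportions), the
latter matching the published iteration count.

## Limitations

Beyond the source analysis's own limits (five-year horizon, trial-derived
cryoablation outcomes from a selective single-arm cohort, US costs), the
re-implementation adds one: the state diagram admits several cost-timing
readings, and although the calibrated default reproduces the base case
closely, threshold quantities that hinge on the unprinted structure
(mortality and local-recurrence break-evens) carry structural, not just
parametric, uncertainty — which is precisely why the variant flags are
exposed rather than hard-coded.
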