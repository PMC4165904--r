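---
title: "Model and methods: assay-guided chemotherapy cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: assay-guided chemotherapy cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(assaycea)
inp <- default_inputs()
```

## The decision problem

Women with estrogen-receptor-positive, lymph-node-negative early breast
cancer face a choice about adjuvant chemotherapy after surgery.  A 21-gene
recurrence-score assay stratifies them into low-, intermediate- and
high-risk groups with sharply different baseline recurrence risks and
chemotherapy benefits, and observational decision-impact data show that
physicians change roughly a third of their recommendations once they see
the score — mostly withdrawing chemotherapy from low-risk women, but also
extending it to every high-risk one.  The package asks what that
redistribution is worth, per average patient over a lifetime, from the
societal perspective: costs in 2013 JPY (including patient time and
transport), health in quality-adjusted life-years, both discounted at
3%/year.

## Model structure

Each of six subgroups (three risk groups × chemotherapy yes/no) is a
deterministic four-state Markov cohort with annual cycles:

* **recurrence-free** — on study after surgery; accrues utility 0.98 and
  surveillance cost ¥25,416/year;
* **distant recurrence** — metastatic relapse; utility 0.30, cost
  ¥2,405,924/year;
* **breast-cancer death** — reached from distant recurrence (annual
  probability 0.40) or via fatal chemotherapy toxicity at time zero;
* **other-cause death** — life-table background mortality.

Strategy arms differ only in the per-group chemotherapy rates (pre- versus
post-assay recommendations) and in whether the ¥350,000 assay cost is
charged once at time zero.  The arm result is the share- and rate-weighted
mix of the six subgroup results.

### From 10-year risks to annual probabilities

Published validation studies report 10-year cumulative distant-recurrence
risks per group.  We convert them with a constant-hazard bridge,
`annual_prob_from_cumulative()`: `p = 1 - (1 - R10)^(1/10)`, whose inverse
property (compounding `p` for ten cycles reproduces `R10`) is enforced by
a unit test.  Chemotherapy multiplies the cumulative risk by
`1 - RRR` before conversion.  A cumulative risk of 1 would mean infinite
hazard and is rejected.

The recurrence hazard continues past year 10
(`recurrence_hazard_mode = "lifetime"`), which is a genuine modelling
choice — the validation studies only constrain the first decade.  We chose
the lifetime mode because the reported post-recurrence cost stream per
patient (on the order of ¥350,000 discounted) is several times larger than
what a hazard confined to ten years can generate at these risk levels; the
calibration section below makes that comparison executable.  The
ten-year mode remains available in the configuration.

### Competing risks

Within a cycle, recurrence (rate $r_1 = -\log(1-p_1)$) competes with
other-cause death (rate $r_2$) multiplicatively on the rate scale: total
event probability $1 - e^{-(r_1+r_2)}$, apportioned $r_1 : r_2$.  At the
magnitudes involved this differs from treating the risks as independent
binomials by less than $10^{-4}$, but the rate-scale form can never
produce a row sum above one, even at extreme sensitivity bounds.  The same
construction combines post-recurrence breast-cancer mortality (0.40/year)
with background mortality — the two causes compete rather than replace
each other, so total post-recurrence mortality slightly exceeds 40%/year
at old ages.

Fatal chemotherapy toxicity is a one-time event at model start with
probability 0.002 per treated patient.  No value is printed in the source
material, only a citation; 0.2% is a conventional order of magnitude for
anthracycline-era regimens, the parameter is exposed in the configuration
(including 0), and its tornado range is 0–0.4%.  Toxicity deaths are
booked as breast-cancer deaths (treatment-attributable); this is a
reporting convention with no effect on totals.

### Discounting and the half-cycle correction

Cycle *k* accrues at discount factor $(1+r)^{-(k+1/2)}$ with occupancy
taken as the mean of cycle-start and cycle-end mass (half-cycle correction
on, the default).  The alternative (cycle-start counting, $h = 0$) is
configurable; transitions then effectively happen at cycle boundaries and
time in the transient recurrence state is overstated by half a cycle.
Acute chemotherapy costs and the 0.53-QALY chemotherapy tariff are
time-zero lump sums and are never discounted: that convention, and only
that convention, reproduces the published acute-cost rows to the yen.

The cohort runs until the living mass drops below $10^{-12}$ or age 110,
whichever comes first; with the bundled life table traces end at 61 cycles.

## Inputs

All inputs live in `inst/extdata/config_default.yaml` and are validated on
load (`validate_inputs()`): proportions in [0, 1], sensitivity bounds
bracketing base values, cohort shares summing to 1.

* **Decision-impact counts.**  Group sizes 50/37/17 (of 104) and
  recommendation counts 16→0, 18→11, 14→17 are stored as integers; rates
  and shares are exact rationals derived from them.  Back-deriving the
  sizes from the published per-group percentages (16/0.320, 18/0.486,
  14/0.824) is what makes the acute-cost accounting exact to the yen,
  where the rounded 48%/36%/16% shares would not be.
* **Recurrence risks.**  Japanese validation estimates (3.3%, 0.0%, 24.8%)
  are the base case; US/UK estimates (5.4%, 13.7%, 29.2%) are a switchable
  alternative (`set_risk_source()`), swapping nothing else.  The
  intermediate-risk 0.0% is a legitimate degenerate case (no recurrences
  observed in the Japanese cohort) and must produce exactly zero
  recurrence occupancy — a unit test holds it there.
* **Relative risk reductions.**  0% / 39% / 74% by group, with wide
  sensitivity ranges (the low-risk upper bound of 54% produces the
  second-highest ICER in the sensitivity analysis).
* **Costs and utilities** as listed in the README, each with its
  tabulated low/high range.
* **Life table.**  Background mortality is an explicit input (CSV,
  `age,q_annual`).  The bundled file is a *synthetic* reconstruction of
  the Japanese female period life table around 2012–2013: published
  abridged anchor values, log-linearly interpolated to single years of
  age, chosen before any model output was inspected.  Lookup clamps to the
  tabulated range (beyond the last age the last probability applies).

## Synthetic data and the microsimulation oracle

`simulate_decision_impact()` emulates the observational study that the
strategy arms are built from: group membership and paired pre/post
recommendations drawn per patient.  It reproduces the study's *sampling*
structure — it does not model covariates (age, tumour size), physician
effects, or the study's exclusion criteria, so passing parameter-recovery
tests says nothing about those real-data features.  Feeding a large
synthetic table back through `inputs_from_decision_impact()` recovers the
base-case ICER up to the rates' sampling error.

`microsim()` is an individual-level Bernoulli re-implementation of the
same process: identical per-cycle probabilities, identical accrual and
discounting (transition cycles accrue the average of start- and end-state
rewards, matching the half-cycle convention — without that the oracle
would disagree with the cohort engine by construction).  The test suite
requires every cohort component to sit within 3 Monte-Carlo standard
errors of the oracle mean at n = 200,000 patients, for both arms and both
risk sources.  Draws are consumed in a fixed cycle-major order from one
seeded stream, so estimates are bit-reproducible for a given seed.

## Sensitivity and threshold analysis

`one_way_sensitivity()` varies each of the 19 bounded inputs to its low
and high bound (endpoints only), two full model evaluations per parameter,
and sorts by swing.  When a bound tips the assay into dominance
(cost-saving with QALY gain) the cost/QALY ratio is negative; we keep the
ratio rather than declaring the swing undefined, because the most
influential parameter — chemotherapy drug cost — crosses exactly that
boundary at its upper bound and belongs at the top of the tornado, where
the published diagrams place it.  The dominance flag is reported alongside.

`threshold_chemo_cost()` bisects the drug cost until |ΔCost| < ¥1
(bracket ¥0–¥10M; ΔCost is monotone in the drug cost because only the
acute-cost term depends on it).  A no-sign-change bracket returns `NA`
with a message rather than an error.

## Calibration of the under-specified choices

Three conventions are not pinned down by the source tables: hazard mode,
half-cycle correction, and fatal toxicity.  Their effect on the headline
results can be inspected directly:

```{r calibration, eval = FALSE}
variants <- list(
  base             = inp,
  ten_year_hazard  = within(inp, settings$recurrence_hazard_mode <- "first_10_years"),
  no_half_cycle    = within(inp, settings$half_cycle_correction <- FALSE),
  no_toxicity      = within(inp, settings$fatal_toxicity_risk <- 0)
)
sapply(variants, function(v) glance(cea_run(v))[c("icer", "delta_qaly")])
```

(`within()` here stands for modifying the settings list by hand;
`set_parameter()` covers the toxicity case.)  The qualitative picture:
the hazard mode is by far the most consequential choice — the ten-year
mode cuts the post-recurrence cost stream to less than half of the
reported level and raises the ICER by roughly 40%, which is why the
lifetime mode is the default.  The half-cycle correction moves the ICER
by well under 1% (both conventions discount at mid-cycle).  Removing
fatal toxicity shifts the ICER by about +3% (toxicity deaths, avoided
more often in the assay arm, contribute a small QALY gain).

## Problem sizes and runtime choices

The package's own test battery runs the cohort to extinction (≤ 61
cycles), the full 19-parameter tornado (39 model evaluations), bisection
threshold searches, and four microsimulation runs at n = 200,000 — sizes
chosen so the complete suite finishes in well under a minute on a single
core while keeping Monte-Carlo standard errors small enough for the 3-SE
oracle criterion to have teeth.

## Known limitations

* The life table is a synthetic stand-in; all life-table-dependent
  outputs (ICER, ΔQALY, survival) inherit a few percent of uncertainty,
  which is why the accounting identities are tested exactly but lifetime
  outcomes are tested against tolerance bands.
* Published immediate-QALY rows (−0.246/−0.144) exceed tariff × proportion
  (−0.2446/−0.1427) by ~0.001–0.003; the discrepancy is unexplained in the
  source (possibly an unrounded tariff near 0.533).  We compute the
  product and do not adjust toward the printed values.
* Local (non-distant) recurrence, second primaries, HER2-positive disease
  and post-recurrence treatment lines are out of scope, as is probabilistic
  sensitivity analysis (only one-way analyses are implemented).
* Utilities come from non-Japanese preference studies; the 10-year
  recurrence-free-survival figures count deaths from any cause and fatal
  toxicity as events (the convention that reproduces the published
  survival row).
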