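---
title: "A dynamic population model of COPD prevalence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic population model of COPD prevalence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdproj)
```

## The model

`copdproj` implements a deterministic, compartmental ("dynamic population")
model of chronic obstructive pulmonary disease in a national population aged
45 and over. It is not a microsimulation: the state is a single array of
continuous person counts over

* single-year age 45–110,
* sex,
* smoking status (never / ex / current),
* health state (no COPD, GOLD grade 1, GOLD grade 2, GOLD grade 3–4).

GOLD grades 3 and 4 are merged because every quantitative input available for
severe disease (prevalent shares, incident shares, a mortality relative risk)
is reported for the merged stratum; the model never resolves a stratum it
cannot parameterize. Death is a flow recorded in a per-cycle ledger, not a
compartment, which makes mass conservation a checkable identity:

```
end total = start total − deaths + entrants        (exact, every cycle)
```

Each calendar year the grid is advanced by five operations in a fixed order:
mortality → smoking transitions → incidence → GOLD progression → ageing with
entrant arrival. The source description of the model does not fix this
order, so it is a design choice of this package, made so that (i) deaths are
drawn from the start-of-year pool, (ii) newly diagnosed cases cannot
progress to a worse grade within their diagnosis year, and (iii) entrants
experience nothing until their first full year. The order is part of the
model contract — permuting it changes results, which is regression-tested —
and `step_year(order = ...)` exposes the permutation for exploration only.

Annual probabilities are applied as-is, with no half-cycle correction: every
published input is an annual probability, not an instantaneous rate, and
converting back and forth would manufacture precision the inputs do not
have. When multiplied risks exceed 1 (possible at high ages under the
relative-risk products) the death probability is capped at 1; the terminal
age 110 has probability 1 by construction, which closes the age ladder (any
mass that would survive past 110 under user-modified risks is retained in
an absorbing top age so conservation still holds).

## Inputs and their defaults

### Published constants (used verbatim)

| Quantity | Default | Units |
|---|---|---|
| Incidence, men / women | 0.006 / 0.003 | annual probability |
| Incident cases at GOLD 1–2 | 0.954 | share |
| Incident smoking mix current / ex / never | 0.635 / 0.329 / 0.036 | share |
| Diagnoses at age 65+ | 0.641 | share (calibration target) |
| Smoking transitions, COPD: quit / relapse | 0.047 / 0.026 | annual probability |
| Smoking transitions, no COPD: quit / relapse / initiate | 0.036 / 0.065 / 0.008 | annual probability |
| Mortality RR by grade G1 / G2 / G3–4 | 1.4 / 2.04 / 2.7 | ratio vs no COPD |
| 2005 prevalence, men / women / overall | 0.106 / 0.067 / 0.084 | probability |
| Prevalent grade split G1 / G2 / G3–4 | 0.584 / 0.374 / 0.042 | share of cases |
| Prevalent age split 45–54 / 55–64 / 65–74 / 75+ | 0.216 / 0.238 / 0.251 / 0.295 | share of cases |

The three 2005 prevalence figures are mutually inconsistent with a 54%
female population share (10.6% and 6.7% weighted by 46/54 give 8.49%, not
8.4%). The package anchors total cases at the overall 8.4% and rescales
both sex-specific prevalences by the common factor that achieves it
(≈ 0.989), preserving the published male:female ratio. Two published grade
splits also conflict (58.4/37.4/4.2 versus 51.4/31.5 with the remainder
severe); the first is internally consistent with the published 2005
prevalence-by-grade rates and is the default, while the second
(51.4/31.5/17.1) is kept as the built-in *alternative severity
distribution* used by the corresponding sensitivity scenario.

### Package defaults standing in for unpublished inputs

Four inputs are cited in the source literature but never printed; they are
package defaults, flagged as such wherever they appear, and all overridable:

* **GOLD transition matrix** — annual to-next-worse probability 0.15 (the
  midpoint of the 10–20% range that the sensitivity description attributes
  to the reference analysis), to-next-better 0.05, remainder on the
  diagonal, no two-grade jumps.
* **Smoking mortality RRs** — current 2.0, ex 1.3, never 1.0.
* **95% CI bounds of the grade mortality RRs** (used only by two
  scenarios) — G1 [1.2, 1.6], G2 [1.8, 2.3], G3–4 [2.3, 3.2].
* **Non-COPD smoking structure** by age band and sex — a synthetic
  French-mid-2000s-like pattern (male current smoking falling from 33% at
  45–54 to 8% at 75+ into a large ex-smoker pool; lower, more age-graded
  current smoking in women).

### The incidence age profile

The published sex-specific incidence rates are treated as population
averages. The age profile is a two-level multiplier (`lt65`, `ge65`) solved
in closed form so that 64.1% of incident cases arise at ages 65+ in the
reference at-risk population, then normalized so the at-risk-weighted mean
multiplier is 1 — the profile *redistributes* incidence across age without
changing the average rate. The alternative reading (0.6%/0.3% as under-65
rates with 65+ scaled up) would inflate total incidence by roughly 43% and
make "0.6% in men" false as a population statement, so it was rejected.
The multiplier is calibrated once against the reference demography and then
treated as a fixed input: sensitivity scenarios never re-calibrate it,
otherwise an incidence scenario would partly undo itself.

## Baseline calibration by iterative proportional fitting

The joint 2005 prevalence table over (age band × sex × smoking × grade) is
reconstructed from its one-dimensional marginals. Case-count margins are
built (sex prevalences × stratum populations, rescaled to the overall
anchor; case-share distributions × total cases) and `ipf_fit()` rakes a
seed table until every implied marginal matches its target, measured as the
maximum relative discrepancy (default tolerance 1e-8, at most 1000 sweeps;
non-convergence is an error that reports the worst discrepancy). With the
default all-ones seed and only one-dimensional margins the fixed point is
the independence table and is reached in one sweep; the full IPF machinery
matters when a user supplies a structured seed carrying interaction
patterns. Fitted case counts are divided by the (band, sex) populations to
give per-stratum probabilities; any stratum whose implied prevalence
exceeds 1 aborts the calibration with the offending stratum named. The
fitter is cross-checked in the test suite against a brute-force alternating
row/column scaling oracle (agreement to 1e-10 per cell on randomized
problems up to 4×4) and its per-sweep discrepancy history is asserted to be
non-increasing.

## The synthetic demography generator

The generator defines the study conditions; it is a first-class, tested
module, not a test fixture. It emulates three things:

* **2005 pyramid** — piecewise-exponential in age with a slope change at
  65: the pre-65 decay rate is a parameter (default 0.005/yr, nearly flat,
  as befits the large post-war cohorts then aged 45–60) and the post-65
  rate is solved with `uniroot` so the 65+ share hits its target exactly.
  Defaults reproduce the published aggregates: 25,665,019 persons 45+, 54%
  women, 49.3% aged 65+, each to well within 0.1%.
* **Entrant cohorts** — the persons turning 45 each year, 2006–2025. Their
  sizes are never published; the default is a constant 820,000/yr (a
  realistic size for the French cohorts reaching 45 in that window), with
  an optional linear drift, split by the pyramid's female share.
* **Background mortality** — Gompertz–Makeham per sex,
  `q(a) = 1 − exp(−(λ + α e^{β(a−45)}))`, with defaults shaped like an
  early-2000s western-European life table (e.g. male q ≈ 0.003 at 45,
  ≈ 0.013 at 65, ≈ 0.10 at 85). The terminal age is forced to q = 1.

What it does **not** emulate: cohort-to-cohort irregularities (war cohorts,
baby-boom spikes), migration, period mortality shocks, and any correlation
between smoking history and the demographic structure. Tests passing on
this demography therefore validate the *mechanics* of the model — not the
accuracy of French projections; with real INSEE tables loaded through
`load_demography()`, the same engine runs unchanged.

The generator is fully deterministic by default; an optional log-normal
jitter (with a seed) perturbs pyramid cells and then re-normalizes so the
three aggregates still hold — useful for robustness checks, never used in
the reference analysis.

## Sensitivity scenarios

A scenario is a named list of declarative edits (`multiply` or `set`) on
the model inputs — including the *marginals* feeding the IPF calibration,
so "alternative severity distribution" re-calibrates the joint baseline
table rather than crudely rescaling it. Distribution edits carry a
proportional renormalization rule: the unedited components shrink or grow
pro rata (how the published analysis renormalized is not stated; this rule
is recorded per edit). `builtin_scenarios()` returns the twelve alternative
hypotheses of the published battery: prevalence ±10%, the two alternative
prevalent-case distributions, incidence ±10%, female incidence raised to
male, severe incident share raised to 14%, to-worse GOLD transitions cut to
5%, grade-mortality RRs at each CI bound, and frozen smoking status. Each
scenario's rate tables are re-validated after editing; the report states
final-year overall and GOLD 3–4 prevalence per 1000 and relative percent
changes versus the reference, computed as `(scenario − reference) /
reference × 100` with no rounding.

## Numerical choices and degenerate inputs

* Counts are continuous doubles; no rounding or stochastic allocation
  anywhere in the engine. Two runs with equal inputs are bit-identical.
* Incident-case allocation across smoking strata is a water-filling loop:
  demand is split by the target mix, capped by stratum availability, and
  the shortfall re-offered to the remaining open strata pro rata; if the
  mix is exhausted, residual demand spreads over any remaining capacity.
  Total demand is also capped by the stratum's at-risk population.
* Distribution and transition-row sums are validated to 1e-9; IPF
  convergence to 1e-8 relative; conservation is asserted in tests to 1e-6
  relative on randomized systems.
* Empty strata are legal everywhere (0/0 cases-to-population divisions are
  defined as 0); a demography with a single populated age-sex cell is a
  supported degenerate case and is used by the unit tests.
* File loaders never zero-fill: a missing (age, sex) or table cell is an
  error naming the first gap.

## Problem sizes in the test suite

The state array is small (66 × 2 × 3 × 4), so full 21-year projections cost
milliseconds and the complete 13-run sensitivity battery a few seconds.
The suite runs the conservation property on 200 randomized systems, the
IPF-versus-oracle comparison on dozens of random problems, and an
individual-based Monte-Carlo cross-check with 10,000 persons over 20 years
(agreement asserted within 3 standard errors of the compartmental COPD
count each year). Several tests use a scaled-down synthetic population
(200,000 persons) purely because stratum arithmetic, not population size,
is what they exercise.

## Known limitations

* Absolute case counts inherit the published denominator inconsistency:
  the published 2005 case count implies a population ≈ 4% larger than the
  published population total on which this model is built, so projected
  *counts* sit below the published ones even where prevalence *rates*
  agree closely.
* The GOLD transition matrix is the documented stand-in; grade-specific
  long-horizon results (especially the GOLD 3–4 trajectory) are sensitive
  to it and should be read as structural, not numerical, statements unless
  the user supplies the cohort-estimated matrix.
* Transitions are age- and sex-homogeneous within their published
  stratification; smoking RRs apply uniformly across age, which likely
  overstates excess mortality at the oldest ages.
* Entrant cohort sizes are exogenous parameters; there is no fertility or
  migration component, and no modelling below age 45.
* The model has no remission to "no COPD", no under-diagnosis layer, and
  no comorbidity heterogeneity.
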