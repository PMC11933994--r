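---
title: "A Markov cohort model of kidney-transplant waiting-list dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of kidney-transplant waiting-list dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`waitlistsim` implements a deterministic, expected-value Markov cohort model
of US adults (18–79 years) with advanced chronic kidney disease
(eGFR ≤ 20 mL/min/1.73 m²) or dialysis-dependent kidney failure. A closed
cohort of 662,190 persons is stepped through monthly cycles over a 10-year
horizon. Seven health states are tracked:

* `CKD_UNLISTED`, `CKD_LISTED` — pre-dialysis CKD, off and on the transplant
  waiting list;
* `DIALYSIS_UNLISTED`, `DIALYSIS_LISTED` — maintenance dialysis, off and on
  the list;
* `REMOVED` — delisted without transplant (cannot be relisted, and faces at
  least dialysis-level mortality, reflecting the deteriorating health that
  usually motivates removal);
* `GRAFT_FUNCTIONING` — alive with a working transplant;
* `DEAD` — absorbing.

Each month, unlisted patients may progress from CKD to dialysis, be added to
the waiting list, undergo an off-list living-donor transplant (LDT), or die.
Listed patients may receive a deceased-donor transplant (DDT), be removed,
or die; under living-donor expansion policies they may also undergo LDT
while listed. At the moment of transplant a one-time perioperative death
probability applies; survivors enter `GRAFT_FUNCTIONING`, and graft failure
returns patients to unlisted dialysis, from which they may be relisted with
a fresh wait-time clock. The two listed states carry a months-since-listing
tunnel dimension, which is what makes wait-time estimation from the cohort
trace possible.

Modelling conventions worth stating explicitly:

* **Closed cohort.** No incident patients enter after model start; the model
  describes the 2022 prevalent population. Event flows therefore decline
  over the decade as the pools deplete.
* **Competing risks.** The monthly exit probabilities from each state are
  applied as mutually exclusive one-step probabilities with no half-cycle
  correction and no within-cycle ordering; at monthly granularity the error
  of ordering conventions is small. If a configuration pushes a state's exit
  probabilities above 1 the engine raises an error rather than renormalise.
* **No stratum migration.** Patients remain in their entry age stratum
  (18–44, 45–64, 65–79) for the full horizon.
* **Linearity.** The engine propagates expected person-counts, so every
  trace quantity scales proportionally with cohort size; fractional persons
  are intentional.

## Parameters and calibration

The parameter vector is one monthly probability per (age stratum,
transition); annual registry rates are converted with the constant-hazard
relation $p_m = 1-(1-p_a)^{1/12}$. Stratum-specific registry rates are not
published as such, so `generate_parameter_set()` provides a synthetic
`"registry2022"` preset: annual base rates with clinically sensible stratum
gradients (younger patients are listed and transplanted more, die and are
removed less), anchored so that an uncalibrated first-year simulation lands
within about 15% of the 2022 registry totals. A small seeded ±2%
perturbation makes distinct seeds give distinct but equally plausible sets.
The preset's free constants — the 20/45/35% stratum shares, a 550,000-person
dialysis population of whom 12.4% are wait-listed, 112,190 pre-dialysis CKD
patients of whom 21,800 are listed pre-emptively (a 90,000-person list), and
the mortality/graft-failure levels — are stated assumptions, not estimates
from registry microdata.

`calibrate_to_registry()` then closes the gap: for each of the five annual
flows (waiting-list additions 33,215; DDT 19,944; removals 6,040; LDT 5,660;
waiting-list deaths 4,454 — the 2022 SRTR/USRDS totals), a scalar factor on
the flow's monthly probabilities is solved by bisection so the simulated
first-year total matches the target, holding the other flows fixed. Flows
are visited from the largest to the smallest target because the dominant
flows set the at-risk pools the smaller flows depend on; sweeps repeat until
all five totals are simultaneously within the 0.5% validation tolerance.
Scaling preserves the preset's stratum pattern — only the level of each flow
is identified by five scalar targets, which is also why the parameter-
recovery guarantee (1% relative) applies to per-flow scale perturbations.
Each one-dimensional solve stops within 0.5 events of its target, so the
tolerance that matters in practice is the cross-flow interaction left after
the final sweep. Calibration targets first-year event counts rather than
steady-state rates because the validation comparison is made after one
model year.

## Expansion scenarios and count-constrained supply

`build_scenario_grid()` enumerates 19 strategies: the status quo;
waiting-list expansion alone at 10% and 50%; and each expansion level
crossed with DDT supply increases of 10/25/50/100% or LDT increases of
25/50/100/200%. List expansion scales the initial listed population (drawing
the increment proportionally from the matching unlisted pools, applied
equally to the CKD and dialysis lists) and the monthly listing probabilities
by the same factor.

The central mechanism is the supply constraint. Transplant *numbers*, not
per-person rates, are the policy quantity: a fixed per-person probability on
a longer list would mint extra organs. The status quo runs
probability-driven with the calibrated per-person DDT probability, and its
realized year-by-year transplant counts define every other scenario's
budget: each year's expected DDT count equals the status quo's count for
that same year times the DDT multiplier, spread evenly over the year's 12
cycles. Using the realized annual trajectory rather than the first-year
count held flat matters in a closed cohort: the status quo's own transplant
counts decline as the pools deplete, and pinning later years to the year-1
figure would drain the expanded lists and distort late-horizon hazards.
Within a cycle, `allocate_budgeted_transplants()` scales the per-cell
probabilities by a common factor λ (preserving the calibrated relative
allocation across strata) solved by one-dimensional root-finding so that
expected transplants equal the budget. Each cell's probability is capped at
its competing-exit headroom — one minus its other monthly exit
probabilities — so if supply ever exceeds what the remaining list can
absorb, the surplus is logged as unused budget instead of forcing exit
probabilities above 1.

Living-donor supply is handled analogously: off-list LDT is held at the
status quo's yearly counts in every scenario (keeping LDT "unchanged by
design" even though the unlisted pools differ under expansion), and under
LDT expansion the incremental supply — baseline × (multiplier − 1) — is
allocated uniformly per person to wait-listed patients, reflecting a
hypothetical policy newly incentivising living donation for listed
candidates while the established off-list pathway continues unchanged.

## Wait-time estimation

Wait time is measured from listing to transplant. `risk_set_from_trace()`
pools every listing entry cohort — including patients listed at model start,
who enter at duration 0 with no credit for pre-model waiting — onto a common
months-since-listing axis: `n_t` is the expected mass at risk in duration
month `t`, events are transplants (DDT plus on-list LDT; perioperative
deaths count as transplant events, not censorings), and censorings are
on-list deaths, removals, and mass still waiting at the simulation horizon.
`km_product_limit()` applies the product-limit formula
$S_t = \prod_{u \le t} (1 - d_u/n_u)$ directly to the expected fractional
counts, and `km_percentile()` reads the median and quartiles off the first
crossing of the corresponding survival level, returning `NA` when the curve
never gets there within the horizon — the same situation in which real-world
medians become incalculable because fewer than half of listed patients have
been transplanted.

Treating death and removal as censoring (rather than competing risks) is a
deliberate replication of the estimation approach being studied; it
implicitly assumes every listed patient would eventually be transplanted and
therefore understates "real" waits. An Aalen–Johansen competing-risk
estimator would be the natural extension but is out of scope here. Patients
relisted after graft failure start a new wait-time clock and contribute a
second spell.

## Cross-validation by microsimulation

`microsimulate()` pushes individual patients through the identical state
space by per-cycle categorical draws, reading its probabilities from the
same `build_stratum_transitions()` definition as the cohort engine, so the
two simulators cannot diverge in the transition graph. Initial states are
apportioned deterministically (largest remainder), so all Monte-Carlo noise
comes from the transitions. The test suite checks that state occupancy
proportions from 50,000 simulated patients fall within 3 binomial standard
errors of the engine's expectations at cycles 12, 60 and 120, and that the
pooled-trace Kaplan–Meier median agrees within one month with a standard
event-table Kaplan–Meier (computed with the `survival` package) on the
simulated records. The 3-SE band trades a little strictness for a
negligible flake rate.

## Numerical choices and problem sizes

* Probability conversions use the constant-hazard formula; its round trip is
  exact to ~1e−12 except where $1-(1-p_m)^{12}$ saturates in double
  precision (monthly probabilities above ~0.93, far outside the model's
  range).
* Calibration solves each flow to within 0.5 events and declares
  convergence at a 0.5% maximum relative deviation across all five flows;
  bisection is capped at 200 iterations per solve and 50 sweeps.
* The allocator's λ is found with `uniroot` at tolerance 1e−12; budget
  satisfaction holds to 1e−6 relative whenever listed demand suffices.
* Occupancy conservation is asserted at every cycle to 1e−9 relative;
  violations abort the run rather than accumulate.
* Parameter files are written at 17 significant digits so a save/load round
  trip is lossless.
* The shipped test and validation workloads use the full 662,190-person
  cohort over the full 120-cycle horizon (the engine is expected-value, so
  cohort size costs nothing), and 50,000 patients for microsimulation
  cross-checks, keeping the whole suite under a minute.

## What the synthetic conditions do and do not show

Because the published stratum-level inputs are not reproducible, all
quantitative guarantees here are about internal consistency: calibration
fidelity to the printed 2022 totals, estimator correctness, conservation,
linearity, budget satisfaction, and agreement between the two independent
simulators. The scenario analyses reproduce the *pattern* of the policy
conclusions — expansion alone lengthens median waits, more expansion
lengthens them more, and added organs shorten them monotonically within
each expansion level — but the absolute month values depend on the
synthetic stratum structure and should be read as illustrative, not as
replicated registry estimates. Real-data features the generator does not
emulate include blood-type and sensitisation matching, geographic variation
across organ procurement organisations, active/inactive list status, and
allocation-policy detail; all are out of scope by design.
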