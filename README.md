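# waitlistsim

A Markov cohort simulation of US kidney-transplant waiting-list dynamics.

## The problem

Kidney transplantation is rationed by organ supply: roughly 25,000 kidneys
are transplanted per year while over half a million adults live with
dialysis-dependent kidney failure, only 12–18% of whom are wait-listed.
Policy proposals pull in two directions — list more patients (to widen
access) and procure more organs (reduce discards, expand donation after
cardiac death, incentivise living donation). How median wait times respond
to combinations of these levers is the question this package simulates.

`waitlistsim` is for health-policy modellers and biostatisticians who want a
tested, reproducible implementation of a monthly-cycle decision-analytic
cohort model of this system: 662,190 adults (18–79 y) with advanced CKD
(eGFR ≤ 20) or ESKD, three age strata, seven health states (CKD and dialysis
on/off the waiting list, removed, graft functioning, dead), a 10-year
horizon, and wait-listing tracked by months since listing.

## The method

Three quantitative pieces sit at the core:

1. **Calibration.** Monthly transition probabilities are solved by bisection
   so that simulated first-year event totals match the 2022 SRTR/USRDS
   registry totals (DDT 19,944; LDT 5,660; additions 33,215; removals
   6,040; waiting-list deaths 4,454) to within 0.5%, the model's validation
   bar. Annual rates convert to monthly probabilities via
   `p_m = 1 − (1 − p_a)^(1/12)`.
2. **Count-constrained supply.** In expansion scenarios the number of
   transplants is a policy quantity: per-cell transplant probabilities are
   scaled by a common factor λ, solved each cycle so that expected
   transplants equal the scenario's budget (the status quo's realized
   year-by-year counts times the supply multiplier).
3. **Kaplan–Meier wait times.** All listing spells are pooled on a
   time-since-listing axis and the product-limit curve
   `S_t = Π (1 − d_u/n_u)` gives the probability of still waiting at month
   t; deaths and removals are treated as censoring. Medians and IQRs are
   read off the curve's level crossings.

Nineteen strategies are built in: status quo, 10%/50% waiting-list expansion
alone, and each expansion level combined with +10/25/50/100% deceased-donor
or +25/50/100/200% living-donor supply.

Published stratum-level inputs are not available, so the package generates
synthetic parameter sets anchored to the printed registry magnitudes
(`generate_parameter_set()`), calibrates them exactly, and cross-validates
the cohort engine against an individual-level microsimulation that shares
the same transition definitions.

## Worked example

```r
library(waitlistsim)

rep <- run_suite(list(seed = 2022,
                      scenarios = c("status_quo", "wl10", "wl50",
                                    "wl10_ddt25", "wl10_ldt50"),
                      horizon = 120))
print(rep$calibration)
#> Calibration: converged after 1 sweep(s); max relative deviation 0.00439
#>   ddt: 20031.6
#>   ldt: 5660.4
#>   additions: 33186.9
#>   removals: 6051.9
#>   waitlist_deaths: 4453.5
print(rep)
#> Scenario suite: 5 scenario(s), horizon 120 cycles
#>    scenario mwt_months q25_months q75_months mwt_change_months
#>  status_quo         37         16         74                 0
#>        wl10         42         18         85                 5
#>        wl50         63         25         NA                26
#>  wl10_ddt25         28         12         54                -9
#>  wl10_ldt50         36         15         71                -1
```

Reading the output: the calibrated status quo matches the five 2022 registry
flows within 0.5% and yields a median wait of 37 months (IQR 16–74).
Expanding the waiting list by 10% without extra organs lengthens the median
wait by 5 months, and by 50% lengthens it by 26 months (its 75th percentile
is `NA`: over a quarter of listed patients are still waiting at the 10-year
horizon). Adding 25% more deceased-donor kidneys to the 10%-longer list
shortens the median by 9 months relative to the status quo, while 50% more
living-donor transplants roughly holds it level. Absolute months depend on
the synthetic stratum structure; the ordering pattern is the robust result.

`run_suite(list(scenarios = "all", outdir = "out"))` runs all 19 strategies
and writes `scenario_summary.csv`, per-scenario Kaplan–Meier curves
(`km_curves.csv`, ready for replotting), the calibrated parameter file, a
calibration report and a run log.

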