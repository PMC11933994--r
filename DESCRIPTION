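Package: waitlistsim
Title: Markov Cohort Simulation of Kidney Transplant Waiting-List Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic monthly-cycle Markov cohort model of US adults
    with advanced chronic kidney disease and kidney failure, tracking movement
    between dialysis, the transplant waiting list, deceased- and living-donor
    transplantation, graft failure, list removal, and death. Monthly
    transition probabilities are calibrated by root-finding so that first-year
    simulated event totals reproduce annual registry totals. Waiting-list and
    organ-supply expansion scenarios are simulated with count-constrained
    transplant supply, and wait-time distributions are summarised by pooled
    Kaplan-Meier product-limit curves with medians and interquartile ranges.
    Includes an individual-level microsimulation that shares the cohort
    engine's transition structure, for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
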