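#' Define a waiting-list / organ-supply expansion scenario
#'
#' A scenario combines a waiting-list expansion factor (applied both to the
#' initial list size and to the monthly listing probabilities) with a
#' deceased-donor or living-donor supply multiplier. On-list living-donor
#' transplantation is enabled exactly when the LDT multiplier exceeds 1,
#' mirroring the hypothetical policy change that incentivises living
#' donation for wait-listed patients.
#'
#' @param name Scenario label.
#' @param list_factor Waiting-list expansion ratio (>= 1).
#' @param ddt_multiplier Deceased-donor supply multiplier (>= 1).
#' @param ldt_multiplier Living-donor supply multiplier (>= 1).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, list_factor = 1, ddt_multiplier = 1,
                          ldt_multiplier = 1) {
  stopifnot(is.character(name), length(name) == 1,
            list_factor >= 1, ddt_multiplier >= 1, ldt_multiplier >= 1)
  if (ddt_multiplier > 1 && ldt_multiplier > 1) {
    stop("at most one of `ddt_multiplier`, `ldt_multiplier` may exceed 1",
         call. = FALSE)
  }
  structure(list(name = name, list_factor = list_factor,
                 ddt_multiplier = ddt_multiplier,
                 ldt_multiplier = ldt_multiplier,
                 ldt_on_list = ldt_multiplier > 1),
            class = "scenario_spec")
}

#' The 19-strategy scenario grid
#'
#' Status quo; waiting-list expansion alone at 10% and 50%; each expansion
#' level crossed with deceased-donor supply increases of 10/25/50/100% and,
#' separately, living-donor supply increases of 25/50/100/200%.
#'
#' @return Named list of 19 `scenario_spec` objects.
#' @export
build_scenario_grid <- function() {
  grid <- list(scenario_spec("status_quo"))
  for (wl in c(10, 50)) {
    f <- 1 + wl / 100
    grid <- c(grid, list(scenario_spec(sprintf("wl%d", wl), list_factor = f)))
  }
  for (wl in c(10, 50)) {
    f <- 1 + wl / 100
    for (dd in c(10, 25, 50, 100)) {
      grid <- c(grid, list(scenario_spec(
        sprintf("wl%d_ddt%d", wl, dd),
        list_factor = f, ddt_multiplier = 1 + dd / 100)))
    }
    for (ld in c(25, 50, 100, 200)) {
      grid <- c(grid, list(scenario_spec(
        sprintf("wl%d_ldt%d", wl, ld),
        list_factor = f, ldt_multiplier = 1 + ld / 100)))
    }
  }
  names(grid) <- vapply(grid, `[[`, character(1), "name")
  grid
}

#' Scale the monthly listing probabilities
#'
#' Waiting-list expansion adds proportionally more patients to both the CKD
#' and dialysis waiting lists: `p_list_ckd` and `p_list_dialysis` are scaled
#' by `factor` in every stratum; all other parameters are untouched. An
#' error is raised (never silent renormalisation) if the scaling pushes a
#' competing-exit sum above 1.
#'
#' @param params A `transition_set`.
#' @param factor Ratio >= 1.
#' @return A new validated `transition_set`.
#' @export
apply_list_expansion <- function(params, factor) {
  stopifnot(inherits(params, "transition_set"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1) {
    stop("`factor` must be a single number >= 1", call. = FALSE)
  }
  v <- params$values
  v[, c("p_list_ckd", "p_list_dialysis")] <-
    v[, c("p_list_ckd", "p_list_dialysis")] * factor
  transition_set(v)
}

#' Derive the per-cycle organ budget for a scenario
#'
#' Annual transplant numbers are fixed policy quantities in the expansion
#' scenarios; budgets spread them evenly across the 12 cycles of each year.
#' The deceased-donor budget is the baseline annual count times the DDT
#' multiplier. Living-donor supply stays at its baseline count off the list
#' in every scenario; under LDT expansion only the *incremental* supply
#' (baseline x (multiplier - 1)) is budgeted, and it is allocated to
#' wait-listed patients.
#'
#' `derive_budget()` works from a single year's baseline totals.
#' [budget_from_trace()] generalises it to the status quo's realized
#' year-by-year totals, which decline as the closed cohort depletes; the
#' expansion scenarios hold each year's transplant numbers at the status
#' quo's number for that year (times the multiplier).
#'
#' @param baseline_annual An `annual_targets` (the calibrated status-quo
#'   first-year totals).
#' @param scenario A `scenario_spec`.
#' @return List with `ddt_per_cycle`, `ldt_offlist_per_cycle`, and
#'   `ldt_on_list_per_cycle` (`NULL` when the LDT multiplier is 1), each in
#'   expected transplants per month.
#' @export
derive_budget <- function(baseline_annual, scenario) {
  stopifnot(inherits(baseline_annual, "annual_targets"),
            inherits(scenario, "scenario_spec"))
  list(
    ddt_per_cycle = baseline_annual$ddt * scenario$ddt_multiplier / 12,
    ldt_offlist_per_cycle = baseline_annual$ldt / 12,
    ldt_on_list_per_cycle = if (scenario$ldt_multiplier > 1) {
      baseline_annual$ldt * (scenario$ldt_multiplier - 1) / 12
    }
  )
}

#' @rdname derive_budget
#' @param baseline_trace The status-quo `cohort_trace` whose realized annual
#'   transplant counts define the budgets.
#' @export
budget_from_trace <- function(baseline_trace, scenario) {
  stopifnot(inherits(baseline_trace, "cohort_trace"),
            inherits(scenario, "scenario_spec"))
  H <- baseline_trace$horizon
  years <- H %/% 12
  if (years * 12 != H) {
    stop("baseline trace horizon must be a whole number of years",
         call. = FALSE)
  }
  ddt_y <- vapply(seq_len(years),
                  function(y) annual_counts(baseline_trace, y)[["ddt"]],
                  numeric(1))
  ldt_y <- vapply(seq_len(years),
                  function(y) annual_counts(baseline_trace, y)[["ldt"]],
                  numeric(1))
  list(
    ddt_per_cycle = rep(ddt_y * scenario$ddt_multiplier / 12, each = 12),
    ldt_offlist_per_cycle = rep(ldt_y / 12, each = 12),
    ldt_on_list_per_cycle = if (scenario$ldt_multiplier > 1) {
      rep(ldt_y * (scenario$ldt_multiplier - 1) / 12, each = 12)
    }
  )
}

#' Allocate a fixed transplant supply over listed cells
#'
#' Solves for the scalar `lambda >= 0` such that per-cell transplant
#' probabilities `min(lambda * base_p, cap)` yield a total expected
#' transplant count equal to `min(budget, achievable demand)`, where the
#' achievable demand is `sum(cap * n)`; relative allocation across cells is
#' preserved wherever the cap does not bind. This is the mechanism that
#' holds transplant *numbers* fixed while the waiting list grows or shrinks.
#'
#' Each cell's cap is the largest transplant probability it can absorb --
#' inside the engine this is the cell's competing-exit headroom (1 minus its
#' other monthly exit probabilities), so supply beyond what the shrinking
#' list can take is reported as `unused_budget` rather than forcing the
#' competing exits above 1.
#'
#' @param n Expected person-count per listed cell (non-negative).
#' @param base_p Baseline per-person transplant probability per cell.
#' @param budget Expected transplants this cycle (>= 0).
#' @param cap Per-cell upper bound on the allocated probability (scalar or
#'   per-cell vector; default 1).
#' @return Numeric vector of per-cell probabilities, with attribute
#'   `unused_budget` (positive when listed demand cannot absorb the supply)
#'   and `lambda`.
#' @export
allocate_budgeted_transplants <- function(n, base_p, budget, cap = 1) {
  stopifnot(is.numeric(n), is.numeric(base_p), length(n) == length(base_p),
            all(n >= 0), all(base_p >= 0), all(base_p <= 1),
            is.numeric(budget), length(budget) == 1, budget >= 0)
  cap <- rep_len(pmin(pmax(cap, 0), 1), length(n))
  achievable <- sum(cap * n)
  out <- numeric(length(n))
  if (budget == 0 || achievable == 0 || sum(base_p * n) == 0) {
    attr(out, "unused_budget") <- budget
    attr(out, "lambda") <- 0
    return(out)
  }
  target <- min(budget, achievable)
  if (target >= achievable) {
    out <- cap
    attr(out, "unused_budget") <- budget - achievable
    attr(out, "lambda") <- Inf
    return(out)
  }
  expected <- function(lam) sum(pmin(lam * base_p, cap) * n)
  active <- base_p > 0 & n > 0
  lam_hi <- max(cap[active] / base_p[active])  # all active cells at cap
  while (expected(lam_hi) < target) lam_hi <- lam_hi * 2
  lam <- stats::uniroot(function(l) expected(l) - target, c(0, lam_hi),
                        tol = 1e-12)$root
  out <- pmin(lam * base_p, cap)
  attr(out, "unused_budget") <- budget - target
  attr(out, "lambda") <- lam
  out
}

#' Run one expansion scenario on calibrated parameters
#'
#' Applies the scenario's list expansion to both the initial occupancy and
#' the listing probabilities, derives the organ budget (except for the
#' status quo, which runs fully probability-driven with the calibrated
#' per-person transplant probabilities), and runs the cohort engine.
#'
#' @param params Calibrated `transition_set`.
#' @param spec A `cohort_spec`.
#' @param scenario A `scenario_spec`.
#' @param baseline Status-quo supply definition, required for any
#'   non-status-quo scenario: either the status-quo `cohort_trace` (budgets
#'   follow its realized year-by-year transplant counts, the default in
#'   [run_suite()]) or an `annual_targets` (first-year totals held flat over
#'   the horizon).
#' @param horizon Cycles to run (default the spec's horizon).
#' @return A `cohort_trace`.
#' @export
run_scenario <- function(params, spec, scenario, baseline = NULL,
                         horizon = spec$horizon) {
  stopifnot(inherits(scenario, "scenario_spec"))
  is_sq <- scenario$list_factor == 1 && scenario$ddt_multiplier == 1 &&
    scenario$ldt_multiplier == 1
  budget <- NULL
  if (!is_sq) {
    if (inherits(baseline, "cohort_trace")) {
      budget <- budget_from_trace(baseline, scenario)
    } else if (inherits(baseline, "annual_targets")) {
      budget <- derive_budget(baseline, scenario)
    } else {
      stop(paste("`baseline` (a status-quo trace or annual targets) is",
                 "required for non-status-quo scenarios"), call. = FALSE)
    }
  }
  params_s <- apply_list_expansion(params, scenario$list_factor)
  occ0 <- make_initial_occupancy(spec, scenario$list_factor)
  run_model(occ0, params_s, horizon = horizon, budget = budget,
            scenario = scenario$name)
}
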