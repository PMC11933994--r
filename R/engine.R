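#' Build the initial occupancy of the cohort
#'
#' Distributes the cohort across (stratum, state) cells according to the
#' cohort specification, optionally expanding the waiting list at model
#' start: listed cells are scaled by `list_expansion_factor`, with the
#' increment drawn proportionally from the corresponding unlisted cells
#' (CKD-listed from CKD-unlisted, dialysis-listed from dialysis-unlisted,
#' within each stratum), so the grand total is preserved. All initial listed
#' persons start with 0 months since listing.
#'
#' @param spec A [cohort_spec()].
#' @param list_expansion_factor Ratio >= 1; 1 reproduces the spec's split.
#' @return An object of class `occupancy`: per-stratum person-counts for the
#'   five unlisted states plus months-since-listing-resolved counts for the
#'   two listed states (durations 0..horizon).
#' @export
make_initial_occupancy <- function(spec, list_expansion_factor = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  f <- list_expansion_factor
  if (!is.numeric(f) || length(f) != 1 || f < 1) {
    stop("`list_expansion_factor` must be a single number >= 1", call. = FALSE)
  }
  H <- spec$horizon
  counts <- spec$total * spec$split
  ns <- length(age_strata())

  unlisted <- counts[, UNLISTED_STATES, drop = FALSE]
  lc0 <- counts[, "CKD_LISTED"]
  ld0 <- counts[, "DIALYSIS_LISTED"]
  extra_c <- (f - 1) * lc0
  extra_d <- (f - 1) * ld0
  if (any(unlisted[, "CKD_UNLISTED"] - extra_c < -1e-9) ||
      any(unlisted[, "DIALYSIS_UNLISTED"] - extra_d < -1e-9)) {
    stop("insufficient unlisted pool for the requested list expansion",
         call. = FALSE)
  }
  unlisted[, "CKD_UNLISTED"] <- unlisted[, "CKD_UNLISTED"] - extra_c
  unlisted[, "DIALYSIS_UNLISTED"] <- unlisted[, "DIALYSIS_UNLISTED"] - extra_d

  listed_ckd <- matrix(0, ns, H + 1)
  listed_dial <- matrix(0, ns, H + 1)
  listed_ckd[, 1] <- lc0 * f
  listed_dial[, 1] <- ld0 * f
  structure(list(unlisted = unlisted, listed_ckd = listed_ckd,
                 listed_dial = listed_dial, horizon = H),
            class = "occupancy")
}

#' Total person-count of an occupancy
#' @param occ An `occupancy`.
#' @return Total expected persons over all cells.
#' @export
occupancy_total <- function(occ) {
  stopifnot(inherits(occ, "occupancy"))
  sum(occ$unlisted) + sum(occ$listed_ckd) + sum(occ$listed_dial)
}

EVENT_COLS <- c("listings", "ddt", "ldt", "removals", "waitlist_deaths",
                "dialysis_deaths", "ckd_deaths", "posttx_deaths",
                "periop_deaths", "graft_failures")

# Resolve this cycle's transplant probabilities, honouring an optional organ
# budget. Deceased-donor supply is allocated over the six listed cells
# (CKD-listed and dialysis-listed x 3 strata) with the calibrated per-person
# probability as the allocation base; the incremental on-list living-donor
# budget is spread uniformly per listed person; the off-list living-donor
# budget is allocated over the unlisted CKD/dialysis cells with the baseline
# off-list LDT probability as the base. Each cell's transplant probability
# is capped at its competing-exit headroom, so excess supply surfaces as
# unused budget instead of pushing the cell's exit probabilities above 1.
# DDT is allocated before the on-list LDT increment.
cycle_transplant_probs <- function(params, occ, budget) {
  v <- params$values
  unused <- 0

  n_l <- c(rowSums(occ$listed_ckd), rowSums(occ$listed_dial))
  p_ddt <- rep(v[, "p_ddt_listed"], 2)
  p_ldt <- rep(v[, "p_ldt_listed"], 2)
  other_l <- c(
    v[, "p_removal"] + v[, "p_death_listed"] + v[, "p_progress"],  # CKD-listed
    v[, "p_removal"] + v[, "p_death_listed"]                       # dial-listed
  )
  if (!is.null(budget) && !is.null(budget$ddt_per_cycle)) {
    cap <- pmax(1 - other_l - p_ldt, 0)
    p <- allocate_budgeted_transplants(n_l, rep(v[, "p_ddt_listed"], 2),
                                       budget$ddt_per_cycle, cap)
    unused <- unused + attr(p, "unused_budget")
    p_ddt <- as.numeric(p)
  }
  if (!is.null(budget) && !is.null(budget$ldt_on_list_per_cycle)) {
    cap <- pmax(1 - other_l - p_ddt - p_ldt, 0)
    p <- allocate_budgeted_transplants(n_l, rep(1, length(n_l)),
                                       budget$ldt_on_list_per_cycle, cap)
    unused <- unused + attr(p, "unused_budget")
    p_ldt <- p_ldt + as.numeric(p)
  }

  p_ldtu <- rep(v[, "p_ldt_unlisted"], 2)
  if (!is.null(budget) && !is.null(budget$ldt_offlist_per_cycle)) {
    n_u <- c(occ$unlisted[, "CKD_UNLISTED"], occ$unlisted[, "DIALYSIS_UNLISTED"])
    other_u <- c(
      v[, "p_progress"] + v[, "p_list_ckd"] + v[, "p_death_ckd"],
      v[, "p_list_dialysis"] + v[, "p_death_dialysis"]
    )
    cap <- pmax(1 - other_u, 0)
    p <- allocate_budgeted_transplants(n_u, rep(v[, "p_ldt_unlisted"], 2),
                                       budget$ldt_offlist_per_cycle, cap)
    unused <- unused + attr(p, "unused_budget")
    p_ldtu <- as.numeric(p)
  }

  list(p_ddt_ckd = p_ddt[1:3], p_ddt_dial = p_ddt[4:6],
       p_ldt_ckd = p_ldt[1:3], p_ldt_dial = p_ldt[4:6],
       p_ldtu_ckd = p_ldtu[1:3], p_ldtu_dial = p_ldtu[4:6],
       unused_budget = unused)
}

#' Advance the cohort by one monthly cycle
#'
#' Applies the competing monthly exit probabilities of every origin state as
#' mutually exclusive one-step probabilities (no half-cycle correction, no
#' within-cycle event ordering); residual mass remains in place. Transplanted
#' mass splits by the one-time perioperative death probability into `DEAD`
#' versus `GRAFT_FUNCTIONING`; graft failure routes to `DIALYSIS_UNLISTED`
#' (relistable with a fresh wait-time clock). Months-since-listing advances
#' by one for listed mass that remains listed; newly listed mass enters at
#' duration 0. Total occupancy is conserved.
#'
#' @param occ An `occupancy`.
#' @param params A `transition_set`.
#' @param budget Optional organ budget for this cycle, a list with any of
#'   `ddt_per_cycle`, `ldt_on_list_per_cycle`, `ldt_offlist_per_cycle`
#'   (expected transplants this month); `NULL` runs fully
#'   probability-driven.
#' @return List with elements `occupancy` (the advanced state), `events`
#'   (named numeric vector of expected event counts for the cycle),
#'   `tx_by_dur` and `cens_by_dur` (events and censorings from listed states
#'   by months-since-listing at cycle start), and `unused_budget`.
#' @export
step_cycle <- function(occ, params, budget = NULL) {
  stopifnot(inherits(occ, "occupancy"), inherits(params, "transition_set"))
  H <- occ$horizon
  ns <- length(age_strata())
  nd <- H + 1

  if (any(occ$listed_ckd[, nd] > 0) || any(occ$listed_dial[, nd] > 0)) {
    stop("listed mass already at maximal duration; cannot advance the cycle",
         call. = FALSE)
  }

  tp <- cycle_transplant_probs(params, occ, budget)

  new_unlisted <- occ$unlisted
  new_lc <- matrix(0, ns, nd)
  new_ld <- matrix(0, ns, nd)
  ev <- stats::setNames(numeric(length(EVENT_COLS)), EVENT_COLS)
  tx_by_dur <- numeric(nd)
  cens_by_dur <- numeric(nd)

  for (s in seq_len(ns)) {
    tr <- build_stratum_transitions(params, s)
    p_ddt_c <- tp$p_ddt_ckd[s];  p_ddt_d <- tp$p_ddt_dial[s]
    p_ldt_c <- tp$p_ldt_ckd[s];  p_ldt_d <- tp$p_ldt_dial[s]

    # listed-state competing exits (duration-independent, incl. budget scaling)
    sum_lc <- p_ddt_c + p_ldt_c + tr$CKD_LISTED[["removal"]] +
      tr$CKD_LISTED[["death"]] + tr$CKD_LISTED[["progress"]]
    sum_ld <- p_ddt_d + p_ldt_d + tr$DIALYSIS_LISTED[["removal"]] +
      tr$DIALYSIS_LISTED[["death"]]
    if (sum_lc > 1 + 1e-9 || sum_ld > 1 + 1e-9) {
      stop(sprintf(
        "competing exit probabilities exceed 1 for listed states in stratum %s (sums %.4f / %.4f)",
        age_strata()[s], sum_lc, sum_ld), call. = FALSE)
    }

    lc <- occ$listed_ckd[s, ]
    ld <- occ$listed_dial[s, ]

    ddt_lc <- p_ddt_c * lc;    ddt_ld <- p_ddt_d * ld
    ldt_lc <- p_ldt_c * lc;    ldt_ld <- p_ldt_d * ld
    rem_lc <- tr$CKD_LISTED[["removal"]] * lc
    rem_ld <- tr$DIALYSIS_LISTED[["removal"]] * ld
    die_lc <- tr$CKD_LISTED[["death"]] * lc
    die_ld <- tr$DIALYSIS_LISTED[["death"]] * ld
    prog_lc <- tr$CKD_LISTED[["progress"]] * lc

    stay_lc <- lc - ddt_lc - ldt_lc - rem_lc - die_lc - prog_lc
    stay_ld <- ld - ddt_ld - ldt_ld - rem_ld - die_ld

    # duration clock advances for everyone who remains listed, including
    # listed CKD mass progressing to dialysis (they stay on the list)
    new_lc[s, 2:nd] <- stay_lc[1:H]
    new_ld[s, 2:nd] <- stay_ld[1:H] + prog_lc[1:H]

    # unlisted origins
    u <- occ$unlisted[s, ]
    cu <- u[["CKD_UNLISTED"]]; du <- u[["DIALYSIS_UNLISTED"]]
    ru <- u[["REMOVED"]]; gu <- u[["GRAFT_FUNCTIONING"]]

    prog_u <- tr$CKD_UNLISTED[["progress"]] * cu
    list_c <- tr$CKD_UNLISTED[["listing"]] * cu
    ldt_cu <- tp$p_ldtu_ckd[s] * cu
    die_cu <- tr$CKD_UNLISTED[["death"]] * cu

    list_d <- tr$DIALYSIS_UNLISTED[["listing"]] * du
    ldt_du <- tp$p_ldtu_dial[s] * du
    die_du <- tr$DIALYSIS_UNLISTED[["death"]] * du

    die_r <- tr$REMOVED[["death"]] * ru
    gfail <- tr$GRAFT_FUNCTIONING[["graft_failure"]] * gu
    die_g <- tr$GRAFT_FUNCTIONING[["death"]] * gu

    # transplanted mass this cycle: perioperative split
    tx <- sum(ddt_lc) + sum(ddt_ld) + sum(ldt_lc) + sum(ldt_ld) +
      ldt_cu + ldt_du
    periop <- tx * tr$p_periop_death
    to_graft <- tx - periop

    new_unlisted[s, "CKD_UNLISTED"] <- cu - prog_u - list_c - ldt_cu - die_cu
    new_unlisted[s, "DIALYSIS_UNLISTED"] <- du - list_d - ldt_du - die_du +
      prog_u + gfail
    new_unlisted[s, "REMOVED"] <- ru - die_r + sum(rem_lc) + sum(rem_ld)
    new_unlisted[s, "GRAFT_FUNCTIONING"] <- gu - gfail - die_g + to_graft
    new_unlisted[s, "DEAD"] <- u[["DEAD"]] + die_cu + die_du + die_r + die_g +
      sum(die_lc) + sum(die_ld) + periop

    new_lc[s, 1] <- new_lc[s, 1] + list_c
    new_ld[s, 1] <- new_ld[s, 1] + list_d

    ev["listings"] <- ev["listings"] + list_c + list_d
    ev["ddt"] <- ev["ddt"] + sum(ddt_lc) + sum(ddt_ld)
    ev["ldt"] <- ev["ldt"] + sum(ldt_lc) + sum(ldt_ld) + ldt_cu + ldt_du
    ev["removals"] <- ev["removals"] + sum(rem_lc) + sum(rem_ld)
    ev["waitlist_deaths"] <- ev["waitlist_deaths"] + sum(die_lc) + sum(die_ld)
    ev["dialysis_deaths"] <- ev["dialysis_deaths"] + die_du
    ev["ckd_deaths"] <- ev["ckd_deaths"] + die_cu
    ev["posttx_deaths"] <- ev["posttx_deaths"] + die_g
    ev["periop_deaths"] <- ev["periop_deaths"] + periop
    ev["graft_failures"] <- ev["graft_failures"] + gfail

    tx_by_dur <- tx_by_dur + ddt_lc + ddt_ld + ldt_lc + ldt_ld
    cens_by_dur <- cens_by_dur + rem_lc + rem_ld + die_lc + die_ld
  }

  if (any(new_unlisted < -1e-9) || any(new_lc < -1e-9) || any(new_ld < -1e-9)) {
    stop("negative occupancy produced; check transition probabilities",
         call. = FALSE)
  }

  new_occ <- structure(list(unlisted = new_unlisted, listed_ckd = new_lc,
                            listed_dial = new_ld, horizon = H),
                       class = "occupancy")
  total0 <- occupancy_total(occ)
  if (abs(occupancy_total(new_occ) - total0) > 1e-9 * max(total0, 1)) {
    stop("occupancy conservation violated in step_cycle", call. = FALSE)
  }
  list(occupancy = new_occ, events = ev, tx_by_dur = tx_by_dur,
       cens_by_dur = cens_by_dur, unused_budget = tp$unused_budget)
}

#' Run the cohort model over a fixed horizon
#'
#' Steps the occupancy through `horizon` monthly cycles and records the full
#' trace: occupancy at every cycle, per-cycle expected event counts, and the
#' listed-state events and censorings resolved by months since listing
#' (required by the wait-time estimator). Deterministic: identical inputs
#' give identical traces.
#'
#' @param occ0 Initial `occupancy` from [make_initial_occupancy()].
#' @param params A `transition_set`.
#' @param horizon Number of monthly cycles to simulate (default 120).
#' @param budget Optional organ budget (see [step_cycle()]); each element
#'   may be a single per-cycle count or a vector of length `horizon` giving
#'   a per-cycle trajectory.
#' @param scenario Scenario label stored in the trace.
#' @return An object of class `cohort_trace`.
#' @export
run_model <- function(occ0, params, horizon = 120L, budget = NULL,
                      scenario = "status_quo") {
  stopifnot(inherits(occ0, "occupancy"), horizon >= 0,
            horizon <= occ0$horizon)
  H <- occ0$horizon
  nd <- H + 1
  occs <- vector("list", horizon + 1)
  occs[[1]] <- occ0
  events <- matrix(0, horizon, length(EVENT_COLS),
                   dimnames = list(NULL, EVENT_COLS))
  tx_by_dur <- matrix(0, horizon, nd)
  cens_by_dur <- matrix(0, horizon, nd)
  listed_occ <- matrix(0, horizon + 1, nd)
  listed_occ[1, ] <- colSums(occ0$listed_ckd) + colSums(occ0$listed_dial)
  unused_budget <- numeric(horizon)

  if (!is.null(budget)) {
    budget <- lapply(budget, function(b) {
      if (is.null(b)) return(NULL)
      if (length(b) == 1) rep(b, horizon)
      else if (length(b) == horizon) b
      else stop("budget trajectories must have length 1 or `horizon`",
                call. = FALSE)
    })
  }
  occ <- occ0
  for (cyc in seq_len(horizon)) {
    budget_c <- if (!is.null(budget)) lapply(budget, `[`, cyc)
    step <- tryCatch(step_cycle(occ, params, budget_c),
                     error = function(e) {
                       stop(sprintf("cycle %d: %s", cyc, conditionMessage(e)),
                            call. = FALSE)
                     })
    occ <- step$occupancy
    occs[[cyc + 1]] <- occ
    events[cyc, ] <- step$events
    tx_by_dur[cyc, ] <- step$tx_by_dur
    cens_by_dur[cyc, ] <- step$cens_by_dur
    listed_occ[cyc + 1, ] <- colSums(occ$listed_ckd) + colSums(occ$listed_dial)
    unused_budget[cyc] <- step$unused_budget
  }
  structure(list(occupancies = occs,
                 events = as.data.frame(events),
                 tx_by_dur = tx_by_dur, cens_by_dur = cens_by_dur,
                 listed_occ = listed_occ, horizon = as.integer(horizon),
                 scenario = scenario, params = params,
                 unused_budget = unused_budget),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", x$scenario, "-", x$horizon, "cycles,",
      format(occupancy_total(x$occupancies[[1]]), big.mark = ","),
      "persons\n")
  invisible(x)
}

#' Sum per-cycle event counts over one model year
#'
#' @param trace A `cohort_trace`.
#' @param year Year index (1 = cycles 1-12).
#' @return Named numeric vector of annual expected event counts.
#' @export
annual_counts <- function(trace, year = 1) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (!is.numeric(year) || length(year) != 1 || year < 1 ||
      12 * year > trace$horizon) {
    stop("`year` out of range for this trace", call. = FALSE)
  }
  rows <- ((year - 1) * 12 + 1):(year * 12)
  colSums(trace$events[rows, , drop = FALSE])
}

#' Export a trace as tidy data frames
#'
#' @param trace A `cohort_trace`.
#' @return List of two data frames: `occupancy` (cycle, stratum, state,
#'   duration, count; duration is `NA` for unlisted states) and `events`
#'   (cycle plus one column per event type).
#' @export
trace_to_df <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  ns <- length(age_strata())
  rows <- lapply(seq_along(trace$occupancies), function(i) {
    occ <- trace$occupancies[[i]]
    nd <- occ$horizon + 1
    u <- data.frame(
      cycle = i - 1L,
      stratum = rep(age_strata(), times = length(UNLISTED_STATES)),
      state = rep(UNLISTED_STATES, each = ns),
      duration = NA_integer_,
      count = as.vector(occ$unlisted)
    )
    l <- data.frame(
      cycle = i - 1L,
      stratum = rep(age_strata(), times = 2 * nd),
      state = rep(rep(LISTED_STATES, each = nd * ns), times = 1),
      duration = rep(rep(0:(nd - 1), each = ns), times = 2),
      count = c(as.vector(occ$listed_ckd), as.vector(occ$listed_dial))
    )
    rbind(u, l[l$count > 0 | l$duration == 0, ])
  })
  occ_df <- do.call(rbind, rows)
  ev_df <- cbind(cycle = seq_len(trace$horizon), trace$events)
  list(occupancy = occ_df, events = ev_df)
}
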