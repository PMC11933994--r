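# Shared fixtures, built in code. The cache avoids re-running the ~2 s
# registry calibration in every file that needs it.
.fixture_cache <- new.env(parent = emptyenv())

canonical_params <- function() generate_parameter_set(2022, "registry2022")

canonical_calibration <- function() {
  if (is.null(.fixture_cache$cal)) {
    .fixture_cache$cal <- calibrate_to_registry(
      registry_targets_2022(), default_cohort_spec(), canonical_params())
  }
  .fixture_cache$cal
}

status_quo_trace <- function(horizon = 120) {
  key <- paste0("sq", horizon)
  if (is.null(.fixture_cache[[key]])) {
    cal <- canonical_calibration()
    .fixture_cache[[key]] <- run_scenario(
      cal$params, default_cohort_spec(), scenario_spec("status_quo"),
      horizon = horizon)
  }
  .fixture_cache[[key]]
}

# transition set with the named monthly probabilities set and all others 0
toy_params <- function(...) {
  v <- matrix(0, 3, length(waitlistsim:::PARAM_NAMES),
              dimnames = list(age_strata(), waitlistsim:::PARAM_NAMES))
  args <- list(...)
  for (nm in names(args)) v[, nm] <- args[[nm]]
  transition_set(v)
}

# small cohort concentrated on the waiting list, handy for listed-state
# arithmetic; horizon kept short for speed
toy_spec <- function(total = 100000, ckd_listed = 0.1, dial_listed = 0.8,
                     horizon = 24) {
  split <- matrix(0, 3, 7, dimnames = list(age_strata(), health_states()))
  split[, "CKD_LISTED"] <- ckd_listed / 3
  split[, "DIALYSIS_LISTED"] <- dial_listed / 3
  split[, "DIALYSIS_UNLISTED"] <- (1 - ckd_listed - dial_listed) / 3
  cohort_spec(total, split, horizon)
}

engine_state_proportions <- function(occ) {
  vapply(health_states(), function(st) {
    if (st == "CKD_LISTED") sum(occ$listed_ckd)
    else if (st == "DIALYSIS_LISTED") sum(occ$listed_dial)
    else sum(occ$unlisted[, st])
  }, numeric(1)) / occupancy_total(occ)
}
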