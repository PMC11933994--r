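test_that("initial occupancy reproduces the cohort split and scales the list", {
  spec <- default_cohort_spec()
  occ <- make_initial_occupancy(spec, 1)
  expect_equal(occupancy_total(occ), spec$total)
  expect_equal(occ$unlisted, spec$total * spec$split[, waitlistsim:::UNLISTED_STATES])
  expect_equal(occ$listed_ckd[, 1], spec$total * spec$split[, "CKD_LISTED"],
               ignore_attr = TRUE)
  expect_true(all(occ$listed_ckd[, -1] == 0))

  occ15 <- make_initial_occupancy(spec, 1.5)
  expect_equal(sum(occ15$listed_ckd) + sum(occ15$listed_dial),
               1.5 * (sum(occ$listed_ckd) + sum(occ$listed_dial)))
  expect_equal(occupancy_total(occ15), spec$total)
})

test_that("list expansion draws the increment from the matching unlisted pools", {
  split <- matrix(0, 3, 7, dimnames = list(age_strata(), health_states()))
  split[, "CKD_UNLISTED"] <- 0.15 / 3
  split[, "CKD_LISTED"] <- 0.10 / 3
  split[, "DIALYSIS_UNLISTED"] <- 0.45 / 3
  split[, "DIALYSIS_LISTED"] <- 0.30 / 3
  spec <- cohort_spec(100000, split, 12)
  occ <- make_initial_occupancy(spec, 1.1)
  # 10,000 CKD-listed -> 11,000 and 30,000 dialysis-listed -> 33,000
  expect_equal(sum(occ$listed_ckd), 11000)
  expect_equal(sum(occ$listed_dial), 33000)
  expect_equal(sum(occ$unlisted[, "CKD_UNLISTED"]), 14000)
  expect_equal(sum(occ$unlisted[, "DIALYSIS_UNLISTED"]), 42000)
  expect_equal(occupancy_total(occ), 100000)
})

test_that("expansion beyond the available unlisted pool is rejected", {
  split <- matrix(0, 3, 7, dimnames = list(age_strata(), health_states()))
  split[, "DIALYSIS_LISTED"] <- 0.3
  split[, "DIALYSIS_UNLISTED"] <- 1 / 30
  spec <- cohort_spec(1000, split, 12)
  expect_error(make_initial_occupancy(spec, 1.5), "insufficient unlisted")
  expect_error(make_initial_occupancy(spec, 0.9), ">= 1")
})

test_that("null dynamics leave the cohort unchanged", {
  spec <- toy_spec()
  occ <- make_initial_occupancy(spec, 1)
  step <- step_cycle(occ, generate_parameter_set(1, "null"))
  expect_equal(sum(step$events), 0)
  expect_equal(step$occupancy$unlisted, occ$unlisted)
  # listed mass merely ages by one month
  expect_equal(step$occupancy$listed_dial[, 2], occ$listed_dial[, 1])
})

test_that("certain death sweeps all living mass into the absorbing state", {
  spec <- toy_spec()
  occ <- make_initial_occupancy(spec, 1)
  ps <- toy_params(p_death_ckd = 1, p_death_dialysis = 1, p_death_listed = 1,
                   p_death_removed = 1, p_death_posttx = 1)
  step <- step_cycle(occ, ps)
  expect_equal(sum(step$occupancy$unlisted[, "DEAD"]), spec$total)
  expect_equal(occupancy_total(step$occupancy), spec$total)
})

test_that("a single listed transition gives exact expected counts", {
  # 100,000 listed, monthly DDT probability 0.01, no other exits
  spec <- toy_spec(total = 100000, ckd_listed = 0, dial_listed = 1)
  occ <- make_initial_occupancy(spec, 1)
  ps <- toy_params(p_ddt_listed = 0.01)
  step <- step_cycle(occ, ps)
  expect_equal(step$events[["ddt"]], 1000)
  expect_equal(sum(step$occupancy$listed_dial[, 2]), 99000)
  expect_equal(sum(step$occupancy$listed_dial[, 1]), 0)
  # transplanted mass lands in graft function (perioperative risk is 0 here)
  expect_equal(sum(step$occupancy$unlisted[, "GRAFT_FUNCTIONING"]), 1000)
})

test_that("perioperative deaths split transplanted mass and count as deaths", {
  spec <- toy_spec(total = 10000, ckd_listed = 0, dial_listed = 1)
  occ <- make_initial_occupancy(spec, 1)
  ps <- toy_params(p_ddt_listed = 0.1, p_periop_death = 0.02)
  step <- step_cycle(occ, ps)
  expect_equal(step$events[["ddt"]], 1000)
  expect_equal(step$events[["periop_deaths"]], 20)
  expect_equal(sum(step$occupancy$unlisted[, "GRAFT_FUNCTIONING"]), 980)
  expect_equal(sum(step$occupancy$unlisted[, "DEAD"]), 20)
})

test_that("graft failure routes back to unlisted dialysis", {
  split <- matrix(0, 3, 7, dimnames = list(age_strata(), health_states()))
  split[, "GRAFT_FUNCTIONING"] <- 1 / 3
  spec <- cohort_spec(9000, split, 12)
  occ <- make_initial_occupancy(spec, 1)
  ps <- toy_params(p_graft_failure = 0.1)
  step <- step_cycle(occ, ps)
  expect_equal(step$events[["graft_failures"]], 900)
  expect_equal(sum(step$occupancy$unlisted[, "DIALYSIS_UNLISTED"]), 900)
})

test_that("occupancy is conserved and deaths accumulate monotonically over 120 cycles", {
  spec <- default_cohort_spec()
  occ0 <- make_initial_occupancy(spec, 1)
  tr <- run_model(occ0, canonical_params(), horizon = 120)
  totals <- vapply(tr$occupancies, occupancy_total, numeric(1))
  expect_true(all(abs(totals - spec$total) <= 1e-9 * spec$total))
  dead <- vapply(tr$occupancies, function(o) sum(o$unlisted[, "DEAD"]),
                 numeric(1))
  expect_true(all(diff(dead) >= -1e-9))
  # listed transplants never exceed the listed pool at cycle start
  listed0 <- rowSums(tr$listed_occ)[seq_len(120)]
  expect_true(all(tr$events$ddt <= listed0 + 1e-9))
})

test_that("the expected-value engine is linear in cohort size", {
  spec1 <- default_cohort_spec()
  spec2 <- cohort_spec(2 * spec1$total, spec1$split, spec1$horizon)
  ps <- canonical_params()
  tr1 <- run_model(make_initial_occupancy(spec1, 1), ps, horizon = 24)
  tr2 <- run_model(make_initial_occupancy(spec2, 1), ps, horizon = 24)
  expect_equal(as.matrix(tr2$events), 2 * as.matrix(tr1$events),
               tolerance = 1e-12)
  expect_equal(tr2$listed_occ, 2 * tr1$listed_occ, tolerance = 1e-12)
})

test_that("runs are deterministic", {
  spec <- toy_spec()
  ps <- canonical_params()
  occ0 <- make_initial_occupancy(spec, 1)
  tr1 <- run_model(occ0, ps, horizon = 24)
  tr2 <- run_model(occ0, ps, horizon = 24)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$listed_occ, tr2$listed_occ)
})

test_that("annual counts sum cycles and validate the year index", {
  spec <- toy_spec(total = 120000, ckd_listed = 0, dial_listed = 1)
  ps <- toy_params(p_ddt_listed = 0.001)
  tr <- run_model(make_initial_occupancy(spec, 1), ps, horizon = 24)
  expect_equal(annual_counts(tr, 1)[["ddt"]], sum(tr$events$ddt[1:12]))
  expect_error(annual_counts(tr, 3), "out of range")
  expect_error(annual_counts(tr, 0), "out of range")
  tr0 <- run_model(make_initial_occupancy(spec, 1),
                   generate_parameter_set(1, "null"), horizon = 12)
  expect_equal(sum(annual_counts(tr0, 1)), 0)
})

test_that("horizon 0 returns only the initial occupancy", {
  spec <- toy_spec()
  occ0 <- make_initial_occupancy(spec, 1)
  tr <- run_model(occ0, canonical_params(), horizon = 0)
  expect_length(tr$occupancies, 1)
  expect_equal(nrow(tr$events), 0)
})

test_that("trace export is tidy and complete", {
  spec <- toy_spec(horizon = 6)
  tr <- run_model(make_initial_occupancy(spec, 1), canonical_params(),
                  horizon = 6)
  dfs <- trace_to_df(tr)
  expect_named(dfs, c("occupancy", "events"))
  expect_setequal(unique(dfs$occupancy$state), health_states())
  expect_equal(nrow(dfs$events), 6)
  # totals are preserved in the export
  tot <- sum(dfs$occupancy$count[dfs$occupancy$cycle == 3])
  expect_equal(tot, spec$total, tolerance = 1e-9)
})
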