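test_that("risk-set tables enforce the bookkeeping identity", {
  tbl <- risk_set_table(n_risk = c(1000, 985), events = c(10, 0),
                        censored = c(5, 985))
  expect_equal(tbl$n_risk[2], 985)
  expect_error(risk_set_table(c(1000, 900), c(10, 0), c(5, 895)),
               "bookkeeping")
})

test_that("the product-limit estimator matches a hand computation", {
  # n = (10, 7), d = (2, 1), c = (1, 0): S = (0.8, 0.8 * 6/7)
  tbl <- risk_set_table(n_risk = c(10, 7), events = c(2, 1),
                        censored = c(1, 0))
  cv <- km_product_limit(tbl)
  expect_equal(cv$surv, c(1, 0.8, 0.685714285714286), tolerance = 1e-12)
  expect_equal(cv$month, c(0, 1, 2))
})

test_that("without censoring the KM curve is the surviving fraction", {
  n0 <- 1000
  d <- c(100, 250, 50, 300)
  n <- n0 - cumsum(c(0, d[-4]))
  tbl <- risk_set_table(n, d, rep(0, 4))
  cv <- km_product_limit(tbl)
  expect_equal(cv$surv[-1], (n - d) / n0, tolerance = 1e-12)
})

test_that("degenerate KM inputs behave as specified", {
  tbl <- risk_set_table(c(10, 10, 10), c(0, 0, 0), c(0, 0, 0))
  expect_true(all(km_product_limit(tbl)$surv == 1))
  # a month in which everyone at risk is transplanted drives S to 0
  full <- km_product_limit(risk_set_table(5, 5, 0))
  expect_equal(full$surv, c(1, 0))
})

test_that("events exceeding the risk set are a data error", {
  tbl <- data.frame(month = 1, n_risk = 5, events = 6, censored = 0)
  class(tbl) <- c("risk_set_table", "data.frame")
  expect_error(km_product_limit(tbl), "exceed")
})

test_that("percentiles read off the first crossing of the survival curve", {
  cv <- data.frame(month = 0:3, surv = c(1, 0.8, 0.6857, 0.3429))
  class(cv) <- c("km_curve", "data.frame")
  expect_equal(km_percentile(cv, 0.5), 3)
  expect_equal(km_percentile(cv, 0.25), 2)
  expect_error(km_percentile(cv, 0), "between 0 and 1")
  expect_error(km_percentile(cv, 1.5), "between 0 and 1")
  flat <- data.frame(month = 0:5, surv = rep(1, 6))
  class(flat) <- c("km_curve", "data.frame")
  expect_true(is.na(km_percentile(flat, 0.5)))
  sm <- wait_time_summary(cv)
  expect_true(sm$q25 <= sm$median)
})

test_that("a single entry cohort reproduces the two-exit closed form", {
  # time-homogeneous transplant hazard p with proportional censoring:
  # KM removes the censoring and S_t = (1 - p_tx)^t exactly
  spec <- toy_spec(total = 10000, ckd_listed = 0, dial_listed = 1,
                   horizon = 24)
  ps <- toy_params(p_ddt_listed = 0.06, p_removal = 0.02,
                   p_death_listed = 0.01, p_death_removed = 0.01)
  tr <- run_model(make_initial_occupancy(spec, 1), ps, horizon = 24)
  cv <- km_product_limit(risk_set_from_trace(tr))
  # the final month is pure administrative censoring (factor 1); every
  # earlier month carries the exact transplant hazard
  idx <- cv$month <= 24
  expect_equal(cv$surv[idx], (1 - 0.06)^(cv$month[idx]), tolerance = 1e-9)
})

test_that("pooled risk sets aggregate entry cohorts consistently", {
  spec <- default_cohort_spec()
  tr <- run_model(make_initial_occupancy(spec, 1), canonical_params(),
                  horizon = 60)
  rs <- risk_set_from_trace(tr)
  # identity n_{t+1} = n_t - d_t - c_t at expected-count precision
  k <- nrow(rs)
  resid <- rs$n_risk[-1] - (rs$n_risk[-k] - rs$events[-k] - rs$censored[-k])
  expect_true(all(abs(resid) <= 1e-9 * pmax(rs$n_risk[-k], 1)))
  # pooled at-risk mass at duration t sums every cycle's occupancy there
  n_direct <- colSums(tr$listed_occ)
  expect_equal(rs$n_risk, n_direct[seq_len(k)], tolerance = 1e-12)
  expect_true(all(rs$n_risk >= 0))
})

test_that("curves from a trace with no listings are empty", {
  split <- matrix(0, 3, 7, dimnames = list(age_strata(), health_states()))
  split[, "DIALYSIS_UNLISTED"] <- 1 / 3
  spec <- cohort_spec(1000, split, 12)
  tr <- run_model(make_initial_occupancy(spec, 1),
                  generate_parameter_set(1, "null"), horizon = 12)
  rs <- risk_set_from_trace(tr)
  expect_equal(nrow(rs), 0)
})

test_that("the product-limit estimator agrees with survival::survfit", {
  skip_if_not_installed("survival")
  ms <- microsimulate(canonical_params(), default_cohort_spec(),
                      n = 4000, seed = 99, horizon = 60)
  sp <- ms$records[!is.na(ms$records$listing_cycle), ]
  time <- sp$event_cycle - sp$listing_cycle
  status <- as.integer(sp$event == "transplant")
  keep <- time > 0
  fit <- survival::survfit(survival::Surv(time[keep], status[keep]) ~ 1)
  # rebuild the same data as a month-by-month risk-set table
  months <- seq_len(max(time[keep]))
  d <- vapply(months, function(t) sum(time[keep] == t & status[keep] == 1),
              numeric(1))
  cns <- vapply(months, function(t) sum(time[keep] == t & status[keep] == 0),
                numeric(1))
  n <- sum(keep) - cumsum(c(0, (d + cns)[-length(months)]))
  cv <- km_product_limit(risk_set_table(n, d, cns))
  ours <- cv$surv[match(fit$time, cv$month)]
  expect_equal(ours, fit$surv, tolerance = 1e-9)
})
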