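#' Pooled risk-set table over time since listing
#'
#' Pools every listing entry cohort in the trace (including patients listed
#' at model start, who enter at duration 0) onto a common
#' months-since-listing axis. For duration month `t` (the interval from
#' `t-1` to `t` months after listing):
#' * `n_risk` is the expected mass observed at risk in that month, summed
#'   over all calendar cycles;
#' * `events` are transplants (deceased-donor plus any on-list living-donor;
#'   perioperative deaths count as transplants, not censorings);
#' * `censored` are on-list deaths and removals, plus mass still waiting
#'   when the simulation horizon ends (administrative censoring).
#'
#' The bookkeeping identity `n_{t+1} = n_t - d_t - c_t` holds exactly.
#'
#' @param trace A `cohort_trace` (duration-resolved, as built by
#'   [run_model()]).
#' @return An object of class `risk_set_table`: data frame with columns
#'   `month`, `n_risk`, `events`, `censored`.
#' @export
risk_set_from_trace <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (is.null(trace$listed_occ) || is.null(trace$tx_by_dur)) {
    stop("trace lacks listing-duration resolution", call. = FALSE)
  }
  H <- trace$horizon
  nd <- ncol(trace$listed_occ)
  # at risk in duration month t (col t): every cycle's mass at duration t-1,
  # including the final cycle's, which is censored within its month
  n_t <- colSums(trace$listed_occ)
  d_t <- colSums(trace$tx_by_dur)
  c_t <- colSums(trace$cens_by_dur) + trace$listed_occ[H + 1, ]
  keep <- which(n_t > 1e-12)
  if (!length(keep)) {
    return(structure(data.frame(month = integer(0), n_risk = numeric(0),
                                events = numeric(0), censored = numeric(0)),
                     class = c("risk_set_table", "data.frame")))
  }
  last <- max(keep)
  out <- data.frame(month = seq_len(last), n_risk = n_t[1:last],
                    events = d_t[1:last], censored = c_t[1:last])
  class(out) <- c("risk_set_table", "data.frame")
  out
}

#' Risk-set table from explicit vectors
#'
#' @param n_risk,events,censored Equal-length non-negative vectors satisfying
#'   `n_risk[t+1] == n_risk[t] - events[t] - censored[t]`.
#' @return A `risk_set_table`.
#' @export
risk_set_table <- function(n_risk, events, censored) {
  stopifnot(length(n_risk) == length(events),
            length(n_risk) == length(censored),
            all(n_risk >= 0), all(events >= 0), all(censored >= 0))
  k <- length(n_risk)
  if (k > 1) {
    resid <- n_risk[-1] - (n_risk[-k] - events[-k] - censored[-k])
    if (any(abs(resid) > 1e-9 * pmax(n_risk[-k], 1))) {
      stop("risk-set bookkeeping identity violated", call. = FALSE)
    }
  }
  out <- data.frame(month = seq_len(k), n_risk = n_risk, events = events,
                    censored = censored)
  class(out) <- c("risk_set_table", "data.frame")
  out
}

#' Kaplan-Meier product-limit curve
#'
#' `S_t = prod_{u <= t} (1 - d_u / n_u)`, the probability of still waiting
#' for a transplant `t` months after listing; factors with an empty risk set
#' are treated as 1. Expected (fractional) counts are used directly, as the
#' cohort engine is an expected-value model.
#'
#' @param table A `risk_set_table`.
#' @return An object of class `km_curve`: data frame with columns `month`
#'   (0-based) and `surv`, starting at `S_0 = 1`.
#' @export
km_product_limit <- function(table) {
  stopifnot(inherits(table, "risk_set_table"))
  if (any(table$events > table$n_risk + 1e-9)) {
    stop("events exceed the at-risk count", call. = FALSE)
  }
  factors <- ifelse(table$n_risk > 0, 1 - table$events / table$n_risk, 1)
  surv <- cumprod(factors)
  out <- data.frame(month = c(0L, table$month), surv = c(1, surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Wait-time percentile from a Kaplan-Meier curve
#'
#' The q-th wait-time percentile is the smallest duration at which the
#' waiting curve drops to `1 - q` or below. When the curve never reaches
#' that level within the horizon the percentile is undefined and `NA` is
#' returned -- the situation in which real-world medians are not calculable
#' because fewer than half of listed patients have received a transplant.
#'
#' @param curve A `km_curve`.
#' @param q Fraction in (0, 1); `q = 0.5` gives the median wait time.
#' @return Duration in months, or `NA_real_` when undefined.
#' @export
km_percentile <- function(curve, q) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    stop("`q` must be a single fraction strictly between 0 and 1",
         call. = FALSE)
  }
  hit <- which(curve$surv <= 1 - q + 1e-12)
  if (!length(hit)) return(NA_real_)
  as.numeric(curve$month[hit[1]])
}

#' Median and interquartile range of wait time
#'
#' @param curve A `km_curve`.
#' @return Named list `median`, `q25`, `q75` (months; `NA` when the curve
#'   never reaches the corresponding level).
#' @export
wait_time_summary <- function(curve) {
  list(median = km_percentile(curve, 0.5),
       q25 = km_percentile(curve, 0.25),
       q75 = km_percentile(curve, 0.75))
}

#' Export a Kaplan-Meier curve as a plain data frame
#'
#' @param curve A `km_curve`.
#' @param scenario Scenario label for the `scenario` column.
#' @return Data frame with columns `scenario`, `month`, `surv`.
#' @export
km_curve_df <- function(curve, scenario = "status_quo") {
  data.frame(scenario = scenario, month = curve$month, surv = curve$surv)
}
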