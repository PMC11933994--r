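#' Convert an annual event probability to a monthly one
#'
#' Uses the constant-hazard relation `1 - (1 - p)^(1/12)`: twelve independent
#' monthly chances compose to the annual probability.
#'
#' @param p_annual Numeric vector of probabilities in \[0, 1\].
#' @return Monthly probabilities, same length as `p_annual`.
#' @examples
#' annual_to_monthly(0.12)            # 0.010596...
#' monthly_to_annual(annual_to_monthly(0.3))  # 0.3
#' @export
annual_to_monthly <- function(p_annual) {
  if (!is.numeric(p_annual) || anyNA(p_annual) ||
      any(p_annual < 0 | p_annual > 1)) {
    stop("`p_annual` must be numeric in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / 12)
}

#' @rdname annual_to_monthly
#' @param p_monthly Numeric vector of monthly probabilities in \[0, 1\].
#' @export
monthly_to_annual <- function(p_monthly) {
  if (!is.numeric(p_monthly) || anyNA(p_monthly) ||
      any(p_monthly < 0 | p_monthly > 1)) {
    stop("`p_monthly` must be numeric in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_monthly)^12
}

#' Construct a set of monthly transition probabilities
#'
#' The model's parameter vector: one monthly probability per (age stratum,
#' transition parameter). All probabilities are *monthly* except
#' `p_periop_death`, a one-time probability applied at the moment of
#' transplant.
#'
#' @param values Numeric matrix, 3 rows (age strata) by 14 columns (the
#'   parameters listed in `PARAM_NAMES`); dimnames optional, values are
#'   matched by name when present.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `transition_set`.
#' @export
transition_set <- function(values, validate = TRUE) {
  values <- as.matrix(values)
  if (!is.null(colnames(values))) {
    missing <- setdiff(PARAM_NAMES, colnames(values))
    if (length(missing)) {
      stop("missing parameter column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    values <- values[, PARAM_NAMES, drop = FALSE]
  } else {
    if (ncol(values) != length(PARAM_NAMES)) {
      stop("`values` must have ", length(PARAM_NAMES), " columns", call. = FALSE)
    }
    colnames(values) <- PARAM_NAMES
  }
  if (nrow(values) != length(age_strata())) {
    stop("`values` must have one row per age stratum", call. = FALSE)
  }
  rownames(values) <- age_strata()
  storage.mode(values) <- "double"
  x <- structure(list(values = values), class = "transition_set")
  if (validate) validate_transition_set(x) else x
}

#' Competing-exit probability sums by origin state
#'
#' @param x A `transition_set`.
#' @return Matrix (stratum by origin state) of the summed monthly exit
#'   probabilities leaving each origin.
#' @export
competing_exit_sums <- function(x) {
  stopifnot(inherits(x, "transition_set"))
  origins <- unique(TRANSITION_GRAPH$origin)
  out <- sapply(origins, function(origin) {
    pars <- TRANSITION_GRAPH$parameter[TRANSITION_GRAPH$origin == origin]
    rowSums(x$values[, pars, drop = FALSE])
  })
  rownames(out) <- age_strata()
  out
}

#' Validate a transition set
#'
#' Checks that every probability lies in \[0, 1\], that the competing exits
#' from each origin state sum to at most 1 in every stratum, and that
#' post-removal mortality is at least dialysis mortality (removal reflects
#' deteriorating health).
#'
#' @param x A `transition_set`.
#' @return `x`, invisibly unchanged, or an error naming the offending
#'   stratum and field.
#' @export
validate_transition_set <- function(x) {
  stopifnot(inherits(x, "transition_set"))
  v <- x$values
  if (anyNA(v) || !is.numeric(v)) {
    stop("transition probabilities must be numeric and non-missing",
         call. = FALSE)
  }
  bad <- which(v < 0 | v > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("probability out of [0, 1]: stratum %s, %s = %g",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]],
                 v[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  sums <- competing_exit_sums(x)
  over <- which(sums > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(over)) {
    stop(sprintf(
      "competing exit probabilities exceed 1: stratum %s, origin %s (sum %.6f)",
      rownames(sums)[over[1, 1]], colnames(sums)[over[1, 2]],
      sums[over[1, , drop = FALSE]]), call. = FALSE)
  }
  worse <- v[, "p_death_removed"] < v[, "p_death_dialysis"] - 1e-12
  if (any(worse)) {
    stop(sprintf(
      "p_death_removed < p_death_dialysis in stratum %s",
      age_strata()[which(worse)[1]]), call. = FALSE)
  }
  x
}

#' @export
print.transition_set <- function(x, ...) {
  cat("Monthly transition probabilities (3 age strata x",
      length(PARAM_NAMES), "parameters)\n")
  print(round(x$values, 6))
  invisible(x)
}

#' Read or write a transition set as a long-format CSV
#'
#' The on-disk dialect is one record per (stratum, parameter):
#' `stratum,parameter,value`, with all probabilities stored as monthly
#' values. `save_parameters()` followed by `load_parameters()` is the
#' identity.
#'
#' @param path File path.
#' @return `load_parameters()` returns a validated `transition_set`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "parameter", "value")
  if (!all(need %in% names(df))) {
    stop("parameter file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$value)) {
    stop("non-numeric `value` entries in ", path, call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(age_strata()),
                ncol = length(PARAM_NAMES),
                dimnames = list(age_strata(), PARAM_NAMES))
  bad_s <- setdiff(unique(df$stratum), age_strata())
  if (length(bad_s)) stop("unknown stratum: ", bad_s[1], call. = FALSE)
  bad_p <- setdiff(unique(df$parameter), PARAM_NAMES)
  if (length(bad_p)) stop("unknown parameter: ", bad_p[1], call. = FALSE)
  mat[cbind(df$stratum, df$parameter)] <- df$value
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value for stratum %s, parameter %s",
                 age_strata()[miss[1]], PARAM_NAMES[miss[2]]), call. = FALSE)
  }
  transition_set(mat)
}

#' @rdname load_parameters
#' @param x A `transition_set`.
#' @export
save_parameters <- function(x, path) {
  stopifnot(inherits(x, "transition_set"))
  df <- data.frame(
    stratum = rep(age_strata(), times = length(PARAM_NAMES)),
    parameter = rep(PARAM_NAMES, each = length(age_strata())),
    value = sprintf("%.17g", as.vector(x$values))  # lossless round trip
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify the simulated cohort
#'
#' @param total Cohort size in persons (default 662,190 adults with advanced
#'   CKD or dialysis-dependent kidney failure).
#' @param split Numeric matrix of initial occupancy fractions, 3 strata by
#'   7 states (columns named as [health_states()]); must sum to 1, with no
#'   initial mass in `REMOVED` or `DEAD`.
#' @param horizon Number of monthly cycles (default 120, a 10-year horizon).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(total, split, horizon = 120L) {
  stopifnot(is.numeric(total), length(total) == 1, total > 0,
            is.numeric(horizon), length(horizon) == 1, horizon >= 0)
  split <- as.matrix(split)
  if (is.null(colnames(split))) colnames(split) <- health_states()
  split <- split[, health_states(), drop = FALSE]
  if (nrow(split) != length(age_strata())) {
    stop("`split` must have one row per age stratum", call. = FALSE)
  }
  rownames(split) <- age_strata()
  if (any(split < 0)) stop("`split` fractions must be non-negative", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-9) {
    stop("`split` fractions must sum to 1", call. = FALSE)
  }
  if (any(split[, c("REMOVED", "DEAD")] > 0)) {
    stop("no initial occupancy allowed in REMOVED or DEAD", call. = FALSE)
  }
  structure(list(total = as.numeric(total), split = split,
                 horizon = as.integer(horizon)),
            class = "cohort_spec")
}

#' Annual registry event totals
#'
#' Container for the five annual flow totals the model is calibrated to:
#' deceased-donor transplants, living-donor transplants, waiting-list
#' additions, waiting-list removals, and deaths on the waiting list.
#'
#' @param ddt,ldt,additions,removals,waitlist_deaths Non-negative annual
#'   event counts.
#' @return An object of class `annual_targets` (a named list).
#' @export
annual_targets <- function(ddt, ldt, additions, removals, waitlist_deaths) {
  x <- list(ddt = ddt, ldt = ldt, additions = additions,
            removals = removals, waitlist_deaths = waitlist_deaths)
  if (any(vapply(x, function(v) !is.numeric(v) || length(v) != 1 || v < 0,
                 logical(1)))) {
    stop("all targets must be single non-negative numbers", call. = FALSE)
  }
  structure(lapply(x, as.numeric), class = "annual_targets")
}

#' 2022 US registry calibration targets
#'
#' The SRTR/USRDS 2022 annual totals used as calibration targets: 19,944
#' deceased-donor transplants, 5,660 living-donor transplants, 33,215
#' waiting-list additions, 6,040 removals, and 4,454 deaths on the waiting
#' list.
#'
#' @return An `annual_targets` object.
#' @export
registry_targets_2022 <- function() {
  annual_targets(ddt = 19944, ldt = 5660, additions = 33215,
                 removals = 6040, waitlist_deaths = 4454)
}
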