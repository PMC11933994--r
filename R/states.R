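#' Health states of the cohort model
#'
#' The model tracks transplant-eligible adults through seven mutually
#' exclusive health states. `DEAD` is absorbing. `REMOVED` patients (delisted
#' without transplant) cannot be relisted. Graft failure returns patients to
#' `DIALYSIS_UNLISTED`, from which they may be relisted with a fresh
#' wait-time clock.
#'
#' @return Character vector of the seven state labels.
#' @export
health_states <- function() {
  c("CKD_UNLISTED", "CKD_LISTED", "DIALYSIS_UNLISTED", "DIALYSIS_LISTED",
    "REMOVED", "GRAFT_FUNCTIONING", "DEAD")
}

#' Age strata of the cohort model
#'
#' Three closed age bands; patients outside 18-79 years do not enter the
#' model, and patients remain in their entry stratum for the whole horizon.
#'
#' @return Character vector of the three stratum labels.
#' @export
age_strata <- function() {
  c("18-44", "45-64", "65-79")
}

# States without a months-since-listing dimension.
UNLISTED_STATES <- c("CKD_UNLISTED", "DIALYSIS_UNLISTED", "REMOVED",
                     "GRAFT_FUNCTIONING", "DEAD")
LISTED_STATES <- c("CKD_LISTED", "DIALYSIS_LISTED")

PARAM_NAMES <- c(
  "p_progress", "p_list_ckd", "p_list_dialysis", "p_ldt_unlisted",
  "p_ldt_listed", "p_ddt_listed", "p_removal", "p_death_ckd",
  "p_death_dialysis", "p_death_listed", "p_death_removed",
  "p_death_posttx", "p_graft_failure", "p_periop_death"
)

# Single source of truth for the transition graph: (origin, event,
# destination). Both the expected-value cohort engine and the individual
# microsimulation read their monthly exit probabilities from
# build_stratum_transitions(), which follows this table; divergence between
# the two simulators in the state graph is therefore impossible.
# "TRANSPLANT" is a pseudo-destination resolved within the same cycle by the
# one-time perioperative-death split into DEAD vs GRAFT_FUNCTIONING.
TRANSITION_GRAPH <- data.frame(
  origin = c(
    "CKD_UNLISTED", "CKD_UNLISTED", "CKD_UNLISTED", "CKD_UNLISTED",
    "DIALYSIS_UNLISTED", "DIALYSIS_UNLISTED", "DIALYSIS_UNLISTED",
    "CKD_LISTED", "CKD_LISTED", "CKD_LISTED", "CKD_LISTED", "CKD_LISTED",
    "DIALYSIS_LISTED", "DIALYSIS_LISTED", "DIALYSIS_LISTED", "DIALYSIS_LISTED",
    "REMOVED",
    "GRAFT_FUNCTIONING", "GRAFT_FUNCTIONING"
  ),
  event = c(
    "progress", "listing", "ldt", "death",
    "listing", "ldt", "death",
    "ddt", "ldt", "removal", "death", "progress",
    "ddt", "ldt", "removal", "death",
    "death",
    "graft_failure", "death"
  ),
  dest = c(
    "DIALYSIS_UNLISTED", "CKD_LISTED", "TRANSPLANT", "DEAD",
    "DIALYSIS_LISTED", "TRANSPLANT", "DEAD",
    "TRANSPLANT", "TRANSPLANT", "REMOVED", "DEAD", "DIALYSIS_LISTED",
    "TRANSPLANT", "TRANSPLANT", "REMOVED", "DEAD",
    "DEAD",
    "DIALYSIS_UNLISTED", "DEAD"
  ),
  parameter = c(
    "p_progress", "p_list_ckd", "p_ldt_unlisted", "p_death_ckd",
    "p_list_dialysis", "p_ldt_unlisted", "p_death_dialysis",
    "p_ddt_listed", "p_ldt_listed", "p_removal", "p_death_listed", "p_progress",
    "p_ddt_listed", "p_ldt_listed", "p_removal", "p_death_listed",
    "p_death_removed",
    "p_graft_failure", "p_death_posttx"
  ),
  stringsAsFactors = FALSE
)

#' Monthly exit probabilities for one age stratum
#'
#' Assembles, for every origin state, the named vector of competing monthly
#' exit probabilities defined by the model's transition graph. This is the
#' single definition consumed by both the cohort engine ([step_cycle()]) and
#' the individual-level microsimulation ([microsimulate()]).
#'
#' @param params A `transition_set`.
#' @param stratum Stratum label or index (1-3).
#' @return Named list: per origin state, a named numeric vector of exit
#'   probabilities keyed by event, each carrying a `dest` attribute; plus
#'   element `p_periop_death`, the one-time death probability applied to all
#'   transplanted mass.
#' @export
build_stratum_transitions <- function(params, stratum) {
  stopifnot(inherits(params, "transition_set"))
  if (is.character(stratum)) stratum <- match(stratum, age_strata())
  v <- params$values[stratum, ]
  out <- list()
  for (origin in unique(TRANSITION_GRAPH$origin)) {
    rows <- TRANSITION_GRAPH[TRANSITION_GRAPH$origin == origin, ]
    p <- as.numeric(v[rows$parameter])
    names(p) <- rows$event
    attr(p, "dest") <- rows$dest
    out[[origin]] <- p
  }
  out$p_periop_death <- as.numeric(v["p_periop_death"])
  out
}
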