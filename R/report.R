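#' Run the full calibration-plus-scenario suite
#'
#' End-to-end driver: obtain a parameter set (from a file or a synthetic
#' preset), calibrate it to the annual registry targets, run the selected
#' expansion scenarios over the full horizon, and summarise each scenario by
#' its median wait time with interquartile range, the change in median wait
#' versus the status quo, and first-year totals of the five registry flows.
#' Deterministic given the configuration.
#'
#' @param config List with elements:
#'   * `preset`, `seed` -- synthetic parameter preset and seed, or
#'     `param_file` -- path to a parameter CSV (takes precedence);
#'   * `scenarios` -- `"all"` (default) or a character vector of scenario
#'     names from [build_scenario_grid()];
#'   * `targets` -- `annual_targets` (default [registry_targets_2022()]);
#'   * `horizon` -- cycles (default 120); must be >= 12;
#'   * `tolerance` -- calibration tolerance (default 0.005);
#'   * `outdir` -- optional directory for CSV outputs and the run log.
#' @return List of class `suite_report`: `summary` (one row per scenario),
#'   `km_curves` (long data frame), `calibration` (the
#'   `calibration_result`), `baseline_annual`, `config`.
#' @export
run_suite <- function(config = list()) {
  preset <- config$preset %||% "registry2022"
  seed <- config$seed %||% 2022L
  targets <- config$targets %||% registry_targets_2022()
  horizon <- as.integer(config$horizon %||% 120L)
  tolerance <- config$tolerance %||% 0.005
  if (horizon < 12) stop("`horizon` must be at least 12 cycles", call. = FALSE)

  params <- if (!is.null(config$param_file)) {
    load_parameters(config$param_file)
  } else {
    generate_parameter_set(seed, preset)
  }
  spec <- config$cohort_spec %||% default_cohort_spec()
  if (spec$horizon != horizon) {
    spec <- cohort_spec(spec$total, spec$split, horizon)
  }

  grid <- build_scenario_grid()
  sel <- config$scenarios %||% "all"
  if (!identical(sel, "all")) {
    missing <- setdiff(sel, names(grid))
    if (length(missing)) {
      stop("unknown scenario(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    grid <- grid[sel]
  }

  if (horizon %% 12 != 0) {
    stop("`horizon` must be a whole number of years", call. = FALSE)
  }
  cal <- calibrate_to_registry(targets, spec, params, tolerance = tolerance)
  baseline_annual <- cal$achieved

  rows <- list(); km_all <- list()
  sq_trace <- run_scenario(cal$params, spec, scenario_spec("status_quo"),
                           horizon = horizon)
  sq_curve <- km_product_limit(risk_set_from_trace(sq_trace))
  sq_median <- km_percentile(sq_curve, 0.5)

  for (nm in names(grid)) {
    scn <- grid[[nm]]
    trace <- if (nm == "status_quo") sq_trace else {
      run_scenario(cal$params, spec, scn, sq_trace, horizon)
    }
    curve <- km_product_limit(risk_set_from_trace(trace))
    sm <- wait_time_summary(curve)
    yr1 <- annual_counts(trace, 1)
    rows[[nm]] <- data.frame(
      scenario = nm,
      list_factor = scn$list_factor,
      ddt_multiplier = scn$ddt_multiplier,
      ldt_multiplier = scn$ldt_multiplier,
      mwt_months = sm$median, q25_months = sm$q25, q75_months = sm$q75,
      mwt_change_months = sm$median - sq_median,
      ddt = yr1[["ddt"]], ldt = yr1[["ldt"]],
      additions = yr1[["listings"]], removals = yr1[["removals"]],
      waitlist_deaths = yr1[["waitlist_deaths"]]
    )
    km_all[[nm]] <- km_curve_df(curve, nm)
  }
  report <- structure(list(
    summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    km_curves = do.call(rbind, c(km_all, list(make.row.names = FALSE))),
    calibration = cal,
    baseline_annual = baseline_annual,
    config = list(preset = preset, seed = seed, horizon = horizon,
                  tolerance = tolerance,
                  scenarios = names(grid))
  ), class = "suite_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$summary,
                     file.path(config$outdir, "scenario_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(report$km_curves,
                     file.path(config$outdir, "km_curves.csv"),
                     row.names = FALSE)
    save_parameters(cal$params,
                    file.path(config$outdir, "calibrated_parameters.csv"))
    write_calibration_report(cal, targets,
                             file.path(config$outdir, "calibration.txt"))
    log_lines <- c(
      sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("waitlistsim version %s",
              as.character(utils::packageVersion("waitlistsim"))),
      sprintf("preset=%s seed=%d horizon=%d tolerance=%g", preset, seed,
              horizon, tolerance),
      sprintf("scenarios: %s", paste(names(grid), collapse = ", "))
    )
    writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  }
  report
}

#' @export
print.suite_report <- function(x, ...) {
  cat("Scenario suite:", nrow(x$summary), "scenario(s), horizon",
      x$config$horizon, "cycles\n")
  df <- x$summary[, c("scenario", "mwt_months", "q25_months", "q75_months",
                      "mwt_change_months")]
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare first-year flows with reference registry totals
#'
#' @param report A `suite_report` (its status-quo row is used), or a named
#'   numeric vector/list containing `ddt`, `ldt`, `additions`, `removals`,
#'   `waitlist_deaths`.
#' @param reference An `annual_targets`.
#' @return Data frame (flow, achieved, reference, rel_dev) with attribute
#'   `max_rel_dev`; deviations are absolute relative differences.
#' @export
compare_to_reference <- function(report, reference) {
  stopifnot(inherits(reference, "annual_targets"))
  flows <- c("ddt", "ldt", "additions", "removals", "waitlist_deaths")
  if (inherits(report, "suite_report")) {
    row <- report$summary[report$summary$scenario == "status_quo", ]
    if (nrow(row) != 1) {
      stop("report does not contain a status-quo row", call. = FALSE)
    }
    achieved <- as.numeric(row[1, flows])
  } else {
    vals <- unlist(report)
    if (!all(flows %in% names(vals))) {
      stop("missing flow(s): ",
           paste(setdiff(flows, names(vals)), collapse = ", "), call. = FALSE)
    }
    achieved <- as.numeric(vals[flows])
  }
  ref <- vapply(flows, function(f) reference[[f]], numeric(1))
  rel <- ifelse(ref > 0, abs(achieved - ref) / ref, as.numeric(achieved > 0))
  out <- data.frame(flow = flows, achieved = achieved, reference = ref,
                    rel_dev = rel)
  attr(out, "max_rel_dev") <- max(rel)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
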