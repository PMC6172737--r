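#' Scenario configuration and trace exchange formats
#'
#' `scenario_from_yaml()` builds a [scenario_config()] from a YAML document.
#' Recognised top-level keys (all optional, falling back to the package
#' defaults): `regimen` (`PRN`/`TE`), `virtual_clinic`, `arrivals` (map of
#' condition to monthly mean or vector), `horizon_months`, `warmup_months`,
#' `report_months`, `replications`, `seed`, `start`, `virtual_fu_cost`,
#' `prevalent` (`n`, `eligible_frac`), `booking` (`dna_prob`, `cancel_prob`,
#' `rebook_within_days`).
#'
#' @param path YAML file path.
#' @return A [scenario_config()].
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  booking <- booking_system()
  if (!is.null(y$booking))
    booking$rules <- do.call(booking_rules, y$booking)
  args <- list(
    regimen = regimen_spec(y$regimen %||% "PRN"),
    virtual_clinic = isTRUE(y$virtual_clinic),
    booking = booking,
    tariffs = tariff_table(virtual_fu_cost = y$virtual_fu_cost %||% 37.5)
  )
  if (!is.null(y$arrivals)) args$arrivals <- y$arrivals
  if (!is.null(y$prevalent)) args$prevalent <- y$prevalent
  for (k in c("horizon_months", "warmup_months", "report_months",
              "replications", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$start)) args$start <- as.Date(y$start)
  do.call(scenario_config, args)
}

#' @rdname scenario_from_yaml
#' @param trace a `simulation_trace` from [run_scenario()].
#' @param out CSV path.
#' @param resources a [service_resources()] used to attach per-visit minutes.
#' @export
export_trace <- function(trace, out, resources = service_resources()) {
  stopifnot(inherits(trace, "simulation_trace"))
  v <- trace$visits
  mpv <- resources$minutes_per_visit
  served <- v$outcome == "attended"
  mins <- function(pool) ifelse(served, mpv[pool, v$visit_type], 0)
  df <- data.frame(
    patient_id = v$patient_id, visit_type = v$visit_type,
    due = format(trace$start + v$due - 1L),
    booked = ifelse(is.na(v$booked), "", format(trace$start + v$booked - 1L)),
    outcome = v$outcome, venue = v$venue,
    minutes_nurse = mins("nurse"),
    minutes_room = mins("consultation_room"),
    minutes_bed = mins("injection_bed"),
    stringsAsFactors = FALSE
  )
  write.csv(df, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @rdname scenario_from_yaml
#' @param report a [kpi_report()].
#' @export
write_kpi_json <- function(report, out) {
  stopifnot(inherits(report, "kpi_report"))
  jsonlite::write_json(
    list(scenario = report$scenario, replications = report$replications,
         horizon_months = report$horizon, monthly_averages = as.list(report$metrics)),
    out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
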