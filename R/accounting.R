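#' Monthly-average KPI reports
#'
#' A KPI report holds the monthly averages a service planner reads off a
#' scenario: attended new referrals, hospital follow-ups (injection, laser
#' and observation follow-up visits; virtual follow-ups are reported
#' separately), anti-VEGF injections, utilisation of each resource pool
#' (busy over scheduled minutes, a proportion in `[0, 1]`), and costing,
#' revenue and surplus in GBP, with surplus identically revenue minus
#' costing.
#'
#' @param metrics named numeric vector of monthly averages.
#' @param scenario label.
#' @param replications,horizon provenance metadata.
#' @return A `kpi_report`.
#' @export
kpi_report <- function(metrics, scenario = "", replications = 1L,
                       horizon = 12L) {
  stopifnot(is.numeric(metrics), !is.null(names(metrics)),
            all(nzchar(names(metrics))))
  util <- grep("^utilisation_", names(metrics))
  if (length(util) && any(metrics[util] < -1e-9 | metrics[util] > 1 + 1e-9))
    stop("utilisation outside [0, 1]")
  if (all(c("surplus", "revenue", "costing") %in% names(metrics)) &&
      abs(metrics["surplus"] - (metrics["revenue"] - metrics["costing"])) > 1)
    stop("surplus must equal revenue minus costing to within 1 GBP")
  structure(list(metrics = metrics, scenario = scenario,
                 replications = as.integer(replications),
                 horizon = as.integer(horizon)),
            class = "kpi_report")
}

#' @export
print.kpi_report <- function(x, ...) {
  cat(sprintf("<kpi_report: %s (monthly averages over %d month(s), %d rep(s))>\n",
              if (nzchar(x$scenario)) x$scenario else "unnamed",
              x$horizon, x$replications))
  print(round(x$metrics, 2))
  invisible(x)
}

#' Compute the monthly-average KPI report of a simulation trace
#'
#' Averages activity, utilisation and money over the trace's reporting
#' months (warm-up already excluded by the engine). Revenue and costing sum
#' the tariff table over attended visits; follow-ups count hospital
#' follow-up visit types, with virtual-clinic visits reported separately.
#' An empty trace yields an all-zero report.
#'
#' @param trace a `simulation_trace` from [run_scenario()].
#' @param tariffs a [tariff_table()].
#' @param scenario label for the report.
#' @return A [kpi_report()].
#' @export
kpi_from_trace <- function(trace, tariffs = tariff_table(), scenario = "") {
  stopifnot(inherits(trace, "simulation_trace"))
  months <- trace$report_months
  n_m <- length(months)
  att <- trace$visits[trace$visits$outcome %in% "attended" &
                        trace$visits$month %in% months, ]
  per_month <- function(sel) sum(sel) / n_m
  fu_types <- c("injection_fu", "laser_fu", "observation_fu")

  rm_df <- trace$resource_months[trace$resource_months$month %in% months, ]
  util <- vapply(split(rm_df, rm_df$pool), function(d) {
    u <- ifelse(d$available > 0, d$busy / d$available, 0)
    mean(u)
  }, numeric(1))
  names(util) <- paste0("utilisation_", names(util))

  revenue <- per_month(tariffs$revenue_per_visit[att$visit_type])
  costing <- per_month(tariffs$cost_per_visit[att$visit_type])
  metrics <- c(
    new_attendances = per_month(att$visit_type == "new_referral"),
    followups = per_month(att$visit_type %in% fu_types),
    virtual_followups = per_month(att$visit_type == "virtual_fu"),
    n_injections = per_month(att$visit_type == "injection"),
    n_lasers = per_month(att$visit_type == "laser"),
    overflow = sum(trace$visits$outcome == "overflow") / n_m,
    util[paste0("utilisation_",
                c("clinic_session", "nurse", "consultation_room",
                  "injection_bed", "virtual_capacity"))],
    costing = costing, revenue = revenue, surplus = revenue - costing
  )
  kpi_report(metrics, scenario = scenario, horizon = n_m)
}

# half-away-from-zero integer rounding, the convention of printed % changes
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percentage change between two KPI reports
#'
#' Per-KPI percentage change of an alternative scenario against a baseline,
#' rounded half-away-from-zero to integer percent. A zero baseline with a
#' non-zero alternative is reported as `NA` (undefined), never a division
#' error; identical reports give 0% everywhere.
#'
#' @param baseline,alternative [kpi_report()]s over the same KPI schema.
#' @return data.frame `kpi`, `baseline`, `alternative`, `pct_change`, class
#'   `comparison_table`.
#' @export
compare_scenarios <- function(baseline, alternative) {
  stopifnot(inherits(baseline, "kpi_report"), inherits(alternative, "kpi_report"))
  if (!identical(names(baseline$metrics), names(alternative$metrics)))
    stop("KPI schema mismatch between reports")
  b <- baseline$metrics
  a <- alternative$metrics
  pct <- ifelse(b == 0, ifelse(a == 0, 0, NA_real_),
                round_half_away(100 * (a - b) / b))
  structure(
    data.frame(kpi = names(b), baseline = unname(b), alternative = unname(a),
               pct_change = unname(pct), stringsAsFactors = FALSE),
    scenarios = c(baseline$scenario, alternative$scenario),
    class = c("comparison_table", "data.frame")
  )
}

#' Four-scenario service-redesign comparison table
#'
#' The canonical presentation of a redesign analysis: monthly averages of
#' the current service, virtual clinic only, treat-and-extend only, and
#' virtual clinic combined with treat-and-extend, plus the percentage change
#' of the combined redesign against the current service. Inputs are matched
#' by scenario name, not position.
#'
#' @param reports named list of four [kpi_report()]s with names
#'   `current_service`, `virtual_clinic`, `treat_and_extend`,
#'   `virtual_clinic_treat_and_extend`.
#' @return data.frame with one row per KPI and one column per scenario plus
#'   `pct_change`, class `scenario_table`.
#' @export
render_table4 <- function(reports) {
  wanted <- c("current_service", "virtual_clinic", "treat_and_extend",
              "virtual_clinic_treat_and_extend")
  missing <- setdiff(wanted, names(reports))
  if (length(missing))
    stop("missing scenario report(s): ", paste(missing, collapse = ", "))
  reports <- reports[wanted]
  schema <- names(reports[[1]]$metrics)
  for (r in reports)
    if (!identical(names(r$metrics), schema)) stop("KPI schema mismatch")
  m <- vapply(reports, function(r) r$metrics, numeric(length(schema)))
  cmp <- compare_scenarios(reports$current_service,
                           reports$virtual_clinic_treat_and_extend)
  out <- data.frame(kpi = schema, m, pct_change = cmp$pct_change,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' @rdname render_table4
#' @param table a `scenario_table`.
#' @param csv_path,txt_path output paths (either may be `NULL`).
#' @export
write_table4 <- function(table, csv_path = NULL, txt_path = NULL) {
  stopifnot(inherits(table, "scenario_table"))
  if (!is.null(csv_path))
    write.csv(as.data.frame(table), csv_path, row.names = FALSE)
  if (!is.null(txt_path))
    writeLines(format_scenario_table(table), txt_path)
  invisible(table)
}

format_scenario_table <- function(x) {
  num <- vapply(x[-1], function(col) format(round(col, 2), trim = TRUE),
                character(nrow(x)))
  body <- cbind(kpi = x$kpi, num)
  widths <- pmax(nchar(colnames(body)), apply(nchar(body), 2, max))
  fmt_row <- function(cells) paste(mapply(formatC, cells, width = widths),
                                   collapse = "  ")
  c(fmt_row(colnames(body)), apply(body, 1, fmt_row))
}

#' @export
print.scenario_table <- function(x, ...) {
  writeLines(format_scenario_table(x))
  invisible(x)
}

#' @export
print.comparison_table <- function(x, ...) {
  sc <- attr(x, "scenarios")
  cat(sprintf("<comparison: %s vs %s>\n",
              if (nzchar(sc[1])) sc[1] else "baseline",
              if (nzchar(sc[2])) sc[2] else "alternative"))
  print(as.data.frame(x))
  invisible(x)
}
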