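# Per-patient summaries used by every estimator: condition, first attended
# visit, treatment status, discharge year.
patient_table <- function(records) {
  stopifnot(is.data.frame(records))
  att <- records[records$status == "attended", ]
  if (nrow(att) == 0L)
    return(data.frame(patient_id = character(0), condition = character(0),
                      first = as.Date(character(0)), treated = logical(0),
                      discharged_year = integer(0), stringsAsFactors = FALSE))
  att <- att[order(att$patient_id, att$visit_date), ]
  first <- !duplicated(att$patient_id)
  treat <- tapply(att$visit_type %in% treatment_types(), att$patient_id, any)
  ids <- att$patient_id[first]
  data.frame(patient_id = ids,
             condition = att$condition[first],
             first = att$visit_date[first],
             treated = as.logical(treat[ids]),
             discharged_year = att$discharged_year[first],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count events per patient and care year
#'
#' Individual patients are tracked over the observation window: each
#' patient's clock starts at their first attended visit, care years are
#' consecutive 12-month blocks from that date, and years beyond the third
#' are pooled into year 3. Only attended visits of the requested category
#' are counted; patients with no attended visit at all are excluded (a
#' warning reports how many).
#'
#' @param records a `retinal_records` data.frame.
#' @param category one of `visit_types()`.
#' @return data.frame with columns `patient_id`, `condition`, `year`,
#'   `count` -- one row per patient-year with at least one event.
#' @export
count_events <- function(records, category) {
  stopifnot(length(category) == 1L)
  assert_visit_type(category)
  if (nrow(records) == 0L) stop("no records to count")
  n_dropped <- length(setdiff(records$patient_id,
                              records$patient_id[records$status == "attended"]))
  if (n_dropped > 0)
    warning(n_dropped, " patient(s) with no attended visits excluded")
  pt <- patient_table(records)
  ev <- records[records$status == "attended" & records$visit_type == category, ]
  if (nrow(ev) == 0L)
    return(data.frame(patient_id = character(0), condition = character(0),
                      year = integer(0), count = integer(0)))
  first <- stats::setNames(pt$first, pt$patient_id)
  yr <- care_year(first[ev$patient_id], ev$visit_date)
  agg <- stats::aggregate(list(count = rep(1L, nrow(ev))),
                          by = list(patient_id = ev$patient_id,
                                    condition = ev$condition, year = yr),
                          FUN = sum)
  agg[order(agg$patient_id, agg$year), c("patient_id", "condition", "year", "count")]
}

#' Estimate the case mix of a cohort
#'
#' @param records a `retinal_records` data.frame.
#' @return Named proportions over `conditions()`, summing to 1.
#' @export
estimate_mix <- function(records) {
  pt <- patient_table(records)
  if (nrow(pt) == 0L) stop("no attending patients")
  tab <- table(factor(pt$condition, levels = conditions()))
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, conditions())
}

#' Attended activity broken down by category and condition
#'
#' The attended-appointment analogue of a service activity table: one row
#' per activity category, one column per condition, with exact row/column
#' totals. Did-not-attend and cancelled rows are excluded, so the table is
#' invariant to their presence and to record order.
#'
#' @param records a `retinal_records` data.frame.
#' @return An integer matrix with a `Total` row and column, class
#'   `activity_table`.
#' @export
activity_table <- function(records) {
  att <- records[records$status == "attended", ]
  cats <- activity_categories()
  extra <- setdiff(unique(att$visit_type), cats)
  cats <- c(cats, sort(extra))
  m <- table(factor(att$visit_type, levels = cats),
             factor(att$condition, levels = conditions()))
  m <- matrix(as.integer(m), nrow = length(cats),
              dimnames = list(cats, conditions()))
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  storage.mode(m) <- "integer"
  structure(m, class = c("activity_table", class(m)))
}

#' @export
print.activity_table <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Estimate the discharge model
#'
#' Discharge probabilities per condition, treatment status and care year.
#' Two conventions are computed: `prob` is the per-year hazard
#' (discharges in year y divided by patients still at risk entering year y),
#' which is what a simulation consumes; `cohort_share` divides by the full
#' cohort size, the convention of a printed summary table. Year-3 entries
#' apply to all later years.
#'
#' @param records a `retinal_records` data.frame carrying `discharged_year`.
#' @return A `discharge_model`: list with `prob` and `cohort_share`
#'   (condition x status x year arrays), `counts`, `n_patients` and
#'   `total_discharges`.
#' @export
estimate_discharge <- function(records) {
  pt <- patient_table(records)
  if (nrow(pt) == 0L) stop("no attending patients")
  status <- ifelse(pt$treated, "treated", "observation")
  dims <- list(condition = conditions(), status = c("treated", "observation"),
               year = as.character(1:3))
  counts <- array(0L, dim = c(3L, 2L, 3L), dimnames = dims)
  n_cs <- array(0L, dim = c(3L, 2L), dimnames = dims[1:2])
  for (c in conditions()) for (s in dims$status) {
    sel <- pt$condition == c & status == s
    n_cs[c, s] <- sum(sel)
    for (y in 1:3)
      counts[c, s, y] <- sum(sel & !is.na(pt$discharged_year) &
                               pt$discharged_year == y)
  }
  prob <- array(0, dim = dim(counts), dimnames = dims)
  for (c in conditions()) for (s in dims$status) {
    at_risk <- n_cs[c, s]
    for (y in 1:3) {
      if (at_risk > 0) {
        prob[c, s, y] <- counts[c, s, y] / at_risk
      } else if (counts[c, s, y] > 0) {
        warning("discharges with zero at-risk denominator for ", c, "/", s)
      }
      at_risk <- at_risk - counts[c, s, y]
    }
  }
  structure(
    list(prob = prob, cohort_share = counts / max(nrow(pt), 1L),
         counts = counts, n_patients = nrow(pt),
         total_discharges = sum(counts)),
    class = "discharge_model"
  )
}

#' @export
print.discharge_model <- function(x, ...) {
  cat(sprintf("<discharge_model: %d of %d patients discharged (%.0f%%)>\n",
              x$total_discharges, x$n_patients,
              100 * x$total_discharges / max(x$n_patients, 1L)))
  invisible(x)
}

#' Select patients eligible for a nurse-led virtual clinic
#'
#' A patient is eligible at `as_of` when they attended at least once in the
#' preceding 24 months, had no attended treatment visit (injection or laser)
#' in the preceding 6 months, and were not discharged. Both lookback windows
#' are half-open: exclusive at the old end, inclusive at `as_of`.
#'
#' @param records a `retinal_records` data.frame.
#' @param as_of reference day; defaults to the end of the record window.
#' @return Character vector of eligible patient ids (sorted).
#' @export
select_virtual_clinic_eligible <- function(records, as_of = NULL) {
  if (is.null(as_of)) as_of <- attr(records, "as_of")
  if (is.null(as_of)) as_of <- max(records$visit_date)
  as_of <- as.Date(as_of)
  if (nrow(records) == 0L) return(character(0))
  lo24 <- months_before(as_of, 24L)
  lo6 <- months_before(as_of, 6L)
  att <- records[records$status == "attended" & records$visit_date <= as_of, ]
  recent <- unique(att$patient_id[att$visit_date > lo24])
  treated_recently <- unique(att$patient_id[
    att$visit_type %in% treatment_types() & att$visit_date > lo6])
  pt <- patient_table(records)
  discharged <- pt$patient_id[!is.na(pt$discharged_year)]
  sort(setdiff(recent, union(treated_recently, discharged)))
}

#' Calibrate all pathway parameters from patient-level records
#'
#' One-stop calibration: case mix, activity table, discharge model,
#' per-condition/category/year count distributions (log-normal where the
#' sample supports it, empirical otherwise) and the virtual-clinic eligible
#' set. The result is the simulator's input contract and can be written to
#' and restored from JSON.
#'
#' @param records a `retinal_records` data.frame.
#' @param as_of eligibility reference day (default: window end).
#' @param categories activity categories to fit count distributions for.
#' @return A `service_calibration` list.
#' @export
calibrate_service <- function(records, as_of = NULL,
                              categories = c("injection", "injection_fu",
                                             "observation_fu")) {
  if (is.null(as_of)) as_of <- attr(records, "as_of")
  if (is.null(as_of)) as_of <- max(records$visit_date)
  dists <- list()
  for (cat in categories) {
    cnt <- count_events(records, cat)
    for (c in conditions()) for (y in 1:3) {
      x <- cnt$count[cnt$condition == c & cnt$year == y]
      if (length(x) > 0)
        dists[[paste(c, cat, y, sep = ".")]] <- fit_count_distribution(x)
    }
  }
  structure(
    list(case_mix = estimate_mix(records),
         activity = activity_table(records),
         discharge = estimate_discharge(records),
         count_distributions = dists,
         eligible_ids = select_virtual_clinic_eligible(records, as_of),
         as_of = as.Date(as_of)),
    class = "service_calibration"
  )
}

#' @rdname calibrate_service
#' @param calibration a `service_calibration` object.
#' @param path JSON file path.
#' @export
write_calibration <- function(calibration, path) {
  x <- calibration
  out <- list(
    case_mix = as.list(x$case_mix),
    activity = as.data.frame(as.table(unclass(x$activity))),
    discharge_prob = as.data.frame(as.table(x$discharge$prob)),
    discharge_counts = as.data.frame(as.table(x$discharge$counts)),
    count_distributions = lapply(x$count_distributions, unclass),
    eligible_ids = x$eligible_ids,
    as_of = format(x$as_of)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
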