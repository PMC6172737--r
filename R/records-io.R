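#' Read and write patient-level visit records
#'
#' Records travel as plain CSV with header
#' `patient_id,condition,visit_date,visit_type,status,discharged_year` and
#' ISO-8601 dates. `discharged_year` (empty when the patient was never
#' discharged) is written so that a round trip reproduces the record set
#' field for field; files without that column are accepted on read.
#'
#' `read_records()` validates every row -- labels against the closed
#' vocabularies, parseable dates, per-patient non-decreasing date order --
#' and rejects a malformed file naming the first offending line (header =
#' line 1).
#'
#' @param records a `retinal_records` data.frame as from [generate_cohort()].
#' @param path file path.
#' @param window_start,window_months observation window metadata attached on
#'   read; defaults are inferred from the dates in the file.
#' @return `read_records()` returns a `retinal_records` data.frame.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- as.data.frame(records)[, c("patient_id", "condition", "visit_date",
                                   "visit_type", "status", "discharged_year")]
  df$visit_date <- format(df$visit_date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, window_start = NULL, window_months = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 na.strings = character(0))
  need <- c("patient_id", "condition", "visit_date", "visit_type", "status")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # header is line 1

  fail <- function(what, bad) {
    stop(sprintf("%s at line %d of %s", what, line[bad][1], path), call. = FALSE)
  }
  bad <- !(df$condition %in% conditions())
  if (any(bad)) fail(paste0("unknown condition '", df$condition[bad][1], "'"), bad)
  bad <- !(df$visit_type %in% visit_types())
  if (any(bad)) fail(paste0("unknown visit type '", df$visit_type[bad][1], "'"), bad)
  bad <- !(df$status %in% visit_statuses())
  if (any(bad)) fail(paste0("unknown status '", df$status[bad][1], "'"), bad)
  dates <- as.Date(df$visit_date, format = "%Y-%m-%d")
  bad <- is.na(dates)
  if (any(bad)) fail(paste0("unparseable date '", df$visit_date[bad][1], "'"), bad)

  dis <- if ("discharged_year" %in% names(df)) {
    d <- suppressWarnings(as.integer(df$discharged_year))
    bad <- !is.na(d) & !(d %in% 1:3) | (is.na(d) & nzchar(df$discharged_year))
    if (any(bad)) fail("discharged_year outside 1-3", bad)
    d
  } else rep(NA_integer_, nrow(df))

  # per-patient dates must be non-decreasing in file order
  ord <- order(df$patient_id, line)
  same <- duplicated(df$patient_id[ord])
  drop_date <- same & diff(c(as.integer(dates)[ord][1] - 1L,
                             as.integer(dates)[ord])) < 0
  if (any(drop_date)) fail("visit dates out of order", ord[drop_date])

  out <- data.frame(patient_id = df$patient_id, condition = df$condition,
                    visit_date = dates, visit_type = df$visit_type,
                    status = df$status, discharged_year = dis,
                    stringsAsFactors = FALSE)
  if (is.null(window_start))
    window_start <- if (nrow(out)) as.Date(cut(min(out$visit_date), "month"))
                    else as.Date("2013-04-01")
  if (is.null(window_months))
    window_months <- if (nrow(out)) max(month_index(out$visit_date, window_start))
                     else 36L
  new_records(out, window_start, window_months)
}

#' @export
print.retinal_records <- function(x, ...) {
  cat(sprintf("<retinal_records: %d visits, %d patients, window %s + %d months>\n",
              nrow(x), length(unique(x$patient_id)),
              format(attr(x, "window_start")), attr(x, "window_months")))
  if (nrow(x)) print(head(as.data.frame(x), 5L))
  invisible(x)
}
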