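#' Appointment slot calendar and booking rules
#'
#' The booking system is an earliest-free-slot calendar: each clinic day
#' offers a fixed number of bookable slots (a weekly template, typically
#' zero at weekends). A due visit is booked into the earliest free slot on
#' or after its due date. A cancelled or did-not-attend appointment releases
#' its slot and triggers exactly one rebooking attempt into the earliest
#' free slot within `rebook_within_days` after the failed date; if the
#' initial booking finds no free slot before the calendar ends the visit is
#' recorded as overflow (unmet demand), never dropped.
#'
#' No attendance-failure rates are published for the reference service; the
#' defaults (5% DNA, 3% cancellation, 14-day rebooking window) are
#' assumptions.
#'
#' @param n_days calendar length in days (day 1 = `start`).
#' @param start first calendar day (a `Date`); fixes the weekday pattern.
#' @param slots_per_weekday integer vector of 7 slot counts, Monday first.
#' @return `slot_calendar()` returns an integer vector of free slots per
#'   day with attribute `start`.
#' @export
slot_calendar <- function(n_days, start = as.Date("2016-04-01"),
                          slots_per_weekday = c(32L, 32L, 32L, 32L, 32L, 0L, 0L)) {
  stopifnot(n_days >= 1, length(slots_per_weekday) == 7L,
            all(slots_per_weekday >= 0))
  wday <- as.POSIXlt(start + seq_len(n_days) - 1L)$wday  # 0 = Sunday
  idx <- ifelse(wday == 0L, 7L, wday)                    # Monday first
  structure(as.integer(slots_per_weekday[idx]), start = as.Date(start))
}

#' @rdname slot_calendar
#' @param dna_prob,cancel_prob per-appointment failure probabilities.
#' @param rebook_within_days rebooking window after a failed appointment.
#' @export
booking_rules <- function(dna_prob = 0.05, cancel_prob = 0.03,
                          rebook_within_days = 14L) {
  stopifnot(dna_prob >= 0, dna_prob < 1, cancel_prob >= 0, cancel_prob < 1,
            rebook_within_days >= 1)
  list(dna_prob = dna_prob, cancel_prob = cancel_prob,
       rebook_within_days = as.integer(rebook_within_days))
}

#' Book a sequence of due visits against a slot calendar
#'
#' Visits are processed in the order given (the engine orders events by due
#' date, patient id and visit-type rank for determinism). Outcomes per
#' visit: `attended` (possibly after one rebooking), `dna` / `cancelled`
#' (the single rebooking attempt found no slot), or `overflow` (no slot at
#' all before the calendar end).
#'
#' @param due integer due days (1-based calendar day indices).
#' @param calendar a [slot_calendar()]; modified copy returned in the result.
#' @param u_cancel,u_dna per-visit uniforms compared against the rule
#'   probabilities (supply `rep(1, n)` for deterministic attendance).
#' @param rules a [booking_rules()].
#' @return list with `visits` (data.frame `due`, `booked`, `service_day`,
#'   `outcome`, `rebooked`) and `calendar` (remaining free slots).
#' @export
book_visits <- function(due, calendar, u_cancel = NULL, u_dna = NULL,
                        rules = booking_rules()) {
  n <- length(due)
  n_days <- length(calendar)
  stopifnot(all(due >= 1), all(due <= n_days))
  if (is.null(u_cancel)) u_cancel <- runif(n)
  if (is.null(u_dna)) u_dna <- runif(n)
  free <- as.integer(calendar)
  booked <- service <- rep(NA_integer_, n)
  outcome <- character(n)
  rebooked <- logical(n)

  first_free <- function(from, to) {
    d <- from
    while (d <= to) {
      if (free[d] > 0L) return(d)
      d <- d + 1L
    }
    NA_integer_
  }

  for (i in seq_len(n)) {
    b <- first_free(due[i], n_days)
    if (is.na(b)) {
      outcome[i] <- "overflow"
      next
    }
    free[b] <- free[b] - 1L
    booked[i] <- b
    failed <- if (u_cancel[i] < rules$cancel_prob) "cancelled"
              else if (u_dna[i] < rules$dna_prob) "dna"
              else NA_character_
    if (is.na(failed)) {
      service[i] <- b
      outcome[i] <- "attended"
      next
    }
    free[b] <- free[b] + 1L  # released slot
    rb <- if (b < n_days)
      first_free(b + 1L, min(b + rules$rebook_within_days, n_days))
    else NA_integer_
    if (is.na(rb)) {
      outcome[i] <- failed
    } else {
      free[rb] <- free[rb] - 1L
      service[i] <- rb
      outcome[i] <- "attended"
      rebooked[i] <- TRUE
    }
  }
  list(
    visits = data.frame(due = as.integer(due), booked = booked,
                        service_day = service, outcome = outcome,
                        rebooked = rebooked, stringsAsFactors = FALSE),
    calendar = structure(free, start = attr(calendar, "start"))
  )
}
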