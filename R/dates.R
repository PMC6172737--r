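# Calendar helpers. Patient-year and eligibility arithmetic is defined in
# calendar months; these helpers keep that arithmetic exact (day-of-month
# clamped) without adding a dependency.

# first day of month index m (1-based) counted from the month containing `start`
month_start <- function(m, start) {
  first <- as.Date(cut(as.Date(start), "month"))
  if (m == 1L) return(first)
  seq(first, by = "month", length.out = m)[m]
}

month_end <- function(m, start) month_start(m + 1L, start) - 1L

# 1-based month index of `date` relative to `start` (vectorised over `date`)
month_index <- function(date, start) {
  d <- as.POSIXlt(date)
  s <- as.POSIXlt(as.Date(start))
  12L * (d$year - s$year) + (d$mon - s$mon) + 1L
}

# `date` minus n calendar months, day-of-month clamped to the target month
months_before <- function(date, n) {
  lt <- as.POSIXlt(as.Date(date))
  tot <- (lt$year + 1900L) * 12L + lt$mon - n  # months since year 0
  y <- tot %/% 12L
  m <- tot %% 12L + 1L                         # 1..12
  nxt <- as.Date(sprintf("%04d-%02d-01", y + (m == 12L), m %% 12L + 1L))
  last <- as.integer(format(nxt - 1L, "%d"))
  as.Date(sprintf("%04d-%02d-%02d", y, m, pmin(lt$mday, last)))
}

# whole calendar months elapsed from `from` to `to` (day-of-month aware);
# 0 when `to` is within the first month. Vectorised over `to`.
months_between <- function(from, to) {
  f <- as.POSIXlt(as.Date(from))
  t <- as.POSIXlt(as.Date(to))
  m <- 12L * (t$year - f$year) + (t$mon - f$mon)
  m - as.integer(t$mday < f$mday)
}

# care year (1,2,3,...) of a visit relative to the patient's first attendance
care_year <- function(first, date, pool_at = 3L) {
  y <- months_between(first, date) %/% 12L + 1L
  pmin(y, pool_at)
}
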