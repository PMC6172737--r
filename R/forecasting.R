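#' Monthly attendance series
#'
#' A light container for a monthly count series of one arrival stream
#' (`new` referrals or `followup` attendances) of one condition.
#'
#' @param values non-negative monthly counts, no gaps.
#' @param start_month first month (`Date`, day ignored).
#' @param condition one of `conditions()`.
#' @param stream `"new"` or `"followup"`.
#' @export
monthly_series <- function(values, start_month = as.Date("2013-04-01"),
                           condition = "AMD", stream = c("new", "followup")) {
  stream <- match.arg(stream)
  assert_condition(condition)
  stopifnot(is.numeric(values), all(values >= 0), all(is.finite(values)))
  structure(list(values = as.numeric(values),
                 start_month = as.Date(cut(as.Date(start_month), "month")),
                 condition = condition, stream = stream),
            class = "monthly_series")
}

#' Forecast monthly arrivals with population-growth adjustment
#'
#' Fits an additive level + linear trend + calendar-month seasonality model
#' by ordinary least squares to at least 24 months of history, extrapolates
#' `horizon` months ahead, then scales month `m` of the forecast by
#' `(1 + growth_rate)^(m/12)` and floors at zero. The method is a fixed,
#' transparent decomposition: on a noise-free level/trend/seasonal series it
#' reproduces the generating process exactly, it is equivariant to scaling,
#' and a zero growth rate leaves the extrapolation untouched.
#'
#' @param history a [monthly_series()] (or bare numeric vector) of at least
#'   24 months.
#' @param horizon months ahead (default 12).
#' @param growth_rate annual population growth as a proportion (e.g. `0.02`).
#' @return A `monthly_forecast` list with `point` (length `horizon`),
#'   `growth_rate` and the history metadata.
#' @examples
#' f <- forecast_arrivals(monthly_series(rep(119, 36)), growth_rate = 0.02)
#' round(f$point[12], 2)  # 119 * 1.02
#' @export
forecast_arrivals <- function(history, horizon = 12L, growth_rate = 0) {
  hs <- if (inherits(history, "monthly_series")) history
        else monthly_series(history)
  y <- hs$values
  n <- length(y)
  if (n < 24L)
    stop("need at least 24 months of history; use a seasonal-naive fallback ",
         "for shorter series")
  stopifnot(horizon >= 1L)
  t <- seq_len(n)
  mon <- factor((month_index(hs$start_month, hs$start_month) + t - 2L) %% 12L)
  fit <- lm(y ~ t + mon)
  t_new <- n + seq_len(horizon)
  mon_new <- factor((t_new - 1L) %% 12L, levels = levels(mon))
  point <- as.numeric(predict(fit, data.frame(t = t_new, mon = mon_new)))
  point <- pmax(point, 0) * (1 + growth_rate)^(seq_len(horizon) / 12)
  structure(list(point = pmax(point, 0), horizon = as.integer(horizon),
                 growth_rate = growth_rate, condition = hs$condition,
                 stream = hs$stream,
                 start_month = month_start(n + 1L, hs$start_month)),
            class = "monthly_forecast")
}

#' Forecast accuracy as 100 minus the mean absolute percentage error
#'
#' @param forecast,actual equal-length numeric vectors; months with zero
#'   actuals are excluded from the MAPE with a warning.
#' @return Accuracy in percent, clipped to `[0, 100]`.
#' @export
forecast_accuracy <- function(forecast, actual) {
  if (inherits(forecast, "monthly_forecast")) forecast <- forecast$point
  stopifnot(length(forecast) == length(actual))
  keep <- actual != 0
  if (!any(keep)) stop("all actual months are zero; MAPE undefined")
  if (any(!keep)) warning(sum(!keep), " zero-actual month(s) excluded from MAPE")
  mape <- mean(abs(forecast[keep] - actual[keep]) / actual[keep]) * 100
  min(max(100 - mape, 0), 100)
}

#' @rdname monthly_series
#' @param series a [monthly_series()] or list of them.
#' @param path CSV path with columns `month,condition,stream,count`.
#' @export
write_monthly_series <- function(series, path) {
  if (inherits(series, "monthly_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(month = format(seq(s$start_month, by = "month",
                                  length.out = length(s$values)), "%Y-%m-%d"),
               condition = s$condition, stream = s$stream, count = s$values)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname monthly_series
#' @export
read_monthly_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("month", "condition", "stream", "count") %in% names(df)))
  keys <- unique(df[, c("condition", "stream")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$condition == keys$condition[i] & df$stream == keys$stream[i], ]
    sub <- sub[order(as.Date(sub$month)), ]
    monthly_series(sub$count, as.Date(sub$month[1]), keys$condition[i],
                   keys$stream[i])
  })
  if (length(out) == 1L) out[[1L]] else out
}
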