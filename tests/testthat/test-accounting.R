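toy_trace <- function(visit_types, months = 4L, report = seq_len(months)) {
  n <- length(visit_types)
  visits <- data.frame(
    patient_id = sprintf("p%d", seq_len(n)), condition = rep("AMD", n),
    visit_type = visit_types,
    venue = ifelse(visit_types == "virtual_fu", "virtual", "hospital"),
    due = rep(1L, n), year = rep(1L, n), booked = rep(1L, n),
    service_day = rep(1L, n), outcome = rep("attended", n),
    rebooked = rep(FALSE, n), month = rep(1L, n),
    stringsAsFactors = FALSE
  )
  pools <- c("clinic_session", "nurse", "consultation_room", "injection_bed",
             "virtual_capacity")
  rm_df <- expand.grid(month = seq_len(months), pool = pools,
                       stringsAsFactors = FALSE)
  rm_df$busy <- 0
  rm_df$available <- 1000
  structure(list(visits = visits, resource_months = rm_df,
                 report_months = report, start = as.Date("2016-04-01"),
                 rep = 1L),
            class = "simulation_trace")
}

test_that("an empty trace produces an all-zero report", {
  tr <- toy_trace(character(0))
  k <- kpi_from_trace(tr, tariff_table())
  expect_true(all(k$metrics == 0))
})

test_that("a hospital monitoring visit bills the reference 89 GBP tariff", {
  tr <- toy_trace("observation_fu", months = 1L, report = 1L)
  k <- kpi_from_trace(tr, tariff_table())
  expect_equal(unname(k$metrics["revenue"]), 89)
  expect_equal(unname(k$metrics["costing"]), 89)
  expect_equal(unname(k$metrics["followups"]), 1)
})

test_that("virtual monitoring saves the stated cost difference", {
  tr_h <- toy_trace(rep("observation_fu", 10), months = 1L, report = 1L)
  tr_v <- toy_trace(rep("virtual_fu", 10), months = 1L, report = 1L)
  tar <- tariff_table(virtual_fu_cost = 37.5)
  dh <- kpi_from_trace(tr_h, tar)$metrics["costing"]
  dv <- kpi_from_trace(tr_v, tar)$metrics["costing"]
  expect_equal(unname(dh - dv), 10 * (89 - 37.5))  # 515 GBP
  expect_error(tariff_table(virtual_fu_cost = 20), ">= 30")
})

test_that("surplus identity and utilisation bounds are enforced on reports", {
  expect_error(kpi_report(c(revenue = 100, costing = 40, surplus = 70)),
               "surplus")
  expect_error(kpi_report(c(utilisation_nurse = 1.2)), "utilisation")
  k <- kpi_report(c(revenue = 100, costing = 40, surplus = 60))
  expect_s3_class(k, "kpi_report")
})

test_that("percentage change reproduces worked examples and handles zero baselines", {
  base <- kpi_report(c(n_injections = 169, surplus = 55735, idle = 0))
  alt <- kpi_report(c(n_injections = 215, surplus = 61464, idle = 0))
  cmp <- compare_scenarios(base, alt)
  expect_identical(cmp$pct_change[cmp$kpi == "n_injections"], 27)
  expect_identical(cmp$pct_change[cmp$kpi == "surplus"], 10)
  expect_identical(cmp$pct_change[cmp$kpi == "idle"], 0)

  same <- compare_scenarios(base, base)
  expect_true(all(same$pct_change == 0))

  z <- compare_scenarios(kpi_report(c(a = 0)), kpi_report(c(a = 5)))
  expect_true(is.na(z$pct_change))

  expect_error(compare_scenarios(base, kpi_report(c(other = 1))), "schema")
})

test_that("rounding convention reproduces every reported percentage-change cell", {
  m <- ref_monthly_averages()
  reports <- lapply(colnames(m), function(s) kpi_report(m[, s], scenario = s))
  names(reports) <- colnames(m)
  tab <- render_table4(reports)
  expect_identical(stats::setNames(tab$pct_change, tab$kpi),
                   attr(m, "pct_change"))
})

test_that("the four-scenario table is name-keyed, not position-keyed", {
  m <- ref_monthly_averages()
  reports <- lapply(colnames(m), function(s) kpi_report(m[, s], scenario = s))
  names(reports) <- colnames(m)
  tab <- render_table4(reports)
  perm <- render_table4(reports[c(3, 1, 4, 2)])
  expect_identical(tab, perm)
  expect_error(render_table4(reports[1:3]), "virtual_clinic_treat_and_extend")

  zero <- lapply(reports, function(r)
    kpi_report(stats::setNames(rep(0, length(r$metrics)), names(r$metrics))))
  tz <- render_table4(zero)
  expect_true(all(tz$current_service == 0))
  expect_true(all(tz$pct_change == 0))

  path <- withr::local_tempfile(fileext = ".csv")
  write_table4(tab, csv_path = path)
  expect_identical(nrow(read.csv(path)), nrow(tab))
})

test_that("revenue and costing are additive over months (linearity)", {
  tr1 <- toy_trace(c("injection", "observation_fu"), months = 2L, report = 1:2)
  k1 <- kpi_from_trace(tr1, tariff_table())
  # same visits averaged over twice the months halves every monthly mean
  expect_equal(unname(k1$metrics["revenue"]), (740 + 89) / 2)
  expect_equal(unname(k1$metrics["surplus"]),
               unname(k1$metrics["revenue"] - k1$metrics["costing"]))
})
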