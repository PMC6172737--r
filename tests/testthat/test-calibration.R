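make_records <- function(df) {
  df$status <- df$status %||% "attended"
  df$discharged_year <- df$discharged_year %||% NA_integer_
  retinasim:::new_records(df, as.Date("2013-04-01"), 36L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("count_events counts per patient-year from first attendance", {
  df <- data.frame(
    patient_id = "p1", condition = "AMD",
    visit_date = as.Date("2013-04-15") + c(0, 90, 180, 270, 400, 800, 1150),
    visit_type = "injection", status = "attended",
    stringsAsFactors = FALSE
  )
  cnt <- count_events(make_records(df), "injection")
  expect_identical(cnt$count[cnt$year == 1], 4L)
  expect_identical(cnt$count[cnt$year == 2], 1L)
  expect_identical(cnt$count[cnt$year == 3], 2L)  # years > 3 pooled into 3
})

test_that("count_events equals a brute-force row scan on any record set", {
  rec <- generate_cohort(mini_spec())
  for (cat in c("injection", "observation_fu", "laser")) {
    cnt <- count_events(rec, cat)
    brute <- sum(rec$status == "attended" & rec$visit_type == cat)
    expect_identical(sum(cnt$count), as.integer(brute))
  }
})

test_that("estimate_mix returns exact patient proportions", {
  counts <- matrix(0L, 5, 3, dimnames = list(activity_categories(), conditions()))
  counts["observation_fu", ] <- c(172L, 423L, 405L) * 2L
  spec <- cohort_spec(1000, c(AMD = 0.172, DR = 0.423, MR = 0.405), counts,
                      array(0L, c(3, 2, 3)), seed = 2)
  mix <- estimate_mix(generate_cohort(spec))
  expect_equal(unname(mix), c(0.172, 0.423, 0.405))
  expect_equal(sum(mix), 1)

  one <- make_records(data.frame(patient_id = "a", condition = "AMD",
                                 visit_date = as.Date("2013-05-01"),
                                 visit_type = "observation_fu",
                                 status = "attended", stringsAsFactors = FALSE))
  expect_equal(unname(estimate_mix(one)), c(1, 0, 0))
})

test_that("discharge estimation: hand-counted toy probabilities and exact totals", {
  df <- data.frame(
    patient_id = sprintf("p%02d", 1:10), condition = "DR",
    visit_date = as.Date("2013-05-01"), visit_type = "observation_fu",
    status = "attended",
    discharged_year = c(1L, 1L, 1L, rep(NA_integer_, 7)),
    stringsAsFactors = FALSE
  )
  dm <- estimate_discharge(make_records(df))
  expect_equal(dm$prob["DR", "observation", "1"], 0.3)
  expect_equal(dm$total_discharges, 3L)

  rec <- generate_cohort(mini_spec())
  pt_discharged <- tapply(!is.na(rec$discharged_year), rec$patient_id, any)
  expect_identical(estimate_discharge(rec)$total_discharges,
                   as.integer(sum(pt_discharged)))

  none <- make_records(data.frame(patient_id = "p", condition = "MR",
                                  visit_date = as.Date("2013-05-01"),
                                  visit_type = "observation_fu",
                                  status = "attended", stringsAsFactors = FALSE))
  expect_true(all(estimate_discharge(none)$prob == 0))
})

test_that("activity table is invariant to record order and non-attended rows", {
  rec <- generate_cohort(mini_spec())
  base <- unclass(activity_table(rec))
  shuffled <- rec[sample(nrow(rec)), ]
  expect_identical(unclass(activity_table(shuffled)), base)
  attended_only <- rec[rec$status == "attended", ]
  expect_identical(unclass(activity_table(attended_only)), base)
  empty <- activity_table(rec[0, ])
  expect_true(all(empty == 0L))
})

test_that("eligibility filter equals the naive double-loop oracle and the planted set", {
  rec <- generate_cohort(mini_spec(seed = 9, eligible = 7))
  got <- select_virtual_clinic_eligible(rec)
  expect_identical(got, oracle_eligible(rec))
  expect_identical(got, sort(attr(rec, "planted_eligible")))
  expect_identical(length(got), 7L)
  expect_identical(select_virtual_clinic_eligible(rec[0, ],
                                                  as_of = as.Date("2016-03-31")),
                   character(0))
})

test_that("eligibility window boundaries behave as half-open intervals", {
  as_of <- as.Date("2016-03-31")
  df <- data.frame(
    patient_id = c("late_inj", "late_inj", "stale", "ok", "boundary"),
    condition = "AMD",
    visit_date = as.Date(c("2015-06-01", "2016-01-15",  # injection 3 months ago
                           "2014-02-01",                # last seen 25 months ago
                           "2015-12-01",
                           "2014-03-31")),              # exactly on the boundary
    visit_type = c("observation_fu", "injection", "observation_fu",
                   "observation_fu", "observation_fu"),
    status = "attended", stringsAsFactors = FALSE
  )
  got <- select_virtual_clinic_eligible(make_records(df), as_of = as_of)
  expect_identical(got, "ok")
})

test_that("calibrate_service bundles every estimator and writes JSON", {
  rec <- generate_cohort(mini_spec())
  cal <- calibrate_service(rec)
  expect_s3_class(cal$count_distributions[[1]], "count_distribution")
  expect_equal(sum(cal$case_mix), 1)
  expect_identical(sort(cal$eligible_ids),
                   sort(attr(rec, "planted_eligible")))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$case_mix$AMD, unname(cal$case_mix["AMD"]))
})
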