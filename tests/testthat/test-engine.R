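test_that("plan_care_year draws regimen counts and spreads due dates over the year", {
  deg <- regimen_spec("PRN",
                      injections_per_year = rep(list(empirical_counts(3L)), 3),
                      fus_per_year = rep(list(empirical_counts(2L)), 3))
  plan <- plan_care_year(list(treated = TRUE), deg, 1, u = c(0.5, 0.5))
  expect_identical(sum(plan$visit_type == "injection"), 3L)
  expect_identical(sum(plan$visit_type == "injection_fu"), 2L)
  expect_true(all(plan$offset >= 0 & plan$offset <= 365))
  inj <- plan$offset[plan$visit_type == "injection"]
  expect_equal(inj, round((1:3 - 0.5) / 3 * 365))

  # combined assessment subsumes follow-ups up to the injection count
  te <- regimen_spec("TE",
                     injections_per_year = rep(list(empirical_counts(5L)), 3),
                     fus_per_year = rep(list(empirical_counts(7L)), 3))
  p2 <- plan_care_year(list(treated = TRUE), te, 2, u = c(0.5, 0.5))
  expect_identical(sum(p2$visit_type == "injection_fu"), 2L)

  # untreated patients only monitor
  p3 <- plan_care_year(list(treated = FALSE), regimen_spec("PRN"), 1,
                       u = c(0.5, 0.5))
  expect_true(all(p3$visit_type == "observation_fu"))
})

test_that("simulated yearly injection means match the regimen calibration", {
  set.seed(21)
  n <- 4000
  u <- matrix(runif(2 * n), n)
  prn <- regimen_spec("PRN")
  m1 <- mean(vapply(seq_len(n), function(i)
    sum(plan_care_year(list(treated = TRUE), prn, 1,
                       u = u[i, ])$visit_type == "injection"), numeric(1)))
  expect_lt(abs(m1 - 4), 3 * 2 / sqrt(n))
  te <- regimen_spec("TE")
  m2 <- mean(vapply(seq_len(n), function(i)
    sum(plan_care_year(list(treated = TRUE), te, 1,
                       u = u[i, ])$visit_type == "injection"), numeric(1)))
  expect_lt(abs(m2 - 8), 3 * 4 / sqrt(n))
})

test_that("apply_discharge is an exact Bernoulli draw on the year hazard", {
  model <- ref_discharge_model()
  model$prob[] <- 0
  p <- list(condition = "AMD", treated = FALSE)
  expect_false(any(vapply(runif(200), function(u)
    apply_discharge(p, 1, model, u), logical(1))))
  model$prob[] <- 1
  expect_true(all(vapply(runif(200), function(u)
    apply_discharge(p, 1, model, u), logical(1))))
  model$prob[] <- 0.3
  set.seed(8)
  rate <- mean(vapply(runif(10000), function(u)
    apply_discharge(p, 2, model, u), logical(1)))
  expect_lt(abs(rate - 0.3), 0.015)
})

test_that("a zero-demand scenario yields an exactly zero report", {
  cfg <- scenario_config(arrivals = list(AMD = 0, DR = 0, MR = 0),
                         prevalent = list(n = 0), horizon_months = 15,
                         seed = 2)
  res <- run_scenario(cfg, replications = 1)
  expect_true(all(res$report$metrics == 0))
})

test_that("a fixed seed reproduces the trace bit for bit", {
  cfg <- small_config()
  a <- run_scenario(cfg, replications = 1)
  b <- run_scenario(cfg, replications = 1)
  expect_identical(a$traces[[1]], b$traces[[1]])
  expect_identical(a$report$metrics, b$report$metrics)
})

test_that("trace conservation: every due visit has exactly one recorded outcome", {
  res <- run_scenario(small_config(), replications = 1)
  v <- res$traces[[1]]$visits
  expect_true(all(v$outcome %in% c("attended", "dna", "cancelled", "overflow")))
  expect_false(any(is.na(v$outcome)))
  att <- v[v$outcome == "attended", ]
  expect_true(all(att$service_day >= att$due))
  expect_true(all(!is.na(att$month)))
})

test_that("utilisation stays within [0, 1] for every pool and month", {
  res <- run_scenario(small_config(seed = 31), replications = 2)
  rm_df <- res$traces[[1]]$resource_months
  busy_months <- rm_df[rm_df$available > 0, ]
  expect_true(all(busy_months$busy <= busy_months$available))
  expect_true(all(rm_df$busy[rm_df$available == 0] == 0))
})

test_that("treat-and-extend plans at least as many injections as PRN, pairwise", {
  mk <- function(reg) scenario_config(regimen = regimen_spec(reg),
                                      prevalent = list(n = 150),
                                      horizon_months = 15, seed = 17)
  prn <- run_scenario(mk("PRN"), replications = 3, keep_trace = TRUE)
  te <- run_scenario(mk("TE"), replications = 3, keep_trace = TRUE)
  n_inj <- function(res) vapply(res$traces, function(t)
    sum(t$visits$visit_type == "injection"), numeric(1))
  expect_true(all(n_inj(te) >= n_inj(prn)))
})

test_that("enabling the virtual clinic weakly lowers hospital clinic load", {
  mk <- function(vc) scenario_config(virtual_clinic = vc,
                                     prevalent = list(n = 150),
                                     horizon_months = 15, seed = 19)
  off <- run_scenario(mk(FALSE), replications = 3, keep_trace = TRUE)
  on <- run_scenario(mk(TRUE), replications = 3, keep_trace = TRUE)
  busy <- function(res) vapply(res$traces, function(t) {
    rm_df <- t$resource_months
    sum(rm_df$busy[rm_df$pool == "clinic_session"])
  }, numeric(1))
  expect_true(all(busy(on) <= busy(off)))
  expect_identical(sum(off$traces[[1]]$visits$visit_type == "virtual_fu"), 0L)
  expect_gt(sum(on$traces[[1]]$visits$visit_type == "virtual_fu"), 0L)
})

test_that("diverted patients are exactly the eligible set from the records", {
  rec <- generate_cohort(mini_spec(seed = 13, eligible = 8))
  pool <- prevalent_from_records(rec)
  expect_identical(sort(pool$patient_id[pool$eligible]),
                   select_virtual_clinic_eligible(rec))
  no_discharge <- ref_discharge_model()
  no_discharge$prob[] <- 0
  cfg <- scenario_config(virtual_clinic = TRUE, prevalent = pool,
                         arrivals = list(AMD = 0, DR = 0, MR = 0),
                         discharge = no_discharge,
                         horizon_months = 24, warmup_months = 3,
                         report_months = 12, seed = 23)
  res <- run_scenario(cfg, replications = 1)
  v <- res$traces[[1]]$visits
  diverted <- unique(v$patient_id[v$visit_type == "virtual_fu"])
  expect_identical(sort(diverted), sort(pool$patient_id[pool$eligible]))
  # eligible patients never occupy a hospital monitoring slot
  expect_identical(sum(v$visit_type == "observation_fu" &
                         v$patient_id %in% diverted), 0L)
})

test_that("the booked schedule equals the earliest-slot oracle when nobody fails", {
  cfg <- scenario_config(prevalent = list(n = 40),
                         arrivals = list(AMD = 2, DR = 2, MR = 2),
                         booking = booking_system(
                           rules = booking_rules(dna_prob = 0, cancel_prob = 0)),
                         horizon_months = 15, seed = 29)
  res <- run_scenario(cfg, replications = 1)
  v <- res$traces[[1]]$visits
  h <- v[v$venue == "hospital", ]
  n_days <- as.integer(retinasim:::month_end(15, cfg$start) - cfg$start) + 1L
  cal <- slot_calendar(n_days, cfg$start,
                       cfg$booking$hospital_slots_per_weekday)
  expected <- oracle_book(h$due, cal)
  expect_identical(h$service_day, expected)
})
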