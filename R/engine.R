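#' Scenario configuration for the care-pathway simulator
#'
#' A scenario bundles everything one run needs: the treatment regimen, the
#' virtual-clinic flag, monthly new-patient arrival means per condition, the
#' probability that a new patient enters treatment, the discharge model, the
#' prevalent (established) caseload present at the start, resources, booking
#' rules, tariffs and the time axis. Defaults reproduce the reference
#' service's published calibration where figures exist (119 new attendances
#' per month split by the 17.2/42.3/40.5% case mix, discharge hazards from
#' the published discharge table) and documented assumptions elsewhere.
#'
#' The simulated horizon exceeds the reported window: `warmup_months` are
#' discarded to remove empty-system bias and `report_months` (default 12)
#' are averaged for KPIs.
#'
#' @param regimen a [regimen_spec()].
#' @param virtual_clinic divert eligible monitoring patients to a nurse-led
#'   virtual clinic?
#' @param arrivals named list over `conditions()` of monthly new-arrival
#'   means (length 1 or `horizon_months`), or `monthly_forecast` objects.
#' @param p_treated named probability per condition that a new patient ever
#'   enters treatment (default derived from the reference patient split).
#' @param discharge a `discharge_model` (see [estimate_discharge()],
#'   [ref_discharge_model()]).
#' @param prevalent either `list(n =, eligible_frac =, year_weights =)`
#'   describing a synthetic established caseload, or a data.frame from
#'   [prevalent_from_records()].
#' @param resources a [service_resources()].
#' @param booking a [booking_system()].
#' @param tariffs a [tariff_table()].
#' @param horizon_months,warmup_months,report_months simulated, discarded
#'   and reported months; `warmup + report <= horizon`.
#' @param replications independent replications pooled in the KPI report.
#' @param seed master seed; every stream is derived from it.
#' @param start first simulated day.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(regimen = regimen_spec("PRN"),
                            virtual_clinic = FALSE,
                            arrivals = NULL,
                            p_treated = NULL,
                            discharge = NULL,
                            prevalent = NULL,
                            resources = service_resources(),
                            booking = booking_system(),
                            tariffs = tariff_table(),
                            horizon_months = 15L, warmup_months = 3L,
                            report_months = 12L, replications = 100L,
                            seed = 1L, start = as.Date("2016-04-01")) {
  stopifnot(inherits(regimen, "regimen_spec"), replications >= 1,
            warmup_months >= 0, report_months >= 1,
            warmup_months < horizon_months,
            warmup_months + report_months <= horizon_months)
  mix <- ref_case_mix()
  if (is.null(arrivals))
    arrivals <- as.list(119 * mix)
  arr <- vapply(conditions(), function(c) {
    a <- arrivals[[c]]
    if (inherits(a, "monthly_forecast")) a <- a$point
    stopifnot(all(a >= 0))
    rep_len(as.numeric(a), horizon_months)
  }, numeric(horizon_months))
  if (is.null(p_treated)) {
    sp <- ref_patient_split()
    p_treated <- stats::setNames((sp$injection + sp$laser) / sp$n, conditions())
  }
  if (is.null(discharge)) discharge <- ref_discharge_model()
  if (is.null(prevalent)) prevalent <- list(n = 1000L)
  if (is.list(prevalent) && !is.data.frame(prevalent)) {
    prevalent$n <- as.integer(prevalent$n %||% 1000L)
    prevalent$eligible_frac <- prevalent$eligible_frac %||% (894 / 4256)
    prevalent$year_weights <- prevalent$year_weights %||% c(0, 0.5, 0.5)
  }
  structure(
    list(regimen = regimen, virtual_clinic = isTRUE(virtual_clinic),
         arrivals = arr, p_treated = p_treated[conditions()],
         discharge = discharge, prevalent = prevalent,
         resources = resources, booking = booking, tariffs = tariffs,
         horizon_months = as.integer(horizon_months),
         warmup_months = as.integer(warmup_months),
         report_months = as.integer(report_months),
         replications = as.integer(replications),
         seed = as.integer(seed), start = as.Date(start)),
    class = "scenario_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname scenario_config
#' @param rules a [booking_rules()].
#' @param hospital_slots_per_weekday,virtual_slots_per_weekday weekly slot
#'   templates (Monday first).
#' @export
booking_system <- function(rules = booking_rules(),
                           hospital_slots_per_weekday = c(32L, 32L, 32L, 32L, 32L, 0L, 0L),
                           virtual_slots_per_weekday = c(20L, 20L, 20L, 20L, 20L, 0L, 0L)) {
  list(rules = rules,
       hospital_slots_per_weekday = as.integer(hospital_slots_per_weekday),
       virtual_slots_per_weekday = as.integer(virtual_slots_per_weekday))
}

#' Discharge model built from the reference discharge table
#'
#' Per-year hazards computed from the published discharge counts with
#' at-risk denominators from [ref_patient_split()].
#'
#' @return A `discharge_model` (same shape as [estimate_discharge()]).
#' @export
ref_discharge_model <- function() {
  counts <- ref_discharge_counts()
  sp <- ref_patient_split()
  dims <- dimnames(counts)
  prob <- array(0, dim = dim(counts), dimnames = dims)
  for (c in conditions()) for (s in dims$status) {
    at_risk <- if (s == "treated") sp[c, "injection"] + sp[c, "laser"]
               else sp[c, "observation"]
    for (y in 1:3) {
      if (at_risk > 0) prob[c, s, y] <- counts[c, s, y] / at_risk
      at_risk <- at_risk - counts[c, s, y]
    }
  }
  structure(list(prob = prob, cohort_share = counts / sum(sp$n),
                 counts = counts, n_patients = sum(sp$n),
                 total_discharges = sum(counts)),
            class = "discharge_model")
}

#' Draw a discharge decision at a care-year end
#'
#' @param patient list with `condition` and `treated`.
#' @param year completed care year (capped at 3 for the model lookup).
#' @param model a `discharge_model`.
#' @param u optional uniform; drawn from the RNG otherwise.
#' @return `TRUE` if the patient is discharged and generates no further
#'   visits.
#' @export
apply_discharge <- function(patient, year, model, u = NULL) {
  if (is.null(u)) u <- runif(1L)
  s <- if (isTRUE(patient$treated)) "treated" else "observation"
  u < model$prob[patient$condition, s, as.character(min(year, 3L))]
}

#' Divert eligible patients' monitoring visits to the virtual clinic
#'
#' Re-types `observation_fu` visits of eligible patients as `virtual_fu`,
#' which the engine books against virtual-clinic capacity and bills at the
#' virtual tariff. With the virtual clinic disabled this is the identity.
#'
#' @param visits data.frame with `patient_id` and `visit_type`.
#' @param eligible_ids patient ids satisfying the eligibility predicate.
#' @param active is a virtual clinic running?
#' @return The visits data.frame with re-typed rows.
#' @export
divert_to_virtual <- function(visits, eligible_ids, active = TRUE) {
  if (!active || length(eligible_ids) == 0L) return(visits)
  sel <- visits$visit_type == "observation_fu" &
    visits$patient_id %in% eligible_ids
  visits$visit_type[sel] <- "virtual_fu"
  visits
}

#' Establish the prevalent caseload from patient-level records
#'
#' Patients active at `as_of` (attended within 24 months, not discharged)
#' enter the simulation as the established caseload; those passing the
#' virtual-clinic eligibility predicate are flagged.
#'
#' @param records a `retinal_records` data.frame.
#' @param as_of reference day (default: window end).
#' @return data.frame `patient_id`, `condition`, `treated`, `eligible`.
#' @export
prevalent_from_records <- function(records, as_of = NULL) {
  if (is.null(as_of)) as_of <- attr(records, "as_of")
  if (is.null(as_of)) as_of <- max(records$visit_date)
  as_of <- as.Date(as_of)
  pt <- patient_table(records)
  lo24 <- months_before(as_of, 24L)
  att <- records[records$status == "attended", ]
  recent <- unique(att$patient_id[att$visit_date > lo24 & att$visit_date <= as_of])
  pt <- pt[pt$patient_id %in% recent & is.na(pt$discharged_year), ]
  elig <- select_virtual_clinic_eligible(records, as_of)
  data.frame(patient_id = pt$patient_id, condition = pt$condition,
             treated = pt$treated, eligible = pt$patient_id %in% elig,
             stringsAsFactors = FALSE, row.names = NULL)
}

# deterministic 31-bit seed derived from integer components
derive_seed <- function(...) {
  x <- 17
  for (a in c(...)) x <- (x * 69069 + (as.numeric(a) %% 2147483629) + 1) %% 2147483647
  as.integer(x)
}

#' Run a scenario of the retinal-service simulation
#'
#' Event-ordered execution per replication: Poisson arrivals from the
#' monthly forecast, per-patient care-year planning under the regimen,
#' earliest-free-slot booking with DNA/cancellation rebooking, resource
#' seizure, discharge at care-year ends, and virtual-clinic diversion of
#' eligible monitoring patients. Every random mechanism draws from a stream
#' derived from `(seed, replication, patient)`, so a fixed seed yields a
#' bit-identical trace and paired scenarios share randomness (common random
#' numbers).
#'
#' @param config a [scenario_config()].
#' @param replications overrides `config$replications`.
#' @param scenario label attached to the KPI report.
#' @param keep_trace return per-replication traces (memory permitting)?
#' @return A `scenario_result`: `report` (pooled [kpi_report()]), `per_rep`
#'   (replications x metric matrix), and `traces` (list of
#'   `simulation_trace`, first replication always kept).
#' @export
run_scenario <- function(config, replications = NULL, scenario = NULL,
                         keep_trace = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  R <- as.integer(replications %||% config$replications)
  scenario <- scenario %||%
    paste0(config$regimen$name, if (config$virtual_clinic) "+VC")
  H <- config$horizon_months
  start <- config$start
  n_days <- as.integer(month_end(H, start) - start) + 1L
  msd <- vapply(seq_len(H + 1L), function(m)
    as.integer(month_start(m, start) - start), integer(1))
  day_month <- findInterval(seq_len(n_days) - 1L, msd)
  wday <- as.POSIXlt(start + seq_len(n_days) - 1L)$wday
  widx <- ifelse(wday == 0L, 7L, wday)
  avail <- avail_minutes(config$resources, widx, day_month, H)

  per_rep <- NULL
  traces <- list()
  for (r in seq_len(R)) {
    tr <- simulate_replication(config, r, n_days, day_month, widx, avail)
    k <- kpi_from_trace(tr, config$tariffs, scenario = scenario)
    if (is.null(per_rep))
      per_rep <- matrix(NA_real_, R, length(k$metrics),
                        dimnames = list(NULL, names(k$metrics)))
    per_rep[r, ] <- k$metrics
    if (keep_trace || r == 1L) traces[[r]] <- tr
  }
  pooled <- kpi_report(colMeans(per_rep), scenario = scenario,
                       replications = R, horizon = config$report_months)
  structure(list(report = pooled, per_rep = per_rep, traces = traces,
                 config = config),
            class = "scenario_result")
}

# scheduled minutes per (month, pool)
avail_minutes <- function(resources, widx, day_month, H) {
  pools <- resources$pools
  out <- matrix(0, H, length(pools), dimnames = list(NULL, pools))
  for (p in pools) {
    per_day <- resources$daily_minutes[p, widx]
    out[, p] <- as.numeric(tapply(per_day, day_month, sum)[as.character(seq_len(H))])
  }
  out[is.na(out)] <- 0
  out
}

simulate_replication <- function(config, r, n_days, day_month, widx, avail) {
  H <- config$horizon_months
  seed <- config$seed
  mix <- ref_case_mix()
  max_years <- H %/% 12L + 2L

  # --- arrival counts: one uniform per (month, condition), its own stream
  set.seed(derive_seed(seed, r, 1L))
  u_arr <- matrix(runif(H * 3L), H, 3L)
  n_arr <- matrix(qpois(u_arr, config$arrivals), H, 3L)

  # --- prevalent caseload composition (deterministic or from records)
  prev <- config$prevalent
  if (is.data.frame(prev)) {
    prev_df <- prev
  } else if (prev$n > 0L) {
    n_c <- allocate_integer(prev$n, mix)
    cond <- rep(conditions(), n_c)
    n_tr <- round(config$p_treated[conditions()] * n_c)
    treated <- unlist(lapply(seq_along(n_c), function(i)
      rep(c(TRUE, FALSE), c(n_tr[i], n_c[i] - n_tr[i]))))
    prev_df <- data.frame(
      patient_id = sprintf("E%05d", seq_len(sum(n_c))),
      condition = cond, treated = treated, eligible = FALSE,
      stringsAsFactors = FALSE)
    unt <- which(!prev_df$treated)
    k_el <- round(prev$eligible_frac * length(unt))
    if (k_el > 0L) {
      set.seed(derive_seed(seed, r, 2L))
      prev_df$eligible[unt[sample.int(length(unt), k_el)]] <- TRUE
    }
  } else {
    prev_df <- data.frame(patient_id = character(0), condition = character(0),
                          treated = logical(0), eligible = logical(0))
  }

  acc <- list()
  add <- function(x) acc[[length(acc) + 1L]] <<- x

  # --- prevalent patients: current care year already in progress
  yw <- if (is.data.frame(prev)) c(0, 0.5, 0.5) else prev$year_weights
  cyw <- cumsum(yw / sum(yw))
  for (j in seq_len(nrow(prev_df))) {
    pkey <- derive_seed(seed, r, 3L, j)
    set.seed(pkey)
    u0 <- runif(2L)
    day0 <- 1L - as.integer(floor(u0[1] * 365))
    year0 <- findInterval(u0[2], cyw) + 1L
    add(sim_patient_years(prev_df$patient_id[j], prev_df$condition[j],
                          prev_df$treated[j], prev_df$eligible[j],
                          year0, day0, config, n_days, max_years))
  }

  # --- new arrivals
  for (m in seq_len(H)) for (ci in 1:3) {
    nk <- n_arr[m, ci]
    if (nk == 0L) next
    d0 <- as.integer(month_start(m, config$start) - config$start)
    dlen <- as.integer(month_end(m, config$start) - month_start(m, config$start)) + 1L
    for (k in seq_len(nk)) {
      pkey <- derive_seed(seed, r, 4L, m, ci, k)
      set.seed(pkey)
      u0 <- runif(2L)
      day0 <- d0 + as.integer(floor(u0[1] * dlen)) + 1L
      treated <- u0[2] < config$p_treated[ci]
      pid <- sprintf("A%02d.%d.%03d", m, ci, k)
      add(sim_patient_years(pid, conditions()[ci], treated, FALSE,
                            1L, day0, config, n_days, max_years,
                            new_referral = TRUE))
    }
  }

  if (length(acc) == 0L) return(empty_trace(config, avail, r))
  nn <- vapply(acc, `[[`, integer(1), "n")
  visits <- data.frame(
    patient_id = rep(vapply(acc, `[[`, character(1), "pid"), nn),
    condition = rep(vapply(acc, `[[`, character(1), "cond"), nn),
    eligible = rep(vapply(acc, `[[`, logical(1), "eligible"), nn),
    due = unlist(lapply(acc, `[[`, "due")),
    visit_type = visit_types()[unlist(lapply(acc, `[[`, "type"))],
    year = unlist(lapply(acc, `[[`, "year")),
    u_cancel = unlist(lapply(acc, `[[`, "uc")),
    u_dna = unlist(lapply(acc, `[[`, "ud")),
    stringsAsFactors = FALSE
  )

  visits <- divert_to_virtual(visits,
                              unique(visits$patient_id[visits$eligible]),
                              active = config$virtual_clinic)
  visits$venue <- ifelse(visits$visit_type == "virtual_fu", "virtual", "hospital")
  ord <- order(visits$due, visits$patient_id, visit_type_rank(visits$visit_type))
  visits <- visits[ord, ]

  rules <- config$booking$rules
  out <- data.frame(booked = rep(NA_integer_, nrow(visits)),
                    service_day = NA_integer_, outcome = NA_character_,
                    rebooked = FALSE)
  for (v in c("hospital", "virtual")) {
    sel <- visits$venue == v
    if (!any(sel)) next
    slots <- if (v == "hospital") config$booking$hospital_slots_per_weekday
             else config$booking$virtual_slots_per_weekday
    cal <- slot_calendar(n_days, config$start, slots)
    bk <- book_visits(visits$due[sel], cal, visits$u_cancel[sel],
                      visits$u_dna[sel], rules)
    out[sel, ] <- bk$visits[, c("booked", "service_day", "outcome", "rebooked")]
  }
  visits <- cbind(visits[, c("patient_id", "condition", "visit_type", "venue",
                             "due", "year")], out)
  visits$month <- ifelse(is.na(visits$service_day), NA_integer_,
                         day_month[visits$service_day])

  # busy minutes per (month, pool) from attended visits
  att <- visits[visits$outcome == "attended", ]
  mpv <- config$resources$minutes_per_visit
  busy <- matrix(0, config$horizon_months, length(config$resources$pools),
                 dimnames = list(NULL, config$resources$pools))
  if (nrow(att)) {
    for (p in config$resources$pools) {
      mins <- mpv[p, att$visit_type]
      agg <- tapply(mins, att$month, sum)
      busy[as.integer(names(agg)), p] <- as.numeric(agg)
    }
  }
  new_trace(visits, busy, avail, config, r)
}

# plan all care years of one patient; mirrors plan_care_year()/
# apply_discharge() but accumulates bare vectors (visit types as integer
# codes into visit_types()) for speed in the replication loop
sim_patient_years <- function(pid, cond, treated, eligible, year0, day0,
                              config, n_days, max_years, new_referral = FALSE) {
  u <- runif(3L * max_years)
  reg <- config$regimen
  dprob <- config$discharge$prob[cond, if (treated) "treated" else "observation", ]
  due <- integer(0); type <- integer(0); year <- integer(0)
  if (new_referral && day0 >= 1L && day0 <= n_days) {
    due <- day0; type <- 1L; year <- year0
  }
  spread <- function(k) if (k == 0L) integer(0) else
    as.integer(round((seq_len(k) - 0.5) / k * 365))
  d <- day0
  y <- year0
  for (b in seq_len(max_years)) {
    if (d > n_days) break
    k <- 3L * (b - 1L)
    yy <- min(y, 3L)
    if (treated) {
      n_inj <- q_count(u[k + 1L], reg$injections_per_year[[yy]])
      n_fu <- q_count(u[k + 2L], reg$fus_per_year[[yy]])
      if (reg$combined_assessment) n_fu <- max(0L, n_fu - n_inj)
      dd <- d + c(spread(n_inj), spread(n_fu))
      tt <- rep(c(2L, 3L), c(n_inj, n_fu))  # injection, injection_fu
    } else {
      n_fu <- q_count(u[k + 2L], reg$obs_fus_per_year[[yy]])
      dd <- d + spread(n_fu)
      tt <- rep(6L, n_fu)                   # observation_fu
    }
    keep <- dd >= 1L & dd <= n_days
    due <- c(due, dd[keep]); type <- c(type, tt[keep])
    year <- c(year, rep(y, sum(keep)))
    if (u[k + 3L] < dprob[yy]) break
    d <- d + 365L
    y <- y + 1L
  }
  n <- length(due)
  if (n == 0L) return(NULL)
  uo <- matrix(runif(2L * n), n, 2L)
  o <- order(due)
  list(pid = pid, cond = cond, eligible = eligible, n = n,
       due = due[o], type = type[o], year = year[o],
       uc = uo[o, 1], ud = uo[o, 2])
}

new_trace <- function(visits, busy, avail, config, rep) {
  rm_df <- data.frame(
    month = rep(seq_len(config$horizon_months), ncol(busy)),
    pool = rep(colnames(busy), each = nrow(busy)),
    busy = as.vector(busy), available = as.vector(avail),
    stringsAsFactors = FALSE
  )
  structure(list(visits = visits, resource_months = rm_df,
                 report_months = config$warmup_months +
                   seq_len(config$report_months),
                 start = config$start, rep = rep),
            class = "simulation_trace")
}

empty_trace <- function(config, avail, rep) {
  v <- data.frame(patient_id = character(0), condition = character(0),
                  visit_type = character(0), venue = character(0),
                  due = integer(0), year = integer(0), booked = integer(0),
                  service_day = integer(0), outcome = character(0),
                  rebooked = logical(0), month = integer(0),
                  stringsAsFactors = FALSE)
  busy <- matrix(0, config$horizon_months, length(config$resources$pools),
                 dimnames = list(NULL, config$resources$pools))
  new_trace(v, busy, avail, config, rep)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result: ", x$report$scenario, ", ",
      x$report$replications, " replication(s)>\n", sep = "")
  print(x$report)
  invisible(x)
}
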