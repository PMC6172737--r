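#' Reference calibration values for a mid-size English hospital retinal service
#'
#' The package ships the published service-evaluation figures of a mid-size
#' NHS hospital retinal service (about 500,000 population served, 36 months
#' of patient-level data, April 2013 -- March 2016) that its defaults are
#' calibrated to:
#'
#' * `ref_case_mix()`: share of attending patients by condition
#'   (17.2% AMD, 42.3% DR, 40.5% MR).
#' * `ref_activity_counts()`: attended appointments by activity category and
#'   condition over the 36 months (22,129 in total; lasers were not part of
#'   the AMD pathway).
#' * `ref_discharge_counts()`: patients discharged at the end of care years
#'   1--3, split by condition and by in-treatment vs observation-only status
#'   (75 in-treatment, 1,249 observation, 1,324 of a 6,530-patient cohort).
#' * `ref_monthly_averages()`: reported monthly-average KPIs of four service
#'   configurations (current PRN service; virtual clinic; treat-and-extend;
#'   virtual clinic + treat-and-extend) together with the reported percentage
#'   change between the first and last.
#' * `ref_event_means()`: average injections and follow-up assessments per
#'   patient-year by condition and care year.
#' * `ref_eligible_virtual()`: number of observation-only patients eligible
#'   for diversion to a nurse-led virtual clinic at the end of the window.
#'
#' @return Numeric vectors, matrices or arrays as described.
#' @export
ref_case_mix <- function() c(AMD = 0.172, DR = 0.423, MR = 0.405)

#' @rdname ref_case_mix
#' @export
ref_activity_counts <- function() {
  m <- rbind(
    injection      = c(3295, 425, 743),
    injection_fu   = c(4851, 599, 955),
    laser          = c(0,    315, 63),
    laser_fu       = c(0,    848, 191),
    observation_fu = c(1208, 4790, 3846)
  )
  colnames(m) <- conditions()
  m
}

#' @rdname ref_case_mix
#' @export
ref_discharge_counts <- function() {
  a <- array(
    0L,
    dim = c(3L, 2L, 3L),
    dimnames = list(condition = conditions(),
                    status = c("treated", "observation"),
                    year = as.character(1:3))
  )
  a[, "treated", "1"]     <- c(12L, 1L, 13L)
  a[, "observation", "1"] <- c(147L, 330L, 611L)
  a[, "treated", "2"]     <- c(16L, 5L, 13L)
  a[, "observation", "2"] <- c(14L, 32L, 58L)
  a[, "treated", "3"]     <- c(10L, 1L, 4L)
  a[, "observation", "3"] <- c(10L, 24L, 23L)
  a
}

#' @rdname ref_case_mix
#' @export
ref_cohort_size <- function() 6530L

#' @rdname ref_case_mix
#' @export
ref_eligible_virtual <- function() 894L

#' @rdname ref_case_mix
#' @export
ref_monthly_averages <- function() {
  m <- cbind(
    current_service                 = c(119, 726, 0.71, 0.71, 0.53, 0.29, 169, 151760, 207494, 55735),
    virtual_clinic                  = c(119, 642, 0.64, 0.65, 0.48, 0.30, 172, 153963, 207494, 53532),
    treat_and_extend                = c(119, 812, 0.85, 0.82, 0.55, 0.40, 218, 192902, 260809, 67906),
    virtual_clinic_treat_and_extend = c(119, 708, 0.71, 0.70, 0.51, 0.37, 215, 190200, 251664, 61464)
  )
  rownames(m) <- c("new_attendances", "followups",
                   "utilisation_clinic_session", "utilisation_nurse",
                   "utilisation_consultation_room", "utilisation_injection_bed",
                   "n_injections", "costing", "revenue", "surplus")
  attr(m, "pct_change") <- c(new_attendances = 0, followups = -2,
                             utilisation_clinic_session = 0,
                             utilisation_nurse = -1,
                             utilisation_consultation_room = -4,
                             utilisation_injection_bed = 28,
                             n_injections = 27, costing = 25,
                             revenue = 21, surplus = 10)
  m
}

#' @rdname ref_case_mix
#' @export
ref_event_means <- function() {
  a <- array(
    c(4, 3, 2.5,     3.5, 2.6, 2.6,   4, 2.8, 2.4,    # injections
      4.8, 4, 3.6,   3.3, 3.1, 3.6,   3.7, 3.1, 2.5,  # FU, injected patients
      1.7, 1.6, 1.4, 1.4, 1.4, 1.2,   1.4, 1.4, 1.1), # FU, observation only
    dim = c(3L, 3L, 3L),
    dimnames = list(year = as.character(1:3), condition = conditions(),
                    category = c("injection", "injection_fu", "observation_fu"))
  )
  aperm(a, c(2L, 1L, 3L))
}

#' Reference per-condition patient split
#'
#' The discharge table reports treated vs observation patients only in
#' aggregate, so the per-condition split used to build the calibrated
#' synthetic cohort is derived: injection patients absorb the condition's
#' injections at about 3 per active patient-year (never fewer than the
#' in-treatment discharges), laser-only patients absorb lasers at about 2
#' per year, and the remainder are observation-only.
#'
#' @param n_patients cohort size to split (default the reference 6,530).
#' @param mix case-mix proportions over conditions.
#' @param counts activity counts matrix as [ref_activity_counts()].
#' @param discharges discharge array as [ref_discharge_counts()].
#' @return data.frame with one row per condition: `n`, `injection`, `laser`,
#'   `observation` patient counts.
#' @export
ref_patient_split <- function(n_patients = ref_cohort_size(),
                              mix = ref_case_mix(),
                              counts = ref_activity_counts(),
                              discharges = ref_discharge_counts()) {
  n_c <- allocate_integer(n_patients, mix)
  out <- data.frame(condition = conditions(), n = n_c,
                    injection = 0L, laser = 0L, observation = 0L,
                    row.names = conditions())
  for (c in conditions()) {
    d_tr <- sum(discharges[c, "treated", ])
    t_inj <- counts["injection", c]
    t_las <- counts["laser", c]
    n_inj <- if (t_inj > 0) max(d_tr, ceiling(t_inj / 9)) else 0L
    n_las <- if (t_las > 0) ceiling(t_las / 6) else 0L
    if (t_inj == 0 && d_tr > 0) n_las <- max(n_las, d_tr)
    out[c, "injection"] <- as.integer(n_inj)
    out[c, "laser"] <- as.integer(n_las)
    out[c, "observation"] <- out[c, "n"] - n_inj - n_las
  }
  out
}

# exact integer allocation of n over proportions p (largest remainder)
allocate_integer <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}
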