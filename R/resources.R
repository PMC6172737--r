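#' Clinic resource pools, visit durations and tariffs
#'
#' A visit seizes each required resource pool for its full duration; monthly
#' utilisation of a pool is busy minutes divided by scheduled available
#' minutes. Virtual follow-ups consume virtual-clinic capacity plus a small
#' configurable amount of nurse time instead of clinic session and
#' consultation room time.
#'
#' The reference service's staffing, session templates and visit durations
#' are not published; the defaults here are ASSUMED values at the scale of a
#' mid-size hospital retinal service (Monday--Friday sessions, slot
#' capacities consistent with the pool minutes so that booked activity can
#' never exceed scheduled availability). Sensitivity to them belongs in
#' scenario configs, not in code edits.
#'
#' @param minutes_per_visit numeric matrix pools x `visit_types()` of minutes
#'   seized per visit.
#' @param daily_minutes numeric matrix pools x 7 (Monday first) of scheduled
#'   minutes per weekday.
#' @return `service_resources()` returns a `service_resources` list.
#' @export
service_resources <- function(minutes_per_visit = NULL, daily_minutes = NULL) {
  pools <- c("clinic_session", "nurse", "consultation_room", "injection_bed",
             "virtual_capacity")
  if (is.null(minutes_per_visit)) {
    minutes_per_visit <- rbind(
      clinic_session    = c(30, 30, 20, 30, 20, 15, 0),
      nurse             = c(20, 30, 15, 20, 15, 10, 5),
      consultation_room = c(30, 0, 20, 30, 20, 15, 0),
      injection_bed     = c(0, 20, 0, 0, 0, 0, 0),
      virtual_capacity  = c(0, 0, 0, 0, 0, 0, 15)
    )
    colnames(minutes_per_visit) <- visit_types()
  }
  if (is.null(daily_minutes)) {
    wk <- function(x) c(rep(x, 5), 0, 0)
    daily_minutes <- rbind(
      clinic_session = wk(960), nurse = wk(1200), consultation_room = wk(960),
      injection_bed = wk(640), virtual_capacity = wk(300)
    )
  }
  stopifnot(identical(rownames(minutes_per_visit), pools),
            identical(colnames(minutes_per_visit), visit_types()),
            all(minutes_per_visit >= 0),
            identical(rownames(daily_minutes), pools),
            ncol(daily_minutes) == 7L, all(daily_minutes >= 0))
  structure(list(pools = pools, minutes_per_visit = minutes_per_visit,
                 daily_minutes = daily_minutes),
            class = "service_resources")
}

#' Visit tariffs and costs
#'
#' Revenue and cost per attended visit in GBP. Two figures are published for
#' the reference service: a hospital outpatient follow-up assessment costs
#' around 89 GBP, and the same visit in a virtual clinic 30--45 GBP (the
#' default takes the midpoint, 37.50). All other entries are documented
#' placeholder defaults at the scale of the reference service's reported
#' monthly finances; override them with local figures for real use.
#'
#' @param virtual_fu_cost virtual follow-up cost, constrained to 30--45 GBP.
#' @param revenue_per_visit,cost_per_visit named vectors over
#'   `visit_types()` (GBP per attended visit).
#' @return A `tariff_table`.
#' @export
tariff_table <- function(virtual_fu_cost = 37.5,
                         revenue_per_visit = NULL, cost_per_visit = NULL) {
  stopifnot(virtual_fu_cost >= 30, virtual_fu_cost <= 45)
  if (is.null(revenue_per_visit))
    revenue_per_visit <- c(new_referral = 150, injection = 740,
                           injection_fu = 89, laser = 200, laser_fu = 89,
                           observation_fu = 89, virtual_fu = 89)
  if (is.null(cost_per_visit))
    cost_per_visit <- c(new_referral = 120, injection = 431,
                        injection_fu = 89, laser = 150, laser_fu = 89,
                        observation_fu = 89, virtual_fu = virtual_fu_cost)
  cost_per_visit["virtual_fu"] <- virtual_fu_cost
  stopifnot(identical(sort(names(revenue_per_visit)), sort(visit_types())),
            identical(sort(names(cost_per_visit)), sort(visit_types())),
            all(revenue_per_visit >= 0), all(cost_per_visit >= 0))
  structure(list(revenue_per_visit = revenue_per_visit[visit_types()],
                 cost_per_visit = cost_per_visit[visit_types()],
                 virtual_fu_cost = virtual_fu_cost),
            class = "tariff_table")
}
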