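#' Treatment regimen specifications
#'
#' A regimen fixes, for each care year, the distribution of the number of
#' injections and of standalone follow-up assessments per patient-year
#' (year-3 entries apply to all later years). Two regimens ship as
#' defaults:
#'
#' * `PRN` (pro re nata): treat only on signs of activity. Mean injections
#'   4 / 3 / 2.5 in years 1 / 2 / 3, with follow-up assessments booked
#'   separately (`combined_assessment = FALSE`).
#' * `TE` (treat-and-extend): treat at every visit with interval extension
#'   on stability. Mean injections 8 / 6 / 5; each injection visit subsumes
#'   an assessment (`combined_assessment = TRUE`), so only the follow-up
#'   draw in excess of the injection count produces standalone visits.
#'
#' Published figures give yearly means only; the spread of the default count
#' distributions (coefficient of variation 0.5 for injections, 0.3 for
#' follow-ups) is an assumption, bounded to the observed 1--14 events per
#' patient-year. Observation-only patients draw their monitoring visits from
#' `obs_fus_per_year` (log-normal, natural-scale mean 1.7 / 1.6 / 1.4).
#'
#' @param name `"PRN"` or `"TE"`.
#' @param injections_per_year,fus_per_year,obs_fus_per_year lists of three
#'   [count_distribution()]s (years 1--3).
#' @param combined_assessment does an injection visit include the follow-up
#'   assessment?
#' @return A `regimen_spec`.
#' @export
regimen_spec <- function(name = c("PRN", "TE"),
                         injections_per_year = NULL,
                         fus_per_year = NULL,
                         obs_fus_per_year = NULL,
                         combined_assessment = NULL) {
  name <- match.arg(name)
  inj_means <- if (name == "PRN") c(4, 3, 2.5) else c(8, 6, 5)
  if (is.null(injections_per_year))
    injections_per_year <- lapply(inj_means, function(m)
      count_distribution(m, 0.5 * m))
  if (is.null(fus_per_year))
    fus_per_year <- lapply(c(4.8, 4, 3.6), function(m)
      count_distribution(m, 0.3 * m))
  if (is.null(obs_fus_per_year))
    obs_fus_per_year <- list(count_distribution(1.7, 0.45),
                             count_distribution(1.6, 0.42),
                             count_distribution(1.4, 0.37))
  if (is.null(combined_assessment)) combined_assessment <- name == "TE"
  stopifnot(length(injections_per_year) == 3L, length(fus_per_year) == 3L,
            length(obs_fus_per_year) == 3L)
  structure(list(name = name,
                 injections_per_year = injections_per_year,
                 fus_per_year = fus_per_year,
                 obs_fus_per_year = obs_fus_per_year,
                 combined_assessment = isTRUE(combined_assessment)),
            class = "regimen_spec")
}

#' Plan one care year of due visits for a patient
#'
#' Draws the year's injection and follow-up counts from the regimen's
#' distributions (via inverse-CDF on supplied or freshly drawn uniforms, so
#' paired scenarios can share randomness) and spreads the due dates evenly
#' over the year. Under a combined-assessment regimen, follow-up assessments
#' coincide with injection visits and only the surplus of the follow-up draw
#' over the injection draw is booked as standalone visits.
#'
#' @param patient list with at least `treated` (logical); untreated patients
#'   draw observation follow-ups only.
#' @param regimen a [regimen_spec()].
#' @param year care year (1, 2, 3, ...; capped at 3 for the distributions).
#' @param u optional two uniforms (injection draw, follow-up draw).
#' @return data.frame of due visits: `offset` (days from the year start,
#'   0-based) and `visit_type`.
#' @export
plan_care_year <- function(patient, regimen, year, u = NULL) {
  stopifnot(inherits(regimen, "regimen_spec"), year >= 1)
  y <- min(as.integer(year), 3L)
  if (is.null(u)) u <- runif(2L)
  treated <- isTRUE(patient$treated)
  if (treated) {
    n_inj <- q_count(u[1], regimen$injections_per_year[[y]])
    n_fu <- q_count(u[2], regimen$fus_per_year[[y]])
    if (regimen$combined_assessment) n_fu <- max(0L, n_fu - n_inj)
    fu_type <- "injection_fu"
  } else {
    n_inj <- 0L
    n_fu <- q_count(u[2], regimen$obs_fus_per_year[[y]])
    fu_type <- "observation_fu"
  }
  offset <- function(k) if (k == 0L) numeric(0) else
    round((seq_len(k) - 0.5) / k * 365)
  data.frame(
    offset = as.integer(c(offset(n_inj), offset(n_fu))),
    visit_type = rep(c("injection", fu_type), c(n_inj, n_fu)),
    stringsAsFactors = FALSE
  )
}
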