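#' Condition and visit-type vocabularies
#'
#' The pathway distinguishes three pooled conditions and seven visit types.
#' `MR` ("medical retina") pools retinal vein occlusion with other
#' non-AMD/DR conditions. `virtual_fu` only arises in scenarios with an
#' active virtual clinic; the five "activity" categories are the ones that
#' appear in an attended-activity breakdown of a hospital service.
#'
#' @return Character vectors of the closed label sets.
#' @export
conditions <- function() c("AMD", "DR", "MR")

#' @rdname conditions
#' @export
visit_types <- function() {
  c("new_referral", "injection", "injection_fu", "laser", "laser_fu",
    "observation_fu", "virtual_fu")
}

#' @rdname conditions
#' @export
activity_categories <- function() {
  c("injection", "injection_fu", "laser", "laser_fu", "observation_fu")
}

#' @rdname conditions
#' @export
visit_statuses <- function() c("attended", "dna", "cancelled")

treatment_types <- function() c("injection", "laser")

# rank used for deterministic event tie-breaking
visit_type_rank <- function(type) match(type, visit_types())

assert_condition <- function(x) {
  bad <- setdiff(unique(x), conditions())
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

assert_visit_type <- function(x) {
  bad <- setdiff(unique(x), visit_types())
  if (length(bad)) stop("unknown visit type(s): ", paste(bad, collapse = ", "))
  invisible(x)
}
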