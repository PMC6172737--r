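# Fixtures are generated in code; the full reference cohort is cached for
# the session because several files use it.

ref_fixture <- local({
  cache <- NULL
  function(seed = 1L) {
    if (is.null(cache)) cache <<- generate_cohort(ref_cohort_spec(seed = seed))
    cache
  }
})

# a small cohort with the same structural features as the reference one
mini_spec <- function(seed = 42L, eligible = 5L) {
  counts <- rbind(
    injection      = c(60, 20, 20),
    injection_fu   = c(80, 30, 30),
    laser          = c(0, 12, 6),
    laser_fu       = c(0, 20, 10),
    observation_fu = c(30, 80, 80)
  )
  colnames(counts) <- conditions()
  disc <- array(0L, c(3, 2, 3),
                dimnames = list(conditions(), c("treated", "observation"),
                                as.character(1:3)))
  disc["AMD", "treated", "1"] <- 1L
  disc["AMD", "observation", "1"] <- 2L
  disc["AMD", "observation", "2"] <- 1L
  disc["DR", "observation", "1"] <- 3L
  disc["MR", "treated", "2"] <- 1L
  disc["MR", "observation", "1"] <- 3L
  cohort_spec(n_patients = 100L, mix = c(AMD = 0.2, DR = 0.4, MR = 0.4),
              category_counts = counts, discharge_counts = disc,
              eligible_planted = eligible, seed = seed)
}

# brute-force earliest-free-slot assignment (no attendance failure)
oracle_book <- function(due, slots) {
  free <- as.integer(slots)
  out <- rep(NA_integer_, length(due))
  for (i in seq_along(due)) {
    cand <- which(free > 0L & seq_along(free) >= due[i])
    if (length(cand)) {
      out[i] <- cand[1]
      free[cand[1]] <- free[cand[1]] - 1L
    }
  }
  out
}

# naive per-patient double-loop eligibility filter
oracle_eligible <- function(records, as_of = attr(records, "as_of")) {
  lo24 <- retinasim:::months_before(as_of, 24L)
  lo6 <- retinasim:::months_before(as_of, 6L)
  out <- character(0)
  for (id in unique(records$patient_id)) {
    v <- records[records$patient_id == id, ]
    att <- v[v$status == "attended" & v$visit_date <= as_of, ]
    if (nrow(att) == 0L) next
    if (any(!is.na(v$discharged_year))) next
    if (!any(att$visit_date > lo24)) next
    tr <- att[att$visit_type %in% c("injection", "laser"), ]
    if (nrow(tr) && any(tr$visit_date > lo6)) next
    out <- c(out, id)
  }
  sort(out)
}

# small scenario shared by engine tests
small_config <- function(..., seed = 11L) {
  scenario_config(prevalent = list(n = 150L), horizon_months = 15L,
                  replications = 2L, seed = seed, ...)
}
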