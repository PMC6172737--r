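#' Specify a synthetic cohort of retinal-service patients
#'
#' A cohort specification fixes everything the generator must reproduce
#' *exactly*: the number of patients and their case mix, the attended
#' appointment count for every activity category and condition, the number
#' of patients discharged per condition, treatment status and care year, and
#' the number of patients planted as virtual-clinic eligible at the end of
#' the observation window. Only visit dates and which patient receives which
#' count are random; all totals are allocated, not sampled.
#'
#' @param n_patients number of attending patients.
#' @param mix named probability triple over `conditions()`; must sum to 1.
#' @param category_counts integer matrix `activity_categories()` x
#'   `conditions()` of attended appointment counts.
#' @param discharge_counts integer array condition x status
#'   (`treated`, `observation`) x year (1--3) of discharged patients, as
#'   [ref_discharge_counts()].
#' @param eligible_planted number of patients constructed to satisfy the
#'   virtual-clinic eligibility predicate at the window end (attended within
#'   24 months, no treatment within 6 months, not discharged).
#' @param window_months length of the observation window (default 36).
#' @param window_start first day of the window.
#' @param dna_rate,cancel_rate per-appointment probabilities of an extra
#'   did-not-attend / cancelled booking row. No such rates are published for
#'   the reference service; the defaults are assumptions, present only so
#'   that rebooking logic can be exercised.
#' @param seed integer seed making the generated records reproducible.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [ref_cohort_spec()]
#' @export
cohort_spec <- function(n_patients, mix, category_counts, discharge_counts,
                        eligible_planted = 0L, window_months = 36L,
                        window_start = as.Date("2013-04-01"),
                        dna_rate = 0.05, cancel_rate = 0.03, seed = 1L) {
  stopifnot(n_patients >= 0, window_months >= 1)
  if (abs(sum(mix) - 1) > 1e-9) stop("case mix must sum to 1")
  if (is.null(names(mix))) names(mix) <- conditions()
  stopifnot(identical(sort(names(mix)), sort(conditions())))
  mix <- mix[conditions()]
  cc <- as.matrix(category_counts)
  stopifnot(identical(rownames(cc), activity_categories()),
            identical(colnames(cc), conditions()),
            all(cc >= 0), all(cc == round(cc)))
  dc <- discharge_counts
  stopifnot(length(dim(dc)) == 3L, all(dim(dc) == c(3L, 2L, 3L)),
            all(dc >= 0), all(dc == round(dc)))
  storage.mode(dc) <- "integer"
  dimnames(dc) <- list(condition = conditions(),
                       status = c("treated", "observation"),
                       year = as.character(1:3))
  if (eligible_planted > n_patients)
    stop("eligible_planted exceeds n_patients")
  stopifnot(dna_rate >= 0, dna_rate < 1, cancel_rate >= 0, cancel_rate < 1)
  structure(
    list(n_patients = as.integer(n_patients), mix = mix,
         category_counts = cc, discharge_counts = dc,
         eligible_planted = as.integer(eligible_planted),
         window_months = as.integer(window_months),
         window_start = as.Date(window_start),
         dna_rate = dna_rate, cancel_rate = cancel_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @details `ref_cohort_spec()` is the specification calibrated cell-by-cell
#'   to the reference service: 6,530 patients, the published activity and
#'   discharge tables, and 894 planted virtual-clinic-eligible patients over
#'   a 36-month window.
#' @export
ref_cohort_spec <- function(seed = 1L) {
  cohort_spec(
    n_patients = ref_cohort_size(),
    mix = ref_case_mix(),
    category_counts = ref_activity_counts(),
    discharge_counts = ref_discharge_counts(),
    eligible_planted = ref_eligible_virtual(),
    window_months = 36L,
    seed = seed
  )
}

# exact allocation of `total` units over slots with per-slot minima and caps;
# randomness only decides which slots receive the surplus
allocate_counts <- function(total, mins, caps) {
  n <- length(mins)
  if (n == 0L) {
    if (total != 0) stop("infeasible allocation: ", total, " events but no slots")
    return(integer(0))
  }
  if (total < sum(mins) || total > sum(caps))
    stop("infeasible allocation: ", total, " events over ", n,
         " patient-year slots (feasible range ", sum(mins), "--", sum(caps), ")")
  x <- as.integer(mins)
  rem <- as.integer(total - sum(mins))
  while (rem > 0L) {
    open <- which(x < caps)
    take <- if (length(open) > rem) sample(open, rem) else open
    x[take] <- x[take] + 1L
    rem <- rem - length(take)
  }
  x
}

# k day positions evenly spread over [d0, d1] with +/- jitter days of noise
spread_days <- function(k, d0, d1, jitter = 7L) {
  if (k == 0L) return(integer(0))
  span <- d1 - d0 + 1L
  pos <- d0 + (seq_len(k) - 0.5) / k * span
  pos <- pos + runif(k, -jitter, jitter)
  sort(as.integer(pmin(pmax(round(pos), d0), d1)))
}

#' Generate synthetic patient-level visit records
#'
#' Builds a cohort matching `spec` exactly: per-category attended totals,
#' per-cell discharge counts and the planted eligible count are reproduced
#' without sampling error; dates and per-patient count assignments are the
#' only random elements, so two runs with the same seed are identical.
#'
#' Within a patient-year, treatment visits are spread at regular intervals
#' with +/-7 days of uniform jitter; per-year injections are capped at 13 so
#' that no rolling 12-month span can exceed 14. Every non-discharged treated
#' patient receives a treatment visit inside the final 6 months of the
#' window, and every non-planted, non-discharged observation patient attends
#' only in the first 12 months, so that the virtual-clinic eligibility
#' predicate identifies exactly the planted set.
#'
#' @param spec a [cohort_spec()].
#' @return A `retinal_records` data.frame with one row per visit and columns
#'   `patient_id`, `condition`, `visit_date`, `visit_type`, `status`,
#'   `discharged_year`, plus attributes `window_start`, `window_months`,
#'   `as_of` and `planted_eligible` (the planted patient ids).
#' @examples
#' spec <- cohort_spec(
#'   n_patients = 2, mix = c(AMD = 1, DR = 0, MR = 0),
#'   category_counts = matrix(c(4, 4, 0, 0, 2), 5, 3,
#'     dimnames = list(activity_categories(), conditions())),
#'   discharge_counts = array(0, c(3, 2, 3)),
#'   seed = 7)
#' generate_cohort(spec)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  start <- spec$window_start
  W <- spec$window_months
  as_of <- month_end(W, start)
  # month boundaries as day offsets from window start
  msd <- vapply(seq_len(W + 1L), function(m) {
    as.integer(month_start(m, start) - start)
  }, integer(1))
  mend <- function(m) msd[m + 1L] - 1L

  if (spec$n_patients == 0L) {
    if (sum(spec$category_counts) != 0)
      stop("infeasible spec: activity counts but no patients")
    return(new_records(empty_record_frame(), start, W, character(0)))
  }
  for (cond in conditions()) {
    cc <- spec$category_counts[, cond]
    if (cc["injection"] == 0 && cc["injection_fu"] > 0)
      stop("infeasible spec: injection follow-ups without injections for ", cond)
    if (cc["laser"] == 0 && cc["laser_fu"] > 0)
      stop("infeasible spec: laser follow-ups without lasers for ", cond)
  }

  split <- ref_patient_split(spec$n_patients, spec$mix,
                             spec$category_counts, spec$discharge_counts)
  if (any(split$observation < 0))
    stop("infeasible spec: treated patients required for the activity counts ",
         "exceed the cohort size for ",
         paste(split$condition[split$observation < 0], collapse = ", "))

  # planted eligible patients drawn from non-discharged observation patients
  d_obs <- apply(spec$discharge_counts[, "observation", , drop = FALSE], 1, sum)
  avail <- split$observation - d_obs
  if (any(avail < 0))
    stop("infeasible spec: observation discharges exceed observation patients")
  if (spec$eligible_planted > sum(avail))
    stop("infeasible spec: only ", sum(avail), " non-discharged observation ",
         "patients available for ", spec$eligible_planted, " planted eligible")
  if (spec$eligible_planted < sum(avail) && W <= 24L)
    stop("infeasible spec: with a window of ", W, " months every attending ",
         "non-discharged observation patient is eligible")
  planted_c <- if (sum(avail) > 0)
    allocate_integer(spec$eligible_planted, avail / sum(avail))
  else stats::setNames(integer(3), conditions())
  over <- planted_c > avail
  while (any(over)) { # largest-remainder repair against per-condition limits
    excess <- sum(planted_c[over] - avail[over])
    planted_c[over] <- avail[over]
    slack <- which(planted_c < avail)
    planted_c[slack[seq_len(excess)]] <- planted_c[slack[seq_len(excess)]] + 1L
    over <- planted_c > avail
  }

  pid_counter <- 0L
  next_ids <- function(n) {
    ids <- sprintf("P%05d", pid_counter + seq_len(n))
    pid_counter <<- pid_counter + n
    ids
  }
  visits <- list()
  planted_ids <- character(0)

  for (cond in conditions()) {
    cc <- spec$category_counts[, cond]
    d_tr <- spec$discharge_counts[cond, "treated", ]
    d_ob <- spec$discharge_counts[cond, "observation", ]
    n_inj <- split[cond, "injection"]
    n_las <- split[cond, "laser"]
    n_obs <- split[cond, "observation"]
    # in-treatment discharges live with injection patients when there are any
    inj_d <- if (n_inj > 0) d_tr else c(0L, 0L, 0L)
    las_d <- if (n_inj > 0) c(0L, 0L, 0L) else d_tr
    if (sum(d_tr) > 0 && n_inj + n_las == 0)
      stop("infeasible spec: in-treatment discharges for ", cond,
           " but no treated patients")

    if (n_inj > 0) {
      g <- build_treated_group(next_ids(n_inj), cond, cc["injection"],
                               cc["injection_fu"], "injection", "injection_fu",
                               inj_d, msd, mend, W)
      visits[[length(visits) + 1L]] <- g
    }
    if (n_las > 0) {
      g <- build_treated_group(next_ids(n_las), cond, cc["laser"],
                               cc["laser_fu"], "laser", "laser_fu",
                               las_d, msd, mend, W)
      visits[[length(visits) + 1L]] <- g
    }
    if (n_obs > 0 || cc["observation_fu"] > 0) {
      g <- build_observation_group(next_ids(n_obs), cond,
                                   cc["observation_fu"], d_ob,
                                   planted_c[cond], msd, mend, W)
      visits[[length(visits) + 1L]] <- g$visits
      planted_ids <- c(planted_ids, g$planted)
    }
  }

  out <- do.call(rbind, visits)
  if (is.null(out) || nrow(out) == 0L)
    return(new_records(empty_record_frame(), start, W, planted_ids))

  # extra non-attended booking rows at the configured (assumed) rates
  if (nrow(out) > 0 && (spec$dna_rate > 0 || spec$cancel_rate > 0)) {
    extra <- list()
    for (st in c("dna", "cancelled")) {
      rate <- if (st == "dna") spec$dna_rate else spec$cancel_rate
      hit <- which(runif(nrow(out)) < rate)
      if (length(hit)) {
        e <- out[hit, ]
        e$day <- pmax(0L, e$day - sample(1:14, length(hit), replace = TRUE))
        e$status <- st
        extra[[st]] <- e
      }
    }
    out <- rbind(out, do.call(rbind, extra))
  }

  out <- out[order(out$patient_id, out$day, visit_type_rank(out$visit_type)), ]
  df <- data.frame(
    patient_id = out$patient_id,
    condition = out$condition,
    visit_date = start + out$day,
    visit_type = out$visit_type,
    status = out$status,
    discharged_year = out$discharged_year,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  new_records(df, start, W, planted_ids)
}

empty_visits <- function() {
  data.frame(patient_id = character(0), condition = character(0),
             day = integer(0), visit_type = character(0),
             status = character(0), discharged_year = integer(0),
             stringsAsFactors = FALSE)
}

empty_record_frame <- function() {
  data.frame(patient_id = character(0), condition = character(0),
             visit_date = as.Date(character(0)), visit_type = character(0),
             status = character(0), discharged_year = integer(0),
             stringsAsFactors = FALSE)
}

new_records <- function(df, window_start, window_months, planted = NULL) {
  structure(df,
            window_start = as.Date(window_start),
            window_months = as.integer(window_months),
            as_of = month_end(window_months, window_start),
            planted_eligible = planted,
            class = c("retinal_records", "data.frame"))
}

# treated patients: allocate main treatment and its follow-up assessments
# over active patient-year slots; every non-discharged patient's last
# treatment is relocated into the final 6 months of the window
build_treated_group <- function(ids, cond, t_main, t_fu, main_type, fu_type,
                                d_years, msd, mend, W) {
  n <- length(ids)
  dy <- rep(c(1L, 2L, 3L, NA_integer_),
            c(d_years[1], d_years[2], d_years[3], n - sum(d_years)))
  dy <- dy[sample.int(n)]
  s0max <- max(1L, min(4L, W - 24L))
  s0 <- sample.int(s0max, n, replace = TRUE)
  active <- ifelse(is.na(dy), 3L, dy)
  avail <- pmin(active, (W - s0) %/% 12L + 1L)

  slot_pat <- rep(seq_len(n), avail)
  slot_year <- unlist(lapply(avail, seq_len))
  mins <- as.integer(slot_year == 1L)
  k_main <- allocate_counts(t_main, mins, rep(13L, length(mins)))
  k_fu <- allocate_counts(t_fu, rep(0L, length(mins)), rep(30L, length(mins)))

  # relocate one treatment per active patient into the final 6 months, so a
  # treated, non-discharged patient can never satisfy the eligibility filter
  for (i in which(is.na(dy))) {
    s <- which(slot_pat == i & k_main > 0)
    s <- s[length(s)]
    k_main[s] <- k_main[s] - 1L
  }

  rows <- vector("list", length(slot_pat) + 1L)
  for (s in seq_along(slot_pat)) {
    if (k_main[s] == 0L && k_fu[s] == 0L) next
    i <- slot_pat[s]
    j <- slot_year[s]
    d0 <- msd[s0[i] + 12L * (j - 1L)]
    d1 <- min(mend(min(s0[i] + 12L * j - 1L, W)), mend(W))
    kd <- spread_days(k_main[s], d0, d1)
    kf <- spread_days(k_fu[s], d0, d1)
    rows[[s]] <- data.frame(
      patient_id = ids[i], condition = cond,
      day = c(kd, kf),
      visit_type = rep(c(main_type, fu_type), c(length(kd), length(kf))),
      status = "attended", discharged_year = dy[i],
      stringsAsFactors = FALSE
    )
  }
  act <- which(is.na(dy))
  if (length(act)) {
    d0 <- msd[max(1L, W - 5L)]
    rows[[length(slot_pat) + 1L]] <- data.frame(
      patient_id = ids[act], condition = cond,
      day = d0 + sample.int(mend(W) - d0 + 1L, length(act), replace = TRUE) - 1L,
      visit_type = main_type, status = "attended",
      discharged_year = NA_integer_, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# observation-only patients: discharged patients attend across their active
# years; planted-eligible patients attend inside the final year with at least
# one visit in the final 6 months; everyone else attends only inside the
# first 12 months (hence outside the 24-month eligibility lookback)
build_observation_group <- function(ids, cond, t_obs, d_years, n_planted,
                                    msd, mend, W) {
  n <- length(ids)
  if (n == 0L) {
    if (t_obs > 0) stop("infeasible spec: observation visits for ", cond,
                        " but no observation patients")
    return(list(visits = empty_visits(), planted = character(0)))
  }
  dy <- rep(c(1L, 2L, 3L, NA_integer_),
            c(d_years[1], d_years[2], d_years[3], n - sum(d_years)))
  free <- which(is.na(dy))
  planted <- rep(FALSE, n)
  planted[free[seq_len(n_planted)]] <- TRUE
  perm <- sample.int(n)
  dy <- dy[perm]; planted <- planted[perm]

  slot_pat <- integer(0); slot_year <- integer(0)
  for (i in seq_len(n)) {
    ny <- if (is.na(dy[i])) 1L else min(dy[i], (W - 1L) %/% 12L + 1L)
    slot_pat <- c(slot_pat, rep(i, ny))
    slot_year <- c(slot_year, seq_len(ny))
  }
  mins <- as.integer(slot_year == 1L)
  k <- allocate_counts(t_obs, mins, rep(13L, length(mins)))

  # non-planted, non-discharged patients attend only before the 24-month
  # eligibility lookback opens
  early_end <- max(1L, W - 24L)
  s0 <- sample.int(max(1L, min(6L, early_end)), n, replace = TRUE)
  rows <- vector("list", length(slot_pat))
  for (s in seq_along(slot_pat)) {
    i <- slot_pat[s]
    j <- slot_year[s]
    if (k[s] == 0L) next
    if (planted[i]) {
      # all visits in the final year, the last one inside the last 6 months
      d_late0 <- msd[max(1L, W - 5L)]
      last <- d_late0 + sample.int(mend(W) - d_late0 + 1L, 1L) - 1L
      rest <- spread_days(k[s] - 1L, msd[max(1L, W - 11L)], mend(W) - 1L)
      days <- sort(c(pmin(rest, last), last))
    } else if (is.na(dy[i])) {
      days <- spread_days(k[s], msd[s0[i]], mend(early_end))
    } else {
      d0 <- msd[min(s0[i] + 12L * (j - 1L), W)]
      d1 <- min(mend(min(s0[i] + 12L * j - 1L, W)), mend(W))
      days <- spread_days(k[s], d0, d1)
    }
    rows[[s]] <- data.frame(
      patient_id = ids[i], condition = cond, day = days,
      visit_type = "observation_fu", status = "attended",
      discharged_year = dy[i], stringsAsFactors = FALSE
    )
  }
  list(visits = do.call(rbind, rows), planted = ids[planted])
}
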