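---
title: "Modelling a hospital retinal injection service with retinasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a hospital retinal injection service with retinasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinasim)
```

## The problem

Medical-retina services treat neovascular age-related macular degeneration
(nAMD), diabetic retinopathy (DR) and other medical retina conditions (MR,
which pools retinal vein occlusion with the remainder) with repeated
intravitreal anti-VEGF injections and long-term monitoring. Visit
frequencies of roughly monthly during active treatment, combined with rising
prevalence, leave many clinics at capacity. Two redesigns dominate the
discussion: the treat-and-extend (T&E) regimen, which injects at every visit
and extends the interval on stability (better outcomes, more injections),
and nurse-led virtual clinics, which move stable monitoring patients out of
consultant clinics at a much lower cost per visit. Spreadsheet models built
on averages mislead here — the "error of averages" — because yearly
injection counts vary widely (1–14 per patient-year) and resources interact
through a booked calendar. `retinasim` therefore simulates individual
patients through the booked pathway.

## Count distributions and their calibration

Yearly event counts are modelled as a log-normal variate rounded to the
nearest integer and clamped to a support, by default 1–14 events per
patient-year, and are parameterised by *natural-scale* moments (events per
patient-year), matching how such figures are reported alongside yearly
averages. Two numerical points deserve care:

* **Rounding shifts the mean.** A log-normal with natural mean 1.4 rounded
  to integers has mean about 1.35. The constructor therefore solves for the
  log-scale location such that the rounded, clamped variate has the
  requested mean exactly (monotone 1-d root solve on the discretised pmf);
  `q_count()` is then the exact inverse CDF of the discrete variate.
* **An integer variate has an sd floor.** At mean 1.4 no integer-valued
  variate can have sd below ~0.49 (the two-point {1,2} mixture), so a
  requested sd of 0.37 is interpreted as the spread of the *underlying*
  continuous log-normal (coefficient of variation preserved) and is
  approximate after discretisation. The mean — which drives workload — is
  exact; the sd is not, and we document rather than hide this.

`fit_count_distribution()` is the inverse operation: a maximum-likelihood
log-normal fit (closed-form log-moment estimates, computed via
`MASS::fitdistr`) on positive integer counts, reporting the natural-scale
sample mean and sd so that fitting draws from a calibrated distribution
recovers its mean. Below 30 observations, or for constant samples, it falls
back to an empirical distribution; we fit on rounded integer counts because
that is what visit records contain.

Regimen defaults use the published yearly means — PRN 4/3/2.5 and T&E 8/6/5
injections in care years 1/2/3 (one source gives "4–5" for T&E year 3; we
take 5, the value given where the redesign is specified, and the
alternative is one constructor argument away). Only means are published, so
the default coefficients of variation (0.5 for injections, 0.3 for
follow-ups) are assumptions bounded by the observed 1–14 range. Observation
follow-up distributions default to natural means 1.7/1.6/1.4 with the
published sd 0.37 at mean 1.4 setting the coefficient of variation.

## The synthetic cohort generator

`generate_cohort()` emulates 36 months of patient-level visit records with
the composition of the reference service: 6,530 patients (17.2/42.3/40.5%
nAMD/DR/MR), the full activity table (22,129 attended appointments), the
discharge table (1,324 discharges by condition, status and year) and 894
virtual-clinic-eligible patients. Totals are *allocated*, not sampled: only
visit dates and the assignment of counts to patients are random, so every
seed reproduces the published cell values exactly. Design choices:

* Within a patient-year, visits sit at regular intervals with ±7 days of
  uniform jitter — smooth monthly workload without inventing seasonality.
* Per-year injections are capped at 13, not 14: with even spacing plus
  jitter, 14 injections in two consecutive years could put 15 into one
  rolling 365-day window, violating the observed 1–14-per-year range.
* The treated/observation split per condition is not published; injection
  patients absorb their condition's injections at ~3 per active
  patient-year (never fewer than the in-treatment discharges), laser-only
  patients at ~2.
* Eligibility is planted constructively: planted patients attend in the
  final six months with no treatment; every other non-discharged
  observation patient attends only before the 24-month lookback opens, and
  every active treated patient receives a treatment visit in the final six
  months. The eligibility filter then provably returns exactly the planted
  set.
* DNA (5%) and cancellation (3%) rows are generated at configurable,
  assumed rates — none are published — solely so rebooking logic can be
  exercised.

What the generator does **not** emulate: seasonality, referral-source
structure, visual-acuity-driven treatment decisions, within-year
autocorrelation of visit intervals, or year-on-year demand growth inside
the window. Tests passing on these fixtures validate the arithmetic and the
pathway logic, not the epidemiology of any real service.

## Calibration conventions

* The patient-year clock starts at each patient's **first attended visit**,
  not a calendar year; years beyond 3 pool into year 3.
* `estimate_discharge()` reports both conventions in circulation: per-year
  at-risk hazards (what a simulation must consume) and cohort shares (the
  convention of printed summary tables, where 75 treated discharges out of
  6,530 patients reads "1%"). The two disagree by construction; the object
  carries both so neither is silently chosen for the reader.
* Eligibility windows are half-open — exclusive at the old end, inclusive
  at the reference day — fixed explicitly because determinism at the
  boundary matters; lookbacks use calendar months with day-of-month
  clamping. A patient whose last attendance sits exactly on the 24-month
  boundary is *not* eligible. We exclude any treatment visit (injection or
  laser) in the 6-month lookback; reading "observation only" as excluding
  injections alone would admit recent laser patients, which we judged
  against the intent.

## Forecasting

The published analysis used an external forecasting package with
unspecified model selection; reproducibility argues for one transparent
method, so `forecast_arrivals()` fits an additive level + linear trend +
calendar-month seasonality model by ordinary least squares (≥ 24 months of
history required), extrapolates, scales month *m* by `(1+g)^(m/12)` for
annual population growth *g*, and floors at zero. The method is linear,
hence scale-equivariant, exact on noise-free level/trend/seasonal input,
and the identity under zero growth — all tested. Accuracy is defined as
100 − MAPE (zero-actual months excluded with a warning), the simplest
reading of a percentage "forecast accuracy". The engine consumes forecasts
as Poisson means — the minimal-assumption arrival process on count data.

## The simulation engine

Each replication builds its population (Poisson arrivals per month and
condition; a prevalent caseload of established patients whose current care
year is already in progress), plans each patient's care years from the
regimen distributions, applies discharge draws at year ends, diverts
eligible patients' monitoring visits to the virtual clinic when one is
active, and books everything into an earliest-free-slot calendar.
Conventions:

* **Event order** is (due date, patient id, visit-type rank) — fixed so
  simultaneous events never depend on storage order.
* **Booking failures**: a DNA or cancellation releases its slot and
  triggers exactly one rebooking attempt within 14 days (assumed); a visit
  that finds no slot before the horizon is recorded as overflow. Every due
  visit therefore appears exactly once as attended, DNA, cancelled or
  overflow.
* **Common random numbers**: every stochastic mechanism draws from a stream
  keyed on (seed, replication, patient), and count draws go through the
  inverse CDF. Paired scenarios that share a seed share randomness, so
  "T&E plans at least as many injections as PRN" holds replication by
  replication (the calibrated T&E quantile dominates the PRN quantile
  pointwise), and enabling the virtual clinic weakly lowers hospital clinic
  load with everything else fixed.
* **Arrival streams**: the engine draws new-patient arrivals from the
  `new` forecast; follow-up demand is generated endogenously by the care
  plans of new and prevalent patients rather than read from the `followup`
  forecast, which serves forecasting and reporting. The prevalent pool is
  therefore an explicit configuration (size, treated share, eligible
  share) rather than something reverse-engineered from a follow-up series.
* **Warm-up**: 3 months are discarded and 12 reported of a 15-month
  horizon, so monthly means are taken from a populated system.

Resource schedules, visit durations, slot capacities and most tariffs are
**not published** for the reference service; the defaults in
`service_resources()`, `booking_system()` and `tariff_table()` are
documented assumptions chosen at the scale of a mid-size service, with slot
capacities consistent with pool minutes so that booked activity can never
exceed scheduled availability (utilisation is structurally within [0, 1]).
Two tariff figures are published and used: a hospital monitoring visit at
about £89 and a virtual one at £30–45 (default: the £37.50 midpoint).
Consequently absolute utilisations and financial levels are
configuration-dependent and are validated as *properties* (bounds,
accounting identity, paired-scenario orderings) rather than reproduced as
absolute values; percentage-change arithmetic between scenario reports is
validated exactly against the published comparison table, including its
half-away-from-zero integer rounding. Under the default configuration T&E
lowers standalone follow-up counts (injection visits subsume assessments);
whether a real service sees follow-ups rise under T&E depends on its T&E
monitoring schedule, which is a configuration choice here.

## Problem sizes

The shipped tests and the acceptance script run at the sizes the method
statements call for where those are cheap — 5,000 draws for the
distribution fit, 10,000 patient-years for regimen means, the full
6,530-patient cohort for calibration arithmetic, 30 replications for the
baseline arrival check — and a scaled prevalent pool (hundreds of patients)
for engine property tests, which is ample for order and identity
properties that hold replication by replication.

## Known limitations

* No intra-day queueing or rostering; lasers share the generic clinic
  resources.
* Discharge is a per-year Bernoulli hazard, not a censoring-adjusted
  survival model.
* Clinical outcomes (visual acuity) are out of scope; the model prices
  visits, it does not value vision.
* New patients are never diverted to the virtual clinic within a run;
  eligibility is assessed for the established caseload.
* The forecast provides point estimates only — no prediction intervals, no
  automatic model selection, single-scalar growth adjustment.
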