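# Patient-level pathway operations: referral admission, follow-up regimen
# sampling, the diagnostics battery and a single attendance. The monthly
# service engine (simulate.R) uses the same draw primitives in vectorised
# form; the functions here are the per-patient surface used for unit-level
# reasoning and tracing.

#' Lognormal draws parameterised by mean and coefficient of variation
#'
#' @param n Number of draws.
#' @param mean Target mean (> 0).
#' @param cv Coefficient of variation (>= 0); `cv = 0` returns the mean
#'   exactly.
#' @return Numeric vector of draws (uses the current RNG state; wrap in
#'   [with_stream()] for substream control).
#' @keywords internal
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Sample a follow-up regimen size
#'
#' Draws the number of follow-up appointments a patient needs in a treatment
#' year: lognormal with the condition/year mean and the configured
#' coefficient of variation, rounded to the nearest integer with floor 1.
#' With `cv = 0` the configured mean (rounded) is returned deterministically.
#'
#' @param profile A condition profile (an element of `params$conditions`).
#' @param year Treatment year, 1 to 3.
#' @param streams Random streams ([rng_streams()]; substream `"regimen"`).
#' @param n Number of draws (default 1).
#' @return Integer vector of regimen sizes, each >= 1.
#' @export
sample_followup_count <- function(profile, year, streams, n = 1L) {
  stopifnot(year %in% 1:3)
  m <- profile$followups_per_year[[year]]
  draws <- with_stream(streams, "regimen",
                       rlnorm_mean_cv(n, m, profile$followup_cv))
  pmax(1L, as.integer(round(draws)))
}

#' Admit a patient
#'
#' New referrals start in treatment year 1; members of the warm-start
#' caseload (patients already mid-treatment when the simulation opens) draw
#' their treatment year from the configured 72/18/10 year mix.
#'
#' @param condition `"AMD"`, `"DR"` or `"RVO"`.
#' @param params A parameter set.
#' @param streams Random streams.
#' @param warm_start Logical; `TRUE` for initial-caseload members.
#' @return A patient record (list) with fields `condition`, `treatment_year`,
#'   `fu_total` (regimen size for the year), `fu_done`, `state`
#'   (`"active"`), `dna_count`, `virtual_eligible`.
#' @export
admit_new_patient <- function(condition, params, streams,
                              warm_start = FALSE) {
  stopifnot(condition %in% CONDITIONS)
  profile <- params$conditions[[condition]]
  year <- if (warm_start) {
    with_stream(streams, "init",
                sample.int(3L, 1L, prob = profile$year_mix))
  } else 1L
  list(condition = condition, treatment_year = year,
       fu_total = sample_followup_count(profile, year, streams),
       fu_done = 0L, state = "active", dna_count = 0L,
       virtual_eligible = FALSE)
}

#' Draw a diagnostics battery
#'
#' Each attendance receives LogMAR and slit-lamp with probability 1 and
#' angiography / OCT with their configured probabilities.
#'
#' @param diag The diagnostics profile (`params$diagnostics`).
#' @param streams Random streams (substream `"routing"`).
#' @param n Number of batteries (default 1).
#' @return Logical matrix `n x 4` with columns `logmar`, `slitlamp`,
#'   `angiography`, `oct`.
#' @export
diagnostics_battery <- function(diag, streams, n = 1L) {
  p <- diag$usage_prob[DIAG_TESTS]
  u <- with_stream(streams, "routing",
                   matrix(stats::runif(n * 4L), n, 4L))
  out <- sweep(u, 2L, p, "<")
  colnames(out) <- DIAG_TESTS
  out
}

#' Draw the treatment delivered at a follow-up attendance
#'
#' Condition-specific categorical draw over injection / laser /
#' photodynamic therapy / best supportive care / none, with a second draw
#' assigning injections to a nurse injector with probability
#' `nurse_injection_share` (the second uniform is always consumed so that
#' scenario runs with share zero remain draw-for-draw aligned with the
#' baseline).
#'
#' @param condition Condition name(s); recycled against `n`.
#' @param params A parameter set.
#' @param streams Random streams (substream `"routing"`).
#' @param nurse_injection_share Fraction of injections performed by nurse
#'   injectors.
#' @param n Number of draws.
#' @return Data frame with columns `treatment` (`"injection"`, `"laser"`,
#'   `"pdt"`, `"bsc"`, `"none"`) and `injector` (`"consultant"`, `"nurse"`
#'   or `NA`).
#' @export
draw_treatment <- function(condition, params, streams,
                           nurse_injection_share = 0, n = length(condition)) {
  condition <- rep_len(condition, n)
  u <- with_stream(streams, "routing", stats::runif(n))
  u2 <- with_stream(streams, "routing", stats::runif(n))
  treatment <- character(n)
  for (cn in unique(condition)) {
    mix <- params$treatment_mix[[cn]]
    br <- cumsum(c(mix[["injection"]], mix[["laser"]], mix[["pdt"]],
                   mix[["bsc"]]))
    idx <- condition == cn
    cat_i <- findInterval(u[idx], c(0, br), rightmost.closed = FALSE)
    treatment[idx] <- c("injection", "laser", "pdt", "bsc", "none")[cat_i]
  }
  injector <- ifelse(treatment == "injection",
                     ifelse(u2 < nurse_injection_share, "nurse",
                            "consultant"),
                     NA_character_)
  data.frame(treatment = treatment, injector = injector,
             stringsAsFactors = FALSE)
}

#' Run a single attendance for a patient
#'
#' With probability `dna_rate` the appointment is missed (outcome `"DNA"`):
#' no diagnostics are done, no resource minutes accrue, and a rebook is
#' implied (up to the configured maximum). Otherwise the patient receives
#' the diagnostics battery and a consultation, a treatment is drawn for
#' follow-up attendances, the remaining-regimen counter decrements, and at
#' the end of a treatment year the discharge / monitoring-transition /
#' advance-year rules apply (year 3 parameters are reused beyond year 3;
#' stable patients enter the `"monitoring"` state and become
#' virtual-eligible).
#'
#' @param patient A patient record from [admit_new_patient()].
#' @param params A parameter set.
#' @param streams Random streams.
#' @param appt_type `"first"` or `"followup"`.
#' @param nurse_injection_share Fraction of injections shifted to nurse
#'   injectors (scenario parameter; 0 at baseline).
#' @return List with the updated `patient` and an `attendance` record
#'   (fields `appt_type`, `outcome` (`"Continue"`, `"Discharge"`, `"DNA"`),
#'   `diagnostics`, `treatment`, `injector`, `staff_minutes` named vector).
#' @export
run_attendance <- function(patient, params, streams, appt_type = "followup",
                           nurse_injection_share = 0) {
  if (patient$state == "discharged") {
    stop("cannot run an attendance for a discharged patient")
  }
  st <- params$service_times
  dna <- with_stream(streams, "dna", stats::runif(1)) < st$dna_rate
  zero_minutes <- stats::setNames(numeric(length(STAFF_ROLES)), STAFF_ROLES)
  if (dna) {
    patient$dna_count <- patient$dna_count + 1L
    return(list(patient = patient,
                attendance = list(appt_type = appt_type, outcome = "DNA",
                                  diagnostics = character(0),
                                  treatment = "none", injector = NA,
                                  staff_minutes = zero_minutes)))
  }
  diag <- diagnostics_battery(params$diagnostics, streams)
  tests <- DIAG_TESTS[diag[1L, ]]
  minutes <- zero_minutes
  for (tst in tests) {
    role <- params$diagnostics$staffing[[tst]]
    minutes[role] <- minutes[role] + params$diagnostics$minutes_per_test[[tst]]
  }
  consult_min <- if (appt_type == "first") st$first_consult_min else
    st$followup_consult_min
  minutes["consultant"] <- minutes["consultant"] + consult_min
  treatment <- "none"; injector <- NA_character_
  if (appt_type == "followup") {
    tr <- draw_treatment(patient$condition, params, streams,
                         nurse_injection_share, n = 1L)
    treatment <- tr$treatment; injector <- tr$injector
    if (treatment == "injection") {
      if (identical(injector, "nurse")) {
        minutes["nurse"] <- minutes["nurse"] + st$injection_nurse_min
      } else {
        minutes["consultant"] <- minutes["consultant"] +
          st$injection_consultant_min
      }
    }
  }
  outcome <- "Continue"
  if (appt_type == "first") {
    patient$fu_done <- 0L
  } else if (patient$state == "active") {
    patient$fu_done <- patient$fu_done + 1L
    if (patient$fu_done >= patient$fu_total) {
      # end of the treatment year
      yr <- min(patient$treatment_year, 3L)
      p_dis <- params$conditions[[patient$condition]]$
        discharge_prob_at_year_end[[yr]]
      p_mon <- params$monitoring$transition_prob
      u <- with_stream(streams, "routing", stats::runif(1))
      if (u < p_dis) {
        patient$state <- "discharged"
        outcome <- "Discharge"
      } else if (u < p_dis + p_mon) {
        patient$state <- "monitoring"
        patient$virtual_eligible <- TRUE
      } else {
        patient$treatment_year <- patient$treatment_year + 1L
        yr_next <- min(patient$treatment_year, 3L)
        patient$fu_total <- sample_followup_count(
          params$conditions[[patient$condition]], yr_next, streams)
        patient$fu_done <- 0L
      }
    }
  }
  patient$dna_count <- 0L
  list(patient = patient,
       attendance = list(appt_type = appt_type, outcome = outcome,
                         diagnostics = tests, treatment = treatment,
                         injector = injector, staff_minutes = minutes))
}
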