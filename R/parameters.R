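# Model configuration: the full input-parameter set consumed by the
# simulator, its validation, and YAML config I/O. Every number the simulator
# uses lives here; nothing numeric is hard-wired in the pathway code.

CONDITIONS <- c("AMD", "DR", "RVO")
STAFF_ROLES <- c("consultant", "photographer", "nurse", "technician",
                 "hca", "optometrist")
DIAG_TESTS <- c("logmar", "slitlamp", "angiography", "oct")
TARIFF_ACTIVITIES <- c("first", "followup", "laser", "pdt", "bsc")

#' Default model configuration
#'
#' Returns the packaged configuration of the retinal-service model: demand
#' forecasts, per-condition follow-up regimens, routing and discharge
#' probabilities, diagnostics usage, staff and equipment counts, hourly staff
#' costs (PSSRU) and national-tariff revenues, together with the service-time
#' and booking-policy values obtained from baseline calibration (see
#' [calibrate_baseline()] and the package vignette).
#'
#' Headline fixed inputs: AMD follow-ups 5/4/4 per treatment year, DR and RVO
#' 4/3/3 (lognormal); treatment-year mix 72/18/10%; year-end discharge
#' 5/2/1%; diagnostics usage LogMAR 100%, slit lamp 100%, angiography 20%,
#' OCT 70%; equipment 2 slit lamps, 1 angiography, 2 OCT; 1 ophthalmic
#' photographer, 4 nurses, 2 technicians, 5 healthcare assistants; 1
#' injection bed, 1 theatre, 4 consultation rooms; 33 clinic sessions/week;
#' tariffs 112/63/292/107/112 GBP.
#'
#' @return A validated parameter set of class `rs_params` (a nested list).
#' @export
#' @examples
#' p <- default_parameters()
#' p$costs$hourly[["consultant"]]  # 48.64
#' p$tariffs[["laser"]]            # 292
default_parameters <- function() {
  demand <- default_demand_series()
  p <- list(
    horizon_months = 12L,
    warmup_months = 3L,
    conditions = list(
      AMD = list(
        followups_per_year = c(year1 = 5, year2 = 4, year3 = 4),
        followup_cv = 0.3,
        year_mix = c(year1 = 0.72, year2 = 0.18, year3 = 0.10),
        discharge_prob_at_year_end = c(year1 = 0.05, year2 = 0.02,
                                       year3 = 0.01)
      ),
      DR = list(
        followups_per_year = c(year1 = 4, year2 = 3, year3 = 3),
        followup_cv = 0.3,
        year_mix = c(year1 = 0.72, year2 = 0.18, year3 = 0.10),
        discharge_prob_at_year_end = c(year1 = 0.05, year2 = 0.02,
                                       year3 = 0.01)
      ),
      RVO = list(
        followups_per_year = c(year1 = 4, year2 = 3, year3 = 3),
        followup_cv = 0.3,
        year_mix = c(year1 = 0.72, year2 = 0.18, year3 = 0.10),
        discharge_prob_at_year_end = c(year1 = 0.05, year2 = 0.02,
                                       year3 = 0.01)
      )
    ),
    # share of referrals and caseload by condition (not printed with the
    # fixed inputs; an assumption documented in the vignette)
    condition_mix = c(AMD = 0.50, DR = 0.30, RVO = 0.20),
    # stable patients under periodic monitoring (the virtual-clinic-eligible
    # population); rates chosen for flow balance, see vignette
    monitoring = list(
      transition_prob = 0.46,         # year-end survivors entering monitoring
      review_interval_months = 4,
      reactivation_prob = 0.10,       # review returns patient to treatment
      discharge_prob = 0.37,          # review discharges (to community care)
      pool_ratio = 0.3786            # initial monitoring pool / active caseload
    ),
    diagnostics = list(
      usage_prob = c(logmar = 1.0, slitlamp = 1.0, angiography = 0.2,
                     oct = 0.7),
      equipment_count = c(slitlamp = 2L, angiography = 1L, oct = 2L),
      minutes_per_test = c(logmar = 10, slitlamp = 10, angiography = 10,
                           oct = 10),
      staffing = c(logmar = "hca", slitlamp = "technician",
                   angiography = "photographer", oct = "technician")
    ),
    resources = list(
      staff_counts = c(consultant = 2L, photographer = 1L, nurse = 4L,
                       technician = 2L, hca = 5L, optometrist = 0L),
      physical_counts = c(injection_bed = 1L, theatre = 1L,
                          consultation_room = 4L),
      clinics_per_week = 33L,
      session_length_hours = 4,
      working_days_per_week = 5L,
      day_length_hours = 8
    ),
    costs = list(
      hourly = c(consultant = 48.64, photographer = 17.66, nurse = 14.27,
                 technician = 14.27, hca = 9.85, optometrist = 17.66),
      virtual_setup_cost_monthly = 5118
    ),
    tariffs = c(first = 112, followup = 63, laser = 292, pdt = 107,
                bsc = 112),
    service_times = list(
      first_consult_min = 18.34,
      followup_consult_min = 8.73,
      injection_consultant_min = 11.35,
      injection_nurse_min = 15,
      laser_min = 30,
      pdt_min = 30,
      virtual_review_min = 10,
      duration_cv = 0.3,
      # average number of nurses providing in-clinic support per running
      # session (prep, visual-acuity support, flow coordination)
      nurse_session_cover = 0.715,
      dna_rate = 0.08,
      rebook_delay_days = 14,
      max_rebooks = 2L
    ),
    treatment_mix = list(
      AMD = c(injection = 0.80, laser = 0, pdt = 0, bsc = 0.05),
      DR = c(injection = 0.50, laser = 0.15, pdt = 0.05, bsc = 0),
      RVO = c(injection = 0.80, laser = 0, pdt = 0, bsc = 0.05)
    ),
    booking = list(
      capacity_fraction = 0.985,  # consultant load ceiling used when booking
      new_slot_share = 0.55,      # share of post-treatment capacity for news
      initial_waiting_list = 40L,
      initial_caseload = 3122L,
      virtual_diversion_rate = 0.07, # of monthly follow-up volume
      # structural assumption (see vignette): share of the follow-up
      # forecast that is active-treatment flow
      active_flow_frac = 0.84,
      # stable monitoring reviews are booked into a fixed monthly template
      # of review slots (sized during calibration)
      review_slots_per_month = 184L,
      # share of consultant capacity released by a scenario that is
      # re-invested in new-patient slots; the rest opens review catch-up
      released_capacity_first_share = 0.88
    ),
    scenario = scenario_spec("SC0"),
    demand = demand
  )
  class(p) <- "rs_params"
  validate_parameters(p)
  p
}

#' Packaged default demand series
#'
#' Monthly expected first-appointment referrals and forecast follow-up volume
#' with a smooth seasonal pattern, scaled so the served baseline reproduces
#' roughly 94 first and 1088 follow-up attendances per month (referral demand
#' slightly exceeds served first-appointment capacity, feeding the waiting
#' list). Expected did-not-attends are derived at the configured DNA rate.
#'
#' @param horizon_months Number of months (default 12).
#' @param mean_first Mean monthly first-appointment referrals.
#' @param mean_followup Mean monthly follow-up demand (forecast; used for
#'   caseload sizing and reporting).
#' @param seasonal_amplitude_first,seasonal_amplitude_followup Relative
#'   seasonal amplitudes.
#' @param dna_rate Expected DNA proportion used for the DNA forecast row.
#' @param condition_mix Named proportions over AMD/DR/RVO.
#' @return A list with data frames `first_appts` (month, condition, count),
#'   `followup_appts` and `dna_expected`.
#' @export
default_demand_series <- function(horizon_months = 12L,
                                  mean_first = 106,
                                  mean_followup = 1088,
                                  seasonal_amplitude_first = 0.15,
                                  seasonal_amplitude_followup = 0.11,
                                  dna_rate = 0.08,
                                  condition_mix = c(AMD = 0.50, DR = 0.30,
                                                    RVO = 0.20)) {
  m <- seq_len(horizon_months)
  seas <- function(amp) 1 + amp * sin(2 * pi * (m - 2) / 12)
  tot_first <- round(mean_first * seas(seasonal_amplitude_first))
  tot_fu <- round(mean_followup * seas(seasonal_amplitude_followup))
  split_by_condition <- function(tot) {
    out <- do.call(rbind, lapply(seq_along(tot), function(i) {
      counts <- floor(tot[i] * condition_mix)
      # allocate the rounding remainder to the largest share
      counts[which.max(condition_mix)] <-
        counts[which.max(condition_mix)] + tot[i] - sum(counts)
      data.frame(month = i, condition = names(condition_mix),
                 count = as.numeric(counts), row.names = NULL)
    }))
    out
  }
  list(
    first_appts = split_by_condition(tot_first),
    followup_appts = split_by_condition(tot_fu),
    dna_expected = data.frame(month = m,
                              count = round(dna_rate * (tot_first + tot_fu)))
  )
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the configuration: probability
#' vectors lie in `[0, 1]` and treatment-year mixes sum to one, follow-up
#' regimens and service times are positive, resource and equipment counts are
#' non-negative integers (equipment >= 1), tariffs and hourly rates are
#' positive, the DNA rate lies in `[0, 1)`, and the demand series covers a
#' consistent set of months with non-negative expected counts.
#'
#' @param params A parameter set.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field and value.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg, value = NULL) {
    stop("invalid parameter '", field, "': ", msg,
         if (!is.null(value)) paste0(" (got ", paste(value, collapse = ", "),
                                     ")"),
         call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      fail(field, "probabilities must lie in [0, 1]", x)
    }
  }
  for (cn in CONDITIONS) {
    cp <- params$conditions[[cn]]
    if (is.null(cp)) fail(paste0("conditions$", cn), "missing condition")
    if (any(cp$followups_per_year <= 0)) {
      fail(paste0("conditions$", cn, "$followups_per_year"),
           "must be positive", cp$followups_per_year)
    }
    if (abs(sum(cp$year_mix) - 1) > 1e-9) {
      fail(paste0("conditions$", cn, "$year_mix"),
           "must sum to 1", sum(cp$year_mix))
    }
    chk_prob(cp$year_mix, paste0("conditions$", cn, "$year_mix"))
    chk_prob(cp$discharge_prob_at_year_end,
             paste0("conditions$", cn, "$discharge_prob_at_year_end"))
    if (cp$followup_cv < 0) {
      fail(paste0("conditions$", cn, "$followup_cv"), "must be >= 0")
    }
  }
  if (abs(sum(params$condition_mix) - 1) > 1e-9) {
    fail("condition_mix", "must sum to 1", sum(params$condition_mix))
  }
  chk_prob(params$condition_mix, "condition_mix")
  chk_prob(params$diagnostics$usage_prob, "diagnostics$usage_prob")
  if (any(params$diagnostics$equipment_count < 1)) {
    fail("diagnostics$equipment_count", "equipment counts must be >= 1",
         params$diagnostics$equipment_count)
  }
  if (any(params$diagnostics$minutes_per_test <= 0)) {
    fail("diagnostics$minutes_per_test", "must be positive")
  }
  if (!all(params$diagnostics$staffing %in% STAFF_ROLES)) {
    fail("diagnostics$staffing", "unknown staff role",
         params$diagnostics$staffing)
  }
  rs <- params$resources
  if (any(rs$staff_counts < 0) || any(rs$physical_counts < 0)) {
    fail("resources", "counts must be >= 0")
  }
  if (rs$clinics_per_week <= 0) fail("resources$clinics_per_week", "must be > 0")
  if (rs$session_length_hours <= 0) {
    fail("resources$session_length_hours", "must be > 0")
  }
  if (any(params$costs$hourly <= 0)) {
    fail("costs$hourly", "rates must be positive", params$costs$hourly)
  }
  if (params$costs$virtual_setup_cost_monthly < 0) {
    fail("costs$virtual_setup_cost_monthly", "must be >= 0")
  }
  if (any(params$tariffs <= 0)) fail("tariffs", "must be positive")
  st <- params$service_times
  durs <- c(st$first_consult_min, st$followup_consult_min,
            st$injection_consultant_min, st$injection_nurse_min, st$laser_min,
            st$pdt_min, st$virtual_review_min,
            params$diagnostics$minutes_per_test)
  if (any(durs <= 0)) fail("service_times", "durations must be positive")
  if (st$dna_rate < 0 || st$dna_rate >= 1) {
    fail("service_times$dna_rate", "must lie in [0, 1)", st$dna_rate)
  }
  mon <- params$monitoring
  chk_prob(c(mon$transition_prob, mon$reactivation_prob, mon$discharge_prob),
           "monitoring")
  if (mon$review_interval_months <= 0) {
    fail("monitoring$review_interval_months", "must be > 0")
  }
  for (cn in CONDITIONS) {
    tm <- params$treatment_mix[[cn]]
    chk_prob(tm, paste0("treatment_mix$", cn))
    if (sum(tm) > 1 + 1e-9) {
      fail(paste0("treatment_mix$", cn), "treatment probabilities exceed 1",
           sum(tm))
    }
  }
  bk <- params$booking
  chk_prob(c(bk$capacity_fraction, bk$new_slot_share,
             bk$virtual_diversion_rate), "booking")
  if (bk$initial_caseload < 0 || bk$initial_waiting_list < 0) {
    fail("booking", "initial caseload / waiting list must be >= 0")
  }
  if (!is.null(params$scenario)) validate_scenario(params$scenario)
  dm <- params$demand
  months <- sort(unique(dm$first_appts$month))
  for (tbl in c("first_appts", "followup_appts")) {
    d <- dm[[tbl]]
    if (any(d$count < 0)) fail(paste0("demand$", tbl), "counts must be >= 0")
    if (!setequal(unique(d$month), months)) {
      fail(paste0("demand$", tbl), "month coverage differs across series")
    }
    if (!all(d$condition %in% CONDITIONS)) {
      fail(paste0("demand$", tbl), "unknown condition")
    }
  }
  if (any(dm$dna_expected$count < 0)) {
    fail("demand$dna_expected", "counts must be >= 0")
  }
  invisible(params)
}

# ---- config file I/O --------------------------------------------------------

params_to_list <- function(params) {
  # named atomic vectors become YAML maps; unnamed vectors stay sequences
  to_tree <- function(x) {
    if (is.data.frame(x)) as.list(x)
    else if (is.list(x)) lapply(x, to_tree)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  p <- to_tree(unclass(params))
  p$scenario <- lapply(unclass(params$scenario), function(x) x)
  p
}

list_to_params <- function(p) {
  to_named_num <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  num_fields <- function(lst, fields) {
    for (f in fields) lst[[f]] <- to_named_num(lst[[f]])
    lst
  }
  for (cn in names(p$conditions)) {
    p$conditions[[cn]] <- num_fields(p$conditions[[cn]],
                                     c("followups_per_year", "year_mix",
                                       "discharge_prob_at_year_end"))
  }
  p$condition_mix <- to_named_num(p$condition_mix)
  p$diagnostics <- num_fields(p$diagnostics,
                              c("usage_prob", "minutes_per_test"))
  p$diagnostics$equipment_count <-
    vapply(p$diagnostics$equipment_count, as.integer, integer(1))
  p$diagnostics$staffing <- unlist(p$diagnostics$staffing)
  p$resources$staff_counts <-
    vapply(p$resources$staff_counts, as.integer, integer(1))
  p$resources$physical_counts <-
    vapply(p$resources$physical_counts, as.integer, integer(1))
  p$resources$clinics_per_week <- as.integer(p$resources$clinics_per_week)
  p$resources$working_days_per_week <-
    as.integer(p$resources$working_days_per_week)
  p$costs$hourly <- to_named_num(p$costs$hourly)
  p$tariffs <- to_named_num(p$tariffs)
  p$treatment_mix <- lapply(p$treatment_mix, to_named_num)
  p$service_times$max_rebooks <- as.integer(p$service_times$max_rebooks)
  p$booking$initial_waiting_list <- as.integer(p$booking$initial_waiting_list)
  p$booking$initial_caseload <- as.integer(p$booking$initial_caseload)
  p$horizon_months <- as.integer(p$horizon_months)
  p$warmup_months <- as.integer(p$warmup_months)
  p$demand <- lapply(p$demand, function(cols) {
    as.data.frame(lapply(cols, unlist), stringsAsFactors = FALSE)
  })
  class(p$scenario) <- "rs_scenario"
  class(p) <- "rs_params"
  p
}

#' Write a parameter set to a YAML config file
#'
#' @param params A parameter set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_parameters()]
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  yaml::write_yaml(params_to_list(params), path, precision = 15)
  invisible(path)
}

#' Load and validate a parameter set from a YAML config file
#'
#' The file must follow the schema written by [write_parameters()] (the
#' packaged baseline fixture `system.file("extdata", "baseline.yaml",
#' package = "retinasim")` is the reference example). Unknown top-level or
#' section keys are rejected; all structural invariants are checked.
#'
#' @param path Path to a YAML configuration.
#' @return A validated parameter set of class `rs_params`.
#' @export
#' @examples
#' path <- system.file("extdata", "baseline.yaml", package = "retinasim")
#' p <- load_parameters(path)
#' p$costs$hourly[["consultant"]]
load_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  template <- params_to_list(default_parameters())
  check_keys <- function(got, want, where) {
    extra <- setdiff(names(got), names(want))
    missing <- setdiff(names(want), names(got))
    if (length(extra)) {
      stop("unknown config field", if (length(extra) > 1) "s", " in ", where,
           ": ", paste(extra, collapse = ", "), call. = FALSE)
    }
    if (length(missing)) {
      stop("missing config field", if (length(missing) > 1) "s", " in ",
           where, ": ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(raw, template, "top level")
  for (sec in c("conditions", "diagnostics", "resources", "costs",
                "service_times", "monitoring", "booking", "scenario",
                "demand")) {
    check_keys(raw[[sec]], template[[sec]], sec)
  }
  params <- list_to_params(raw)
  validate_parameters(params)
  params
}

#' @export
print.rs_params <- function(x, ...) {
  dm <- x$demand$first_appts
  cat("<rs_params> retinal-service model configuration\n")
  cat("  horizon:", x$horizon_months, "months (+", x$warmup_months,
      "warm-up)\n")
  cat("  conditions:", paste(names(x$conditions), collapse = ", "), "\n")
  cat("  staff:", paste(names(x$resources$staff_counts),
                        x$resources$staff_counts, collapse = ", "), "\n")
  cat("  clinics/week:", x$resources$clinics_per_week, "\n")
  cat("  mean monthly referral demand:",
      round(sum(dm$count) / length(unique(dm$month)), 1), "first appts\n")
  invisible(x)
}
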