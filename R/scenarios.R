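# Scenario definitions and application, and the baseline calibration
# procedure. Four scenarios are modelled: SC0 baseline; SC1 nurse injectors
# with a 5% uplift in DR referrals; SC2 community virtual clinic for stable
# monitoring patients; SC3 = SC1 + SC2 combined.

#' Construct a scenario specification
#'
#' Presets: `"SC0"` (baseline, all interventions off), `"SC1"` (nurse
#' injectors performing a share of intravitreal injections plus a 5%
#' non-compounding uplift on monthly DR first-appointment referrals),
#' `"SC2"` (community virtual clinic: stable monitoring reviews move to a
#' nurse-led community service), `"SC3"` (SC1 and SC2 simultaneously).
#' Individual fields can be overridden.
#'
#' @param id `"SC0"`, `"SC1"`, `"SC2"` or `"SC3"`.
#' @param nurse_injectors Enable nurse injectors.
#' @param nurse_injection_share Fraction of injections performed by nurse
#'   injectors (default 0.30 when enabled).
#' @param dr_uplift Relative uplift applied to every month's DR
#'   first-appointment referrals (default 0.05 for SC1/SC3;
#'   non-compounding).
#' @param virtual_clinic Enable the community virtual clinic.
#' @param virtual_diversion_rate Fraction of monthly follow-up volume the
#'   virtual clinic can absorb (`NA` = take the configured default from the
#'   parameter set when the scenario is applied).
#' @param virtual_setup_cost_monthly Monthly virtual-clinic infrastructure
#'   cost in GBP (`NA` = configured default).
#' @return A list of class `rs_scenario`.
#' @export
#' @examples
#' scenario_spec("SC1")
#' scenario_spec("SC2", virtual_diversion_rate = 0.10)
scenario_spec <- function(id = c("SC0", "SC1", "SC2", "SC3"),
                          nurse_injectors = NULL,
                          nurse_injection_share = NULL,
                          dr_uplift = NULL,
                          virtual_clinic = NULL,
                          virtual_diversion_rate = NULL,
                          virtual_setup_cost_monthly = NULL) {
  id <- match.arg(id)
  preset <- switch(id,
    SC0 = list(nurse_injectors = FALSE, nurse_injection_share = 0,
               dr_uplift = 0, virtual_clinic = FALSE,
               virtual_diversion_rate = 0, virtual_setup_cost_monthly = 0),
    SC1 = list(nurse_injectors = TRUE, nurse_injection_share = 0.30,
               dr_uplift = 0.05, virtual_clinic = FALSE,
               virtual_diversion_rate = 0, virtual_setup_cost_monthly = 0),
    SC2 = list(nurse_injectors = FALSE, nurse_injection_share = 0,
               dr_uplift = 0, virtual_clinic = TRUE,
               virtual_diversion_rate = NA_real_,
               virtual_setup_cost_monthly = NA_real_),
    SC3 = list(nurse_injectors = TRUE, nurse_injection_share = 0.30,
               dr_uplift = 0.05, virtual_clinic = TRUE,
               virtual_diversion_rate = NA_real_,
               virtual_setup_cost_monthly = NA_real_)
  )
  ovr <- list(nurse_injectors = nurse_injectors,
              nurse_injection_share = nurse_injection_share,
              dr_uplift = dr_uplift, virtual_clinic = virtual_clinic,
              virtual_diversion_rate = virtual_diversion_rate,
              virtual_setup_cost_monthly = virtual_setup_cost_monthly)
  for (f in names(ovr)) if (!is.null(ovr[[f]])) preset[[f]] <- ovr[[f]]
  spec <- c(list(id = id), preset)
  class(spec) <- "rs_scenario"
  validate_scenario(spec)
  spec
}

#' Validate a scenario specification
#'
#' @param spec A scenario specification.
#' @return `spec`, invisibly, if valid.
#' @export
validate_scenario <- function(spec) {
  if (!inherits(spec, "rs_scenario")) stop("not a scenario specification")
  frac <- c(spec$nurse_injection_share, spec$dr_uplift,
            spec$virtual_diversion_rate)
  frac <- frac[!is.na(frac)]
  if (any(frac < 0 | frac > 1)) {
    stop("scenario fractions must lie in [0, 1]")
  }
  if (!spec$nurse_injectors && spec$nurse_injection_share > 0) {
    stop("nurse_injection_share requires nurse_injectors")
  }
  if (!spec$virtual_clinic &&
      (isTRUE(spec$virtual_diversion_rate > 0))) {
    stop("virtual_diversion_rate requires virtual_clinic")
  }
  invisible(spec)
}

resolve_scenario <- function(spec, params) {
  if (is.na(spec$virtual_diversion_rate)) {
    spec$virtual_diversion_rate <-
      if (spec$virtual_clinic) params$booking$virtual_diversion_rate else 0
  }
  if (is.na(spec$virtual_setup_cost_monthly)) {
    spec$virtual_setup_cost_monthly <-
      if (spec$virtual_clinic) params$costs$virtual_setup_cost_monthly else 0
  }
  spec
}

#' Apply a scenario to a parameter set
#'
#' Returns a transformed copy of the configuration: the DR first-appointment
#' referral expectations are multiplied by `1 + dr_uplift` for every month
#' (a constant, non-compounding uplift), unresolved scenario fields are
#' filled from the configured defaults, and the scenario is recorded in the
#' parameter set, where the simulator reads the nurse-injector share and the
#' virtual-clinic settings. Applying the baseline scenario SC0 is the
#' identity. Applying a further scenario to an already-transformed set
#' composes the interventions (booleans combine, shares take the maximum,
#' demand uplifts apply on top of one another).
#'
#' @param params A parameter set.
#' @param spec A scenario from [scenario_spec()].
#' @return The transformed parameter set.
#' @export
#' @examples
#' p <- default_parameters()
#' p3 <- apply_scenario(p, scenario_spec("SC3"))
#' p3$scenario$id
apply_scenario <- function(params, spec) {
  validate_scenario(spec)
  spec <- resolve_scenario(spec, params)
  cur <- params$scenario
  if (identical(cur, spec)) return(params)
  baseline <- is.null(cur) || identical(cur, resolve_scenario(
    scenario_spec("SC0"), params))
  if (baseline) {
    merged <- spec
  } else {
    merged <- cur
    merged$nurse_injectors <- cur$nurse_injectors || spec$nurse_injectors
    merged$nurse_injection_share <- max(cur$nurse_injection_share,
                                        spec$nurse_injection_share)
    merged$dr_uplift <- (1 + cur$dr_uplift) * (1 + spec$dr_uplift) - 1
    merged$virtual_clinic <- cur$virtual_clinic || spec$virtual_clinic
    merged$virtual_diversion_rate <- max(cur$virtual_diversion_rate,
                                         spec$virtual_diversion_rate)
    merged$virtual_setup_cost_monthly <- max(
      cur$virtual_setup_cost_monthly, spec$virtual_setup_cost_monthly)
    merged$id <- canonical_scenario_id(merged)
  }
  if (spec$dr_uplift > 0) {
    fa <- params$demand$first_appts
    dr <- fa$condition == "DR"
    fa$count[dr] <- fa$count[dr] * (1 + spec$dr_uplift)
    params$demand$first_appts <- fa
  }
  params$scenario <- merged
  params
}

canonical_scenario_id <- function(spec) {
  if (spec$nurse_injectors && spec$virtual_clinic) "SC3"
  else if (spec$nurse_injectors) "SC1"
  else if (spec$virtual_clinic) "SC2"
  else "SC0"
}

#' Calibrate the baseline model to its operating targets
#'
#' Adjusts only the declared free parameters -- service-time means, the
#' booking-policy shares, the nurse clinic-cover level and the initial
#' caseload -- by damped iterative search until the simulated baseline
#' reproduces the target operating point: mean monthly first and follow-up
#' attendances and consultant and nurse utilisation. All fixed inputs
#' (regimens, routing probabilities, resource counts, costs, tariffs) are
#' untouched.
#'
#' @param params Starting parameter set.
#' @param targets Named list: `consultant_util`, `nurse_util` (fractions in
#'   (0, 1]), `monthly_first`, `monthly_followup` (attendances/month).
#' @param tol Named list: `util` (absolute, default 0.02) and `activity`
#'   (relative, default 0.03).
#' @param n_reps Replications per evaluation (default 5).
#' @param seed Master seed for calibration runs.
#' @param max_iter Maximum search iterations.
#' @param cost_delta_target Optional: after convergence, set the monthly
#'   virtual-clinic setup cost so the combined scenario's total-cost
#'   increase over baseline is approximately this fraction.
#' @return The calibrated parameter set, with a `calibration` attribute
#'   holding the iteration history.
#' @export
calibrate_baseline <- function(params,
                               targets = list(consultant_util = 0.98,
                                              nurse_util = 0.59,
                                              monthly_first = 94,
                                              monthly_followup = 1088),
                               tol = list(util = 0.02, activity = 0.03),
                               n_reps = 5L, seed = 20230401, max_iter = 8L,
                               cost_delta_target = NULL) {
  stopifnot(targets$consultant_util > 0, targets$consultant_util <= 1,
            targets$nurse_util > 0, targets$nurse_util <= 1)
  sc0 <- scenario_spec("SC0")
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  history <- list()
  # structural decomposition of the follow-up volume (see vignette): the
  # active-treatment flow target; the stable-review flow equilibrium is set
  # by the monitoring transition/reactivation/discharge rates
  active_target <- params$booking$active_flow_frac * targets$monthly_followup
  measure <- function(p) {
    s <- run_scenario(p, sc0, n_reps = n_reps, seed = seed)$summary
    list(first = mean(s$first_att), fu = mean(s$fu_att),
         cu = mean(s$util_consultant), nu = mean(s$util_nurse),
         active = mean(s$fu_active_att),
         stable_flow = mean(s$monitoring_patients) /
           p$monitoring$review_interval_months,
         deferred_active = mean(s$deferred_active))
  }
  ok <- function(ms) {
    abs(ms$cu - targets$consultant_util) <= tol$util &&
      abs(ms$nu - targets$nurse_util) <= tol$util &&
      abs(ms$first / targets$monthly_first - 1) <= tol$activity &&
      abs(ms$fu / targets$monthly_followup - 1) <= tol$activity
  }
  ms <- measure(params)
  it <- 0L
  if (!ok(ms)) {
    # starting point from flow balance: the caseload whose regimen flow
    # sustains the active-treatment target, a review-slot template sized to
    # the stable-review residual, and a monitoring pool (1.3 buffer) whose
    # review flow keeps the template supplied
    mean_fu_year <- sum(vapply(CONDITIONS, function(cn) {
      cp <- params$conditions[[cn]]
      params$condition_mix[[cn]] * sum(cp$year_mix * cp$followups_per_year)
    }, numeric(1)))
    att_p <- 1 - params$service_times$dna_rate
    stable_fill <- targets$monthly_followup - active_target
    params$booking$initial_caseload <-
      as.integer(round(12 * active_target / mean_fu_year))
    params$booking$review_slots_per_month <-
      as.integer(round(stable_fill / att_p))
    params$monitoring$pool_ratio <-
      1.3 * stable_fill / att_p * params$monitoring$review_interval_months /
      params$booking$initial_caseload
    ms <- measure(params)
  }
  while (!ok(ms) && it < max_iter) {
    it <- it + 1L
    history[[it]] <- ms
    # nurse clinic cover scales utilisation directly at baseline
    params$service_times$nurse_session_cover <- clamp(
      params$service_times$nurse_session_cover * targets$nurse_util / ms$nu,
      0.05, 4)
    # consultant-facing service times jointly fill the capacity toward the
    # utilisation target and admit the target appointment volume
    k <- clamp((targets$consultant_util / ms$cu)^0.55 *
                 (ms$fu / targets$monthly_followup)^0.45, 0.8, 1.25)
    for (f in c("followup_consult_min", "first_consult_min",
                "injection_consultant_min")) {
      params$service_times[[f]] <- params$service_times[[f]] * k
    }
    # caseload (with the monitoring pool scaling alongside) supplies the
    # appointment volume; deferred active work counts as overshoot
    params$booking$initial_caseload <- as.integer(round(
      params$booking$initial_caseload *
        clamp((targets$monthly_followup /
                 (ms$fu + 0.7 * ms$deferred_active))^0.6, 0.85, 1.15)))
    # new-patient slot share aligns first attendances
    params$booking$new_slot_share <- clamp(
      params$booking$new_slot_share * targets$monthly_first / ms$first,
      0.02, 0.98)
    ms <- measure(params)
  }
  if (!ok(ms)) {
    stop("calibration did not converge within ", max_iter, " iterations; ",
         sprintf(paste0("achieved first=%.1f (target %g), fu=%.1f (%g), ",
                        "consultant util=%.3f (%g), nurse util=%.3f (%g)"),
                 ms$first, targets$monthly_first, ms$fu,
                 targets$monthly_followup, ms$cu, targets$consultant_util,
                 ms$nu, targets$nurse_util))
  }
  if (!is.null(cost_delta_target)) {
    params <- calibrate_setup_cost(params, cost_delta_target,
                                   n_reps = n_reps, seed = seed)
  }
  attr(params, "calibration") <- list(iterations = it, history = history,
                                      final = ms)
  params
}

#' Set the virtual-clinic setup cost from a total-cost target
#'
#' Runs the combined scenario with zero setup cost, measures the staff-cost
#' difference against baseline, and sets the monthly setup cost so the
#' combined scenario's total-cost increase lands at `cost_delta_target`.
#'
#' @param params A (calibrated) parameter set.
#' @param cost_delta_target Target relative cost increase of the combined
#'   scenario over baseline (e.g. 0.21).
#' @param n_reps Replications used for the measurement.
#' @param seed Master seed.
#' @return The parameter set with `costs$virtual_setup_cost_monthly` set.
#' @export
calibrate_setup_cost <- function(params, cost_delta_target, n_reps = 5L,
                                 seed = 20230401) {
  p0 <- params
  p0$costs$virtual_setup_cost_monthly <- 0
  s0 <- run_scenario(p0, scenario_spec("SC0"), n_reps, seed)$summary
  s3 <- run_scenario(p0, scenario_spec("SC3"), n_reps, seed)$summary
  monthly0 <- mean(s0$cost_gbp) / 12
  monthly3 <- mean(s3$cost_gbp) / 12
  setup <- max(0, cost_delta_target * monthly0 - (monthly3 - monthly0))
  params$costs$virtual_setup_cost_monthly <- round(setup)
  params
}
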