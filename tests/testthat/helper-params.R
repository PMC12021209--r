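# A scaled-down configuration for fast pipeline tests: a small service with
# the same structure (about 1/10 the caseload), 6 reporting months.
tiny_params <- function() {
  p <- default_parameters()
  p$horizon_months <- 6L
  p$warmup_months <- 2L
  p$booking$initial_caseload <- 320L
  p$booking$initial_waiting_list <- 6L
  p$booking$review_slots_per_month <- 20L
  p$demand <- default_demand_series(horizon_months = 6L, mean_first = 11,
                                    mean_followup = 110)
  p$resources$clinics_per_week <- 4L
  p$resources$staff_counts[["consultant"]] <- 1L
  validate_parameters(p)
  p
}

# a deterministic single-patient configuration: one AMD patient on the
# waiting list, no noise, no DNAs, certain injection treatment
trace_params <- function() {
  p <- default_parameters()
  p$horizon_months <- 12L
  p$warmup_months <- 0L
  p$booking$initial_caseload <- 0L
  p$booking$initial_waiting_list <- 1L
  p$condition_mix <- c(AMD = 1, DR = 0, RVO = 0)
  p$demand <- default_demand_series(horizon_months = 12L, mean_first = 0,
                                    mean_followup = 100,
                                    condition_mix = c(AMD = 1, DR = 0,
                                                      RVO = 0))
  p$demand$first_appts$count[] <- 0
  p$conditions$AMD$followup_cv <- 0
  p$conditions$AMD$discharge_prob_at_year_end[] <- 0
  p$monitoring$transition_prob <- 0
  p$service_times$duration_cv <- 0
  p$service_times$dna_rate <- 0
  p$diagnostics$usage_prob <- c(logmar = 1, slitlamp = 1, angiography = 0,
                                oct = 1)
  p$treatment_mix$AMD <- c(injection = 1, laser = 0, pdt = 0, bsc = 0)
  validate_parameters(p)
  p
}
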