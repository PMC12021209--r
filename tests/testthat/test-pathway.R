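test_that("regimen sampling hits the configured means with floor one", {
  p <- default_parameters()
  streams <- rng_streams(1)
  # zero-dispersion draws return the configured means exactly
  p0 <- p$conditions
  p0$AMD$followup_cv <- 0; p0$DR$followup_cv <- 0; p0$RVO$followup_cv <- 0
  expect_equal(sample_followup_count(p0$AMD, 1, streams), 5L)
  expect_equal(sample_followup_count(p0$DR, 2, streams), 3L)
  expect_equal(sample_followup_count(p0$RVO, 1, streams), 4L)
  # lognormal draws: mean of 100,000 AMD year-1 draws within 5 +/- 0.1
  draws <- sample_followup_count(p$conditions$AMD, 1, streams, n = 100000L)
  expect_true(all(draws >= 1L))
  expect_lt(abs(mean(draws) - 5), 0.1)
  # rounding floor: a tiny mean cannot produce zero appointments
  low <- p$conditions$AMD
  low$followups_per_year <- c(year1 = 0.3, year2 = 0.3, year3 = 0.3)
  expect_true(all(sample_followup_count(low, 1, streams, n = 500L) >= 1L))
})

test_that("admission assigns treatment years per the configured mix", {
  p <- default_parameters()
  streams <- rng_streams(2)
  pat <- admit_new_patient("AMD", p, streams)
  expect_equal(pat$treatment_year, 1L)
  expect_equal(pat$state, "active")
  expect_gte(pat$fu_total, 1L)

  n <- 10000L
  years <- vapply(seq_len(n), function(i) {
    admit_new_patient("DR", p, streams, warm_start = TRUE)$treatment_year
  }, integer(1))
  freq <- tabulate(years, 3) / n
  target <- c(0.72, 0.18, 0.10)
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(freq - target) < 3 * se))
})

test_that("the diagnostics battery matches the configured usage rates", {
  p <- default_parameters()
  streams <- rng_streams(3)
  n <- 100000L
  bat <- diagnostics_battery(p$diagnostics, streams, n = n)
  expect_true(all(bat[, "logmar"]))
  expect_true(all(bat[, "slitlamp"]))
  se <- function(q) sqrt(q * (1 - q) / n)
  expect_lt(abs(mean(bat[, "angiography"]) - 0.2), 3 * se(0.2))
  expect_lt(abs(mean(bat[, "oct"]) - 0.7), 3 * se(0.7))
  # expected battery size: 1 + 1 + 0.2 + 0.7 = 2.9 tests per attendance
  expect_lt(abs(mean(rowSums(bat)) - 2.9), 3 * sqrt(0.21 + 0.16) / sqrt(n))
})

test_that("treatment draws follow the condition-specific mix", {
  p <- default_parameters()
  streams <- rng_streams(4)
  n <- 50000L
  tr <- draw_treatment(rep("DR", n), p, streams, nurse_injection_share = 0.3)
  freq <- table(tr$treatment) / n
  expect_lt(abs(freq[["laser"]] - 0.15), 0.01)
  expect_lt(abs(freq[["pdt"]] - 0.05), 0.01)
  expect_lt(abs(freq[["injection"]] - 0.50), 0.01)
  inj <- tr$injector[tr$treatment == "injection"]
  expect_lt(abs(mean(inj == "nurse") - 0.3), 0.02)
  # share zero sends every injection to the consultant
  tr0 <- draw_treatment(rep("AMD", 1000), p, streams)
  expect_true(all(tr0$injector[tr0$treatment == "injection"] ==
                    "consultant"))
})

test_that("a deterministic AMD patient attends first plus five follow-ups", {
  p <- default_parameters()
  p$conditions$AMD$followup_cv <- 0
  p$conditions$AMD$discharge_prob_at_year_end[] <- 0
  p$monitoring$transition_prob <- 0
  p$service_times$dna_rate <- 0
  p$treatment_mix$AMD <- c(injection = 1, laser = 0, pdt = 0, bsc = 0)
  streams <- rng_streams(5)
  pat <- admit_new_patient("AMD", p, streams)
  expect_equal(pat$fu_total, 5L)
  res <- run_attendance(pat, p, streams, appt_type = "first")
  n_fu <- 0L
  pat <- res$patient
  while (pat$treatment_year == 1L && pat$fu_done < pat$fu_total) {
    res <- run_attendance(pat, p, streams, appt_type = "followup")
    pat <- res$patient
    n_fu <- n_fu + 1L
    expect_equal(res$attendance$outcome, "Continue")
  }
  expect_equal(n_fu, 5L)
  expect_equal(pat$treatment_year, 2L)  # advanced, regimen resampled
  expect_equal(pat$fu_total, 4L)
})

test_that("year-end discharge frequencies match the configured rates", {
  p <- default_parameters()
  p$monitoring$transition_prob <- 0  # isolate the discharge decision
  streams <- rng_streams(6)
  n <- 20000L
  outcomes <- vapply(seq_len(n), function(i) {
    pat <- list(condition = "AMD", treatment_year = 1L, fu_total = 1L,
                fu_done = 0L, state = "active", dna_count = 0L,
                virtual_eligible = FALSE)
    run_attendance(pat, p, streams)$attendance$outcome
  }, character(1))
  frac <- mean(outcomes == "Discharge")
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("missed appointments consume nothing and attendance on a discharged patient errors", {
  p <- default_parameters()
  p$service_times$dna_rate <- 0.9
  streams <- rng_streams(7)
  pat <- admit_new_patient("RVO", p, streams)
  dnas <- 0L
  for (i in 1:60) {
    res <- run_attendance(pat, p, streams, appt_type = "followup")
    if (res$attendance$outcome == "DNA") {
      dnas <- dnas + 1L
      expect_equal(sum(res$attendance$staff_minutes), 0)
      expect_equal(length(res$attendance$diagnostics), 0L)
    }
    pat <- res$patient
    pat$fu_done <- 0L  # keep the year open for the loop
  }
  expect_gt(dnas, 30L)

  pat$state <- "discharged"
  expect_error(run_attendance(pat, p, streams), "discharged")
})
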