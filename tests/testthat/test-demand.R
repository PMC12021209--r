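test_that("the synthetic history is deterministic and respects its formula", {
  # degenerate noise: every monthly total equals the level
  h <- generate_synthetic_history(1, level = 100, trend = 0,
                                  seasonal_amplitude = 0, noise_cv = 0)
  tot <- stats::aggregate(count ~ month, h, sum)
  expect_equal(tot$count, rep(100, 36))
  expect_equal(sort(unique(h$month)), 1:36)

  # deterministic given the seed
  h1 <- generate_synthetic_history(42, level = 800, trend = 3,
                                   seasonal_amplitude = 0.1, noise_cv = 0.08)
  h2 <- generate_synthetic_history(42, level = 800, trend = 3,
                                   seasonal_amplitude = 0.1, noise_cv = 0.08)
  expect_identical(h1, h2)
  expect_true(all(h1$count >= 0))

  # noiseless totals follow the stated trend/seasonality formula
  h3 <- generate_synthetic_history(1, level = 500, trend = 2,
                                   seasonal_amplitude = 0.2, noise_cv = 0)
  t <- 1:36
  expected <- round(pmax(0, (500 + 2 * t) * (1 + 0.2 * sin(2 * pi * t / 12))))
  expect_equal(stats::aggregate(count ~ month, h3, sum)$count, expected)
  expect_error(generate_synthetic_history(1, level = 0), "positive")
})

test_that("forecast selection recovers the generating model class", {
  mk_history <- function(counts) {
    do.call(rbind, lapply(seq_along(counts), function(m) {
      data.frame(month = m, condition = "AMD", appt_type = "followup",
                 age_band = "65-79", count = counts[m])
    }))
  }
  # noiseless linear series -> linear trend, zero holdout error
  fits <- fit_and_select_forecast(mk_history(100 + 3 * (1:36)),
                                  holdout_months = 6)
  expect_equal(fits[[1]]$method, "LinearTrend")
  expect_equal(fits[[1]]$holdout_error, 0, tolerance = 1e-6)
  expect_equal(fits[[1]]$forecast, 100 + 3 * (37:48), tolerance = 1e-6)

  # noiseless 12-month-periodic series -> seasonal naive, zero error
  seasonal <- rep(c(80, 95, 120, 140, 130, 110, 90, 85, 100, 125, 135, 105),
                  3)
  fits <- fit_and_select_forecast(mk_history(seasonal), holdout_months = 6)
  expect_equal(fits[[1]]$method, "SeasonalNaive")
  expect_equal(fits[[1]]$holdout_error, 0)

  expect_error(fit_and_select_forecast(mk_history(seasonal), 2), "holdout")
  expect_error(fit_and_select_forecast(mk_history(rep(0, 36)), 6),
               "all zero")
})

test_that("selection agrees with a brute-force sweep of the candidates", {
  mape_oracle <- function(actual, pred) {
    keep <- actual != 0
    100 * mean(abs(actual[keep] - pred[keep]) / actual[keep])
  }
  h <- generate_synthetic_history(11, level = 900, trend = 4,
                                  seasonal_amplitude = 0.12, noise_cv = 0.05)
  fits <- fit_and_select_forecast(h, holdout_months = 6)
  for (f in fits) {
    errs <- f$candidate_errors
    best <- names(errs)[which.min(errs)]  # which.min keeps declared order
    expect_equal(f$method, best)
    expect_equal(unname(f$holdout_error), unname(min(errs)))
    expect_true(all(f$forecast >= 0))
  }
})

test_that("the selected forecast tracks the generator's analytic mean", {
  h <- generate_synthetic_history(5, level = 1000, trend = 5,
                                  seasonal_amplitude = 0.1, noise_cv = 0.04)
  fits <- fit_and_select_forecast(h, holdout_months = 6)
  total_fc <- Reduce(`+`, lapply(fits, `[[`, "forecast"))
  t <- 37:48
  analytic <- mean((1000 + 5 * t) * (1 + 0.1 * sin(2 * pi * t / 12)))
  expect_lt(abs(mean(total_fc) - analytic) / analytic, 0.10)
})

test_that("monthly arrivals are Poisson with uniform instants", {
  p <- default_parameters()
  streams <- rng_streams(123)
  zero <- p
  zero$demand$first_appts$count[1] <- 0
  inst <- arrivals_for_month(zero$demand, 1, "AMD", streams)
  expect_identical(inst, numeric(0))

  lambda <- p$demand$first_appts$count[
    p$demand$first_appts$month == 1 & p$demand$first_appts$condition == "AMD"]
  n_draws <- 2000
  counts <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    x <- arrivals_for_month(p$demand, 1, "AMD", streams,
                            working_minutes = 10400)
    counts[i] <- length(x)
    if (length(x)) {
      expect_true(all(x >= 0 & x <= 10400))
      expect_false(is.unsorted(x))
    }
  }
  se <- sqrt(lambda / n_draws)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("splitting a Poisson stream by condition conserves the total rate", {
  p <- default_parameters()
  streams <- rng_streams(77)
  months <- unique(p$demand$first_appts$month)
  total <- 0
  for (rep in 1:150) for (m in months) {
    for (cn in c("AMD", "DR", "RVO")) {
      total <- total + length(arrivals_for_month(p$demand, m, cn, streams))
    }
  }
  lam_tot <- sum(p$demand$first_appts$count) * 150
  expect_lt(abs(total - lam_tot) / lam_tot, 3 * sqrt(lam_tot) / lam_tot)
})

test_that("history CSV and demand construction round-trip", {
  h <- generate_synthetic_history(3, level = 600, trend = 1,
                                  seasonal_amplitude = 0.1, noise_cv = 0.05)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(h, tmp)
  h2 <- read_history_csv(tmp)
  expect_equal(as.data.frame(h2), as.data.frame(h))

  fits <- fit_and_select_forecast(h, holdout_months = 6)
  dm <- forecast_to_demand(fits, dna_rate = 0.08)
  expect_setequal(names(dm), c("first_appts", "followup_appts",
                               "dna_expected"))
  expect_true(all(dm$first_appts$count >= 0))
  expect_equal(nrow(dm$dna_expected), 12)
  # DNA forecast is the configured rate applied to total forecast activity
  tot <- stats::aggregate(count ~ month,
                          rbind(dm$first_appts, dm$followup_appts), sum)
  expect_equal(dm$dna_expected$count, round(0.08 * tot$count))
})
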