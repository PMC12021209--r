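# Demand generation and forecasting: a synthetic 36-month historical
# attendance series (trend + seasonality + noise, partitioned by condition,
# age band and first/follow-up type), candidate forecast models scored on a
# holdout window, and Poisson arrival sampling for the simulator.

AGE_BANDS <- c("50-64", "65-79", "80+")

#' Generate a synthetic 36-month historical attendance series
#'
#' Emulates the monthly attendance extract a hospital informatics team would
#' provide: total monthly counts follow
#' `round(max(0, (level + trend * t) * (1 + seasonal_amplitude *
#' sin(2 * pi * t / 12)) * (1 + eps)))` with mean-zero Gaussian noise of the
#' stated coefficient of variation, then are partitioned into condition, age
#' band and first/follow-up cells by fixed proportions. Deterministic given
#' the seed.
#'
#' @param seed Integer seed.
#' @param level Baseline monthly count (> 0).
#' @param trend Additive monthly trend (counts/month^2).
#' @param seasonal_amplitude Relative seasonal amplitude.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_months Series length (default 36).
#' @param condition_mix Named proportions over conditions.
#' @param age_mix Named proportions over age bands.
#' @param first_frac Proportion of attendances that are first appointments.
#' @return A data frame of class `rs_history` with columns `month`,
#'   `condition`, `appt_type` ("first"/"followup"), `age_band`, `count`.
#' @export
#' @examples
#' h <- generate_synthetic_history(1, level = 1000, trend = 2,
#'                                 seasonal_amplitude = 0.1, noise_cv = 0.05)
#' aggregate(count ~ month, h, sum)[1:3, ]
generate_synthetic_history <- function(seed, level, trend = 0,
                                       seasonal_amplitude = 0,
                                       noise_cv = 0,
                                       n_months = 36L,
                                       condition_mix = c(AMD = 0.50,
                                                         DR = 0.30,
                                                         RVO = 0.20),
                                       age_mix = c("50-64" = 0.25,
                                                   "65-79" = 0.45,
                                                   "80+" = 0.30),
                                       first_frac = 0.08) {
  if (level <= 0) stop("level must be positive")
  streams <- rng_streams(seed, "history")
  t <- seq_len(n_months)
  eps <- if (noise_cv > 0) {
    with_stream(streams, "history", stats::rnorm(n_months, 0, noise_cv))
  } else {
    numeric(n_months)
  }
  total <- round(pmax(0, (level + trend * t) *
                        (1 + seasonal_amplitude * sin(2 * pi * t / 12)) *
                        (1 + eps)))
  cells <- expand.grid(condition = names(condition_mix),
                       appt_type = c("first", "followup"),
                       age_band = names(age_mix),
                       stringsAsFactors = FALSE)
  cells$prop <- condition_mix[cells$condition] * age_mix[cells$age_band] *
    ifelse(cells$appt_type == "first", first_frac, 1 - first_frac)
  out <- do.call(rbind, lapply(t, function(m) {
    counts <- floor(total[m] * cells$prop)
    rem <- total[m] - sum(counts)
    if (rem > 0) {
      # deterministic largest-remainder allocation
      fr <- total[m] * cells$prop - counts
      idx <- order(fr, decreasing = TRUE)[seq_len(rem)]
      counts[idx] <- counts[idx] + 1
    }
    data.frame(month = m, cells[, c("condition", "appt_type", "age_band")],
               count = counts, row.names = NULL)
  }))
  class(out) <- c("rs_history", class(out))
  out
}

mape <- function(actual, predicted) {
  keep <- actual != 0
  if (!any(keep)) return(NA_real_)
  100 * mean(abs(actual[keep] - predicted[keep]) / actual[keep])
}

fit_method <- function(method, y) {
  n <- length(y)
  if (method == "SeasonalNaive") {
    list(predict = function(h) {
      last_year <- y[seq(n - 11, n)]
      rep_len(last_year, h)
    })
  } else if (method == "LinearTrend") {
    t <- seq_len(n)
    fit <- stats::lm(y ~ t)
    list(predict = function(h) {
      as.numeric(stats::predict(fit, data.frame(t = n + seq_len(h))))
    })
  } else if (method == "ExponentialSmoothing") {
    # Holt's linear-trend exponential smoothing; falls back to simple
    # exponential smoothing when optimisation fails on degenerate series
    fit <- tryCatch(
      suppressWarnings(stats::HoltWinters(stats::ts(y, frequency = 1),
                                          gamma = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- suppressWarnings(
        stats::HoltWinters(stats::ts(y, frequency = 1), beta = FALSE,
                           gamma = FALSE))
    }
    list(predict = function(h) as.numeric(stats::predict(fit, h)))
  } else {
    stop("unknown forecast method: ", method)
  }
}

FORECAST_METHODS <- c("SeasonalNaive", "LinearTrend", "ExponentialSmoothing")

fit_one_partition <- function(y, holdout_months, horizon = 12L) {
  n <- length(y)
  train <- y[seq_len(n - holdout_months)]
  test <- y[seq(n - holdout_months + 1, n)]
  if (all(train == 0)) stop("training window is all zero; cannot fit")
  errs <- vapply(FORECAST_METHODS, function(m) {
    pred <- tryCatch(fit_method(m, train)$predict(holdout_months),
                     error = function(e) rep(NA_real_, holdout_months))
    if (any(!is.finite(pred))) return(Inf)
    mape(test, pmax(0, pred))
  }, numeric(1))
  errs[is.na(errs)] <- Inf
  # ties broken by the declared method order
  best <- FORECAST_METHODS[which.min(errs)]
  fc <- pmax(0, fit_method(best, y)$predict(horizon))
  structure(list(method = best, holdout_error = unname(errs[best]),
                 forecast = fc, candidate_errors = errs),
            class = "rs_forecast")
}

#' Fit candidate forecast models and select the best per partition
#'
#' For every partition of the historical series (condition x appointment type
#' x age band) each candidate method -- seasonal naive, linear trend and
#' exponential smoothing -- is fit on the training window, scored by MAPE on
#' the holdout window, refit on the full series, and the lowest-MAPE method's
#' 12-month forecast is returned. Ties are broken in the order SeasonalNaive,
#' LinearTrend, ExponentialSmoothing. Negative predictions are clipped to
#' zero.
#'
#' @param history A series from [generate_synthetic_history()] or read via
#'   [read_history_csv()].
#' @param holdout_months Holdout window length, between 3 and 12.
#' @param horizon Forecast horizon in months (default 12).
#' @return A list of `rs_forecast` objects keyed
#'   `condition.appt_type.age_band`, each with fields `method`,
#'   `holdout_error` (MAPE, %) and `forecast`.
#' @export
fit_and_select_forecast <- function(history, holdout_months = 6L,
                                    horizon = 12L) {
  if (holdout_months < 3 || holdout_months > 12) {
    stop("holdout_months must lie in [3, 12]")
  }
  parts <- split(history,
                 list(history$condition, history$appt_type, history$age_band),
                 drop = TRUE)
  lapply(parts, function(d) {
    d <- d[order(d$month), ]
    fit_one_partition(d$count, holdout_months, horizon)
  })
}

#' Collapse partitioned forecasts into a simulator demand series
#'
#' Age bands are summed (the simulated pathway does not differentiate by
#' age); first-appointment forecasts become the referral arrival
#' expectations and follow-up forecasts the forecast follow-up volume.
#'
#' @param fits Output of [fit_and_select_forecast()].
#' @param dna_rate Expected DNA proportion for the DNA forecast row.
#' @return A demand list with `first_appts`, `followup_appts`,
#'   `dna_expected`, as in a parameter set.
#' @export
forecast_to_demand <- function(fits, dna_rate = 0.08) {
  keys <- strsplit(names(fits), ".", fixed = TRUE)
  horizon <- length(fits[[1]]$forecast)
  rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    data.frame(month = seq_len(horizon), condition = keys[[i]][1],
               appt_type = keys[[i]][2], count = fits[[i]]$forecast)
  }))
  agg <- stats::aggregate(count ~ month + condition + appt_type, rows, sum)
  first <- agg[agg$appt_type == "first", c("month", "condition", "count")]
  fu <- agg[agg$appt_type == "followup", c("month", "condition", "count")]
  tot <- stats::aggregate(count ~ month, agg, sum)
  list(first_appts = first[order(first$month, first$condition), ],
       followup_appts = fu[order(fu$month, fu$condition), ],
       dna_expected = data.frame(month = tot$month,
                                 count = round(dna_rate * tot$count)))
}

#' Sample arrival instants for one month
#'
#' The number of referrals is Poisson with the month's expected count for the
#' condition; instants are uniform over the month's working minutes.
#'
#' @param demand A demand list (`first_appts` component is used).
#' @param month Month index within the series.
#' @param condition Condition name.
#' @param streams Random streams from [rng_streams()] (substream
#'   `"arrivals"`).
#' @param working_minutes Working minutes in the month (instants are drawn in
#'   `[0, working_minutes)`).
#' @param rate_multiplier Optional multiplier on the expected count (e.g. a
#'   scenario demand uplift).
#' @return Sorted numeric vector of arrival instants (minutes from the start
#'   of the month); empty when the expected count is zero.
#' @export
arrivals_for_month <- function(demand, month, condition, streams,
                               working_minutes = 9600,
                               rate_multiplier = 1) {
  d <- demand$first_appts
  lambda <- d$count[d$month == month & d$condition == condition]
  if (length(lambda) != 1L) stop("month/condition not in demand series")
  lambda <- lambda * rate_multiplier
  if (lambda <= 0) return(numeric(0))
  # inverse-transform Poisson so that a common uniform couples scenario
  # runs that differ only in the rate (common random numbers)
  n <- with_stream(streams, "arrivals",
                   stats::qpois(stats::runif(1), lambda))
  if (n == 0) return(numeric(0))
  sort(with_stream(streams, "arrivals", stats::runif(n, 0, working_minutes)))
}

#' Write / read a historical or demand series as tidy CSV
#'
#' @param history A history data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("month", "condition", "appt_type", "age_band", "count")
  if (!all(need %in% names(out))) {
    stop("history CSV must have columns: ", paste(need, collapse = ", "))
  }
  class(out) <- c("rs_history", class(out))
  out
}
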