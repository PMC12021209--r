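# Simulation-methodology layer: warm-up determination (Welch's moving
# average), replication sizing from pilot variance, common-random-number
# scenario comparison and reference validation.

#' Determine the warm-up period by Welch's moving-average procedure
#'
#' The KPI's monthly series is averaged across pilot replications, smoothed
#' with a centred moving average, and the warm-up is the first month after
#' which the smoothed curve stays within `margin` of its terminal value
#' (floor 1 month).
#'
#' @param pilot A matrix of KPI values (months in rows, replications in
#'   columns) or an `rs_reps` object with `kpi` naming a monthly column.
#' @param kpi Monthly KPI column when `pilot` is `rs_reps` (e.g.
#'   `"fu_att"`).
#' @param window Half-width of the moving-average window (months).
#' @param margin Relative settlement band (default 0.05).
#' @return Warm-up length in months (integer >= 1).
#' @export
determine_warmup <- function(pilot, kpi = "fu_att", window = 2L,
                             margin = 0.05) {
  if (inherits(pilot, "rs_reps")) {
    pilot <- vapply(pilot$runs, function(r) r$monthly[[kpi]],
                    numeric(nrow(pilot$runs[[1]]$monthly)))
  }
  if (ncol(pilot) < 5L) stop("need at least 5 pilot replications")
  ybar <- rowMeans(pilot)
  n <- length(ybar)
  smooth <- vapply(seq_len(n), function(t) {
    w <- min(window, t - 1L, n - t)
    mean(ybar[(t - w):(t + w)])
  }, numeric(1))
  terminal <- mean(smooth[max(1L, n - window):n])
  dev <- abs(smooth - terminal) / abs(terminal)
  settled <- rev(cumprod(rev(dev <= margin))) == 1  # within band to the end
  wu <- if (any(settled)) max(1L, which(settled)[1L] - 1L) else n
  if (wu > n / 2) {
    stop("KPI never settles within ", margin * 100,
         "% of its terminal mean in the first half of the pilot horizon; ",
         "run a longer pilot horizon")
  }
  wu
}

#' Number of replications for a target confidence-interval half-width
#'
#' Smallest n such that the t-based 95% confidence half-width, using the
#' pilot standard deviation, is at most `rel_halfwidth` times the pilot
#' mean; floored at 10 and capped at 200. A zero-variance pilot returns the
#' floor.
#'
#' @param pilot Numeric vector of a KPI's replication values.
#' @param rel_halfwidth Target relative half-width (default 0.02).
#' @param n_min,n_max Floor and cap.
#' @return Integer number of replications.
#' @export
replications_needed <- function(pilot, rel_halfwidth = 0.02, n_min = 10L,
                                n_max = 200L) {
  stopifnot(rel_halfwidth > 0)
  s <- stats::sd(pilot)
  m <- mean(pilot)
  if (s == 0 || m == 0) return(n_min)
  target <- rel_halfwidth * abs(m)
  for (n in seq(n_min, n_max)) {
    hw <- stats::qt(0.975, n - 1L) * s / sqrt(n)
    if (hw <= target) return(n)
  }
  n_max
}

#' Compare scenarios under common random numbers
#'
#' Runs every scenario with the same per-replication substream seeds, so
#' paired differences isolate the intervention effect. Percentage deltas are
#' computed on replication-mean aggregates relative to the first scenario
#' (normally SC0); paired 95% confidence intervals accompany each delta.
#'
#' @param specs List of scenario specifications (first is the reference).
#' @param params A parameter set.
#' @param n_reps Replications per scenario (>= 2).
#' @param seed Master seed shared across scenarios.
#' @return A list of class `rs_comparison`: `kpis` (data frame: scenario,
#'   kpi, mean, delta, pct_delta, ci_lo, ci_hi of the paired difference) and
#'   `summaries` (per-scenario replication summaries).
#' @export
compare_scenarios <- function(specs, params, n_reps = 30L,
                              seed = 20230401) {
  stopifnot(n_reps >= 2L)
  if (inherits(specs, "rs_scenario")) specs <- list(specs)
  reps <- lapply(specs, function(sp) {
    run_scenario(params, sp, n_reps = n_reps, seed = seed)
  })
  names(reps) <- vapply(specs, `[[`, character(1), "id")
  ref <- reps[[1L]]$summary
  kpi_cols <- setdiff(names(ref), "rep")
  rows <- list()
  for (i in seq_along(reps)) {
    s <- reps[[i]]$summary
    for (k in kpi_cols) {
      diff <- s[[k]] - ref[[k]]
      md <- mean(diff)
      se <- stats::sd(diff) / sqrt(length(diff))
      ci <- md + c(-1, 1) * stats::qt(0.975, length(diff) - 1L) * se
      refmean <- mean(ref[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = names(reps)[i], kpi = k, mean = mean(s[[k]]),
        delta = md,
        pct_delta = if (abs(refmean) > 0) 100 * md / refmean else NA_real_,
        ci_lo = ci[1L], ci_hi = ci[2L])
    }
  }
  out <- list(kpis = do.call(rbind, rows), summaries = reps,
              n_reps = n_reps, seed = seed)
  class(out) <- "rs_comparison"
  out
}

#' @export
print.rs_comparison <- function(x, ...) {
  key <- c("first_att", "fu_att", "virtual_att", "util_consultant",
           "util_nurse", "cost_gbp", "revenue_gbp")
  d <- x$kpis[x$kpis$kpi %in% key, ]
  cat("<rs_comparison>", length(x$summaries), "scenarios,", x$n_reps,
      "replications (common random numbers)\n")
  for (sc in unique(d$scenario)) {
    cat(" ", sc, "\n")
    dd <- d[d$scenario == sc, ]
    for (i in seq_len(nrow(dd))) {
      cat(sprintf("    %-16s %10.2f  (%+.1f%% vs %s)\n", dd$kpi[i],
                  dd$mean[i], dd$pct_delta[i], unique(x$kpis$scenario)[1]))
    }
  }
  invisible(x)
}

#' Extract a comparison value
#'
#' @param comparison An `rs_comparison`.
#' @param scenario Scenario id.
#' @param kpi KPI name.
#' @param what `"mean"`, `"delta"` or `"pct_delta"`.
#' @return Numeric scalar.
#' @export
comparison_value <- function(comparison, scenario, kpi,
                             what = c("mean", "delta", "pct_delta")) {
  what <- match.arg(what)
  d <- comparison$kpis
  v <- d[[what]][d$scenario == scenario & d$kpi == kpi]
  if (length(v) != 1L) stop("no such scenario/KPI in comparison")
  v
}

#' Validate simulated KPIs against a reference table
#'
#' Each KPI passes when `|simulated - reference| / |reference|` is at most
#' `margin`; KPIs with a zero reference are compared absolutely.
#'
#' @param report Named numeric vector of simulated KPI values.
#' @param reference Named numeric vector of reference values (names must
#'   match `report`).
#' @param margin Relative margin (default 0.05).
#' @return Data frame with columns `kpi`, `simulated`, `reference`,
#'   `rel_err`, `pass`; attribute `overall` is `TRUE` iff all KPIs pass.
#' @export
validate_against_reference <- function(report, reference, margin = 0.05) {
  stopifnot(margin > 0)
  kpis <- names(reference)
  if (!all(kpis %in% names(report))) {
    stop("report is missing KPIs: ",
         paste(setdiff(kpis, names(report)), collapse = ", "))
  }
  sim <- report[kpis]
  rel <- ifelse(reference != 0, abs(sim - reference) / abs(reference),
                abs(sim - reference))
  out <- data.frame(kpi = kpis, simulated = as.numeric(sim),
                    reference = as.numeric(reference),
                    rel_err = as.numeric(rel),
                    pass = as.numeric(rel) <= margin, row.names = NULL)
  attr(out, "overall") <- all(out$pass)
  out
}

#' Write per-replication KPI summaries to CSV
#'
#' @param reps An `rs_reps` from [run_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kpi_csv <- function(reps, path) {
  utils::write.csv(reps$summary, path, row.names = FALSE)
  invisible(path)
}
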