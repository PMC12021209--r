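# Cost and revenue ledgers. Staff time is costed at PSSRU hourly rates,
# activity earns national-tariff revenue, and monetary amounts are held as
# integer pence (round-half-up per entry) so ledger sums are exact.

#' Staff cost of an attendance
#'
#' Sums minutes by role times the hourly rate, in integer pence
#' (round-half-up per role entry). A DNA consumes no resource time and
#' therefore costs nothing.
#'
#' @param attendance An attendance record: either the list produced by
#'   [run_attendance()] (field `staff_minutes`) or a row of the simulation
#'   ledger (columns `consultant_min`, `nurse_min`, ...).
#' @param costs The cost schedule (`params$costs`).
#' @return Integer pence.
#' @export
#' @examples
#' p <- default_parameters()
#' att <- list(staff_minutes = c(consultant = 60))
#' cost_of(att, p$costs)  # 4864 pence
cost_of <- function(attendance, costs) {
  minutes <- attendance_minutes(attendance)
  unknown <- setdiff(names(minutes), names(costs$hourly))
  if (length(unknown)) {
    stop("unknown staff role: ", paste(unknown, collapse = ", "))
  }
  rate_pmin <- costs$hourly[names(minutes)] * 100 / 60
  as.integer(sum(round_half_up(minutes * rate_pmin)))
}

attendance_minutes <- function(attendance) {
  if (!is.null(attendance$staff_minutes)) {
    m <- attendance$staff_minutes
    return(m[m > 0])
  }
  cols <- paste0(STAFF_ROLES, "_min")
  cols <- cols[cols %in% names(attendance)]
  m <- vapply(cols, function(cl) as.numeric(attendance[[cl]]), numeric(1))
  names(m) <- sub("_min$", "", cols)
  m[m > 0]
}

#' Tariff revenue of an attendance
#'
#' First appointments earn the first-appointment tariff and follow-ups
#' (including monitoring and virtual community reviews) the follow-up
#' tariff; laser, photodynamic therapy and best-supportive-care treatments
#' add their activity tariffs. Intravitreal injections earn the attendance
#' tariff only. DNAs earn nothing.
#'
#' @param attendance An attendance record (list with `appt_type`,
#'   `outcome`, `treatment`, or a ledger row).
#' @param tariffs The tariff schedule (`params$tariffs`), GBP per activity.
#' @return Integer pence.
#' @export
revenue_of <- function(attendance, tariffs) {
  if (identical(attendance$outcome, "DNA")) return(0L)
  base <- if (identical(attendance$appt_type, "first")) {
    tariffs[["first"]]
  } else {
    tariffs[["followup"]]
  }
  extra <- switch(attendance$treatment,
                  laser = tariffs[["laser"]],
                  pdt = tariffs[["pdt"]],
                  bsc = tariffs[["bsc"]],
                  0)
  as.integer(round_half_up(100 * (base + extra)))
}

#' Monthly financial summary of a simulation run
#'
#' @param run An `rs_run` from [simulate_replication()], or an attendance
#'   ledger data frame (in which case scenario setup costs, which are not
#'   attendance-linked, are absent).
#' @return List with `monthly` (data frame: month, cost_gbp, revenue_gbp)
#'   and `total` (named vector over the reporting horizon).
#' @export
monthly_financials <- function(run) {
  if (inherits(run, "rs_run")) {
    d <- run$monthly
    monthly <- data.frame(month = d$month, reporting = d$reporting,
                          cost_gbp = d$cost_pence / 100,
                          revenue_gbp = d$revenue_pence / 100)
  } else {
    led <- run
    if (nrow(led) == 0) {
      return(list(monthly = data.frame(month = integer(0),
                                       cost_gbp = numeric(0),
                                       revenue_gbp = numeric(0)),
                  total = c(cost_gbp = 0, revenue_gbp = 0)))
    }
    cost <- tapply(led$cost_pence, led$month, sum) / 100
    rev <- tapply(led$revenue_pence, led$month, sum) / 100
    monthly <- data.frame(month = as.integer(names(cost)),
                          reporting = TRUE,
                          cost_gbp = as.numeric(cost),
                          revenue_gbp = as.numeric(rev))
  }
  rep_rows <- monthly$reporting
  list(monthly = monthly[, c("month", "cost_gbp", "revenue_gbp")],
       total = c(cost_gbp = sum(monthly$cost_gbp[rep_rows]),
                 revenue_gbp = sum(monthly$revenue_gbp[rep_rows])))
}

#' Recompute ledger totals independently from the attendance CSV
#'
#' Conservation check: total revenue must equal the sum over attendances of
#' their tariffs, and total staff cost the sum of minutes times rates, both
#' recomputed row by row from first principles (not from the stored pence
#' columns).
#'
#' @param ledger Attendance ledger data frame (from an `rs_run`, possibly
#'   round-tripped through CSV).
#' @param params The parameter set that produced it.
#' @return Named vector: `cost_pence`, `revenue_pence`.
#' @export
recompute_ledger_totals <- function(ledger, params) {
  cost <- 0L; rev <- 0L
  for (i in seq_len(nrow(ledger))) {
    row <- as.list(ledger[i, ])
    cost <- cost + cost_of(row, params$costs)
    rev <- rev + revenue_of(row, params$tariffs)
  }
  c(cost_pence = cost, revenue_pence = rev)
}

#' Write an attendance ledger to CSV
#'
#' @param run An `rs_run` with a ledger, or a ledger data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(run, path) {
  led <- if (inherits(run, "rs_run")) run$ledger else run
  if (is.null(led)) stop("run has no ledger (keep_ledger = FALSE?)")
  utils::write.csv(led, path, row.names = FALSE)
  invisible(path)
}
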