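test_that("staff costing follows the hourly rates in integer pence", {
  p <- default_parameters()
  expect_equal(cost_of(list(staff_minutes = c(consultant = 60)), p$costs),
               4864L)
  # nurse 30 min + healthcare assistant 30 min: 714 + 493 pence
  expect_equal(cost_of(list(staff_minutes = c(nurse = 30, hca = 30)),
                       p$costs), 1207L)
  expect_equal(cost_of(list(staff_minutes = c(consultant = 0)), p$costs), 0L)
  expect_error(cost_of(list(staff_minutes = c(surgeon = 10)), p$costs),
               "unknown staff role")
  # ledger-row form
  row <- list(consultant_min = 60, nurse_min = 0, technician_min = 0,
              hca_min = 0, photographer_min = 0)
  expect_equal(cost_of(row, p$costs), 4864L)
})

test_that("revenue is tariff additivity over attendance and treatment", {
  p <- default_parameters()
  expect_equal(revenue_of(list(appt_type = "first", outcome = "Attended",
                               treatment = "none"), p$tariffs), 11200L)
  expect_equal(revenue_of(list(appt_type = "followup", outcome = "Attended",
                               treatment = "laser"), p$tariffs),
               (63 + 292) * 100L)
  expect_equal(revenue_of(list(appt_type = "followup", outcome = "Attended",
                               treatment = "pdt"), p$tariffs),
               (63 + 107) * 100L)
  expect_equal(revenue_of(list(appt_type = "first", outcome = "Attended",
                               treatment = "bsc"), p$tariffs),
               (112 + 112) * 100L)
  # injections earn the attendance tariff only
  expect_equal(revenue_of(list(appt_type = "followup", outcome = "Attended",
                               treatment = "injection"), p$tariffs), 6300L)
  # DNAs earn nothing
  expect_equal(revenue_of(list(appt_type = "followup", outcome = "DNA",
                               treatment = "none"), p$tariffs), 0L)
})

test_that("monthly financial summaries add up", {
  empty <- data.frame(month = integer(0), cost_pence = integer(0),
                      revenue_pence = integer(0))
  fin <- monthly_financials(empty)
  expect_equal(unname(fin$total), c(0, 0))

  two <- data.frame(month = c(1L, 1L), cost_pence = c(0L, 0L),
                    revenue_pence = c(6300L, 6300L))
  expect_equal(unname(monthly_financials(two)$total[["revenue_gbp"]]), 126)
})

test_that("ledger totals are conserved under independent re-aggregation", {
  p <- tiny_params()
  r <- simulate_replication(p, scenario_spec("SC2"), seed = 5,
                            keep_ledger = TRUE)
  # re-derive every row's cost and revenue from rates and tariffs
  tot <- recompute_ledger_totals(r$ledger, p)
  expect_identical(unname(tot[["cost_pence"]]), sum(r$ledger$cost_pence))
  expect_identical(unname(tot[["revenue_pence"]]),
                   sum(r$ledger$revenue_pence))
  # the monthly KPI financials equal ledger sums plus the setup cost
  setup <- round(100 * p$costs$virtual_setup_cost_monthly) *
    nrow(r$monthly)
  expect_equal(sum(r$monthly$cost_pence), sum(r$ledger$cost_pence) + setup)
  expect_equal(sum(r$monthly$revenue_pence), sum(r$ledger$revenue_pence))
  # DNAs carry no money
  dna <- r$ledger[r$ledger$outcome == "DNA", ]
  expect_true(all(dna$cost_pence == 0 & dna$revenue_pence == 0))
})

test_that("the attendance ledger survives a CSV round-trip", {
  p <- tiny_params()
  r <- simulate_replication(p, scenario_spec("SC0"), seed = 9,
                            keep_ledger = TRUE)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_ledger_csv(r, tmp)
  led <- utils::read.csv(tmp)
  expect_equal(nrow(led), nrow(r$ledger))
  tot <- recompute_ledger_totals(led, p)
  expect_equal(unname(tot[["revenue_pence"]]), sum(r$ledger$revenue_pence))
})
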