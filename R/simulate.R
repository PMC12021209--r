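# The retinal-service simulation engine: a monthly booking cycle over the
# weekly clinic template. Follow-up demand is endogenous (each patient's
# regimen generates appointments); first appointments are booked from a
# referral-fed waiting list into residual consultant capacity; stable
# monitoring reviews take what capacity remains (or the community virtual
# clinic when a scenario enables it). Did-not-attends rebook. Resource pools
# accrue busy/open time for utilisation KPIs and every attendance posts
# staff-cost and tariff-revenue ledger entries.

STATE_ACTIVE <- 1L
STATE_MONITORING <- 2L
STATE_DISCHARGED <- 3L

POOL_NAMES <- c("consultant", "nurse", "technician", "hca", "photographer",
                "slitlamp", "angiography", "oct", "injection_bed", "theatre",
                "consultation_room")

# uniform accounting months of 52/12 weeks, so 12 months = 52 weeks exactly
weeks_in_month <- function(m) rep_len(52 / 12, length(m))

round_half_up <- function(x) floor(x + 0.5)

#' Run one replication of the retinal-service simulation
#'
#' Simulates `warmup_months + horizon_months` months of the service under a
#' scenario, returning monthly KPI series, pool utilisations, the
#' attendance-level ledger and financial totals. Fully deterministic given
#' `seed`: all randomness flows through named substreams, so two runs with
#' the same seed and configuration produce identical ledgers, and scenario
#' runs sharing a seed are coupled (common random numbers).
#'
#' @param params A parameter set ([default_parameters()] or
#'   [load_parameters()]).
#' @param scenario A scenario from [scenario_spec()]; default baseline SC0.
#' @param seed Integer replication seed.
#' @param keep_ledger Keep the attendance-level ledger (default `TRUE`).
#' @return A list of class `rs_run`: `monthly` (data frame of per-month
#'   KPIs, with `reporting` flagging post-warm-up months), `ledger`
#'   (attendance rows) and `scenario`.
#' @export
simulate_replication <- function(params, scenario = scenario_spec("SC0"),
                                 seed = 1L, keep_ledger = TRUE) {
  if (!identical(params$scenario, scenario)) {
    params <- apply_scenario(params, scenario)
  }
  scenario <- params$scenario
  st <- params$service_times
  bk <- params$booking
  rs <- params$resources
  streams <- rng_streams(seed)
  n_months <- params$warmup_months + params$horizon_months
  dm_idx <- function(m) ((m - params$warmup_months - 1L) %%
                           nrow(params$demand$dna_expected)) + 1L
  week_min <- rs$working_days_per_week * rs$day_length_hours * 60
  session_week_min <- rs$clinics_per_week * rs$session_length_hours * 60
  share <- scenario$nurse_injection_share
  # monthly virtual-clinic capacity from the diversion rate and the
  # forecast follow-up volume
  fu_forecast_mean <- sum(params$demand$followup_appts$count) /
    length(unique(params$demand$followup_appts$month))
  v_cap <- if (scenario$virtual_clinic) {
    round(scenario$virtual_diversion_rate * fu_forecast_mean)
  } else 0L

  # expected attended consultant minutes per booking, for capacity planning
  p_inj <- vapply(CONDITIONS,
                  function(cn) params$treatment_mix[[cn]][["injection"]],
                  numeric(1))
  att_p <- 1 - st$dna_rate
  p_laser <- vapply(CONDITIONS,
                    function(cn) params$treatment_mix[[cn]][["laser"]],
                    numeric(1))
  p_pdt <- vapply(CONDITIONS,
                  function(cn) params$treatment_mix[[cn]][["pdt"]],
                  numeric(1))
  fu_exp_cons <- st$followup_consult_min +
    p_inj * (1 - share) * st$injection_consultant_min +
    p_laser * st$laser_min + p_pdt * st$pdt_min
  first_exp_cons <- st$first_consult_min
  mon_exp_cons <- st$followup_consult_min

  # ---- patient state vectors ------------------------------------------------
  n0 <- bk$initial_caseload
  nm0 <- round(params$monitoring$pool_ratio * n0)
  cap <- n0 + nm0 + bk$initial_waiting_list + 200L * n_months + 500L
  cond <- integer(cap); year <- integer(cap)
  fu_total <- integer(cap); fu_done <- integer(cap)
  state <- integer(cap)
  next_due <- rep(Inf, cap); mon_next <- rep(Inf, cap)
  dna_streak <- integer(cap)
  n_pat <- 0L

  sample_regimen <- function(conds, years) {
    out <- integer(length(conds))
    for (cn in CONDITIONS) for (yr in 1:3) {
      idx <- which(conds == cn & pmin(years, 3L) == yr)
      if (length(idx)) {
        out[idx] <- sample_followup_count(params$conditions[[cn]], yr,
                                          streams, n = length(idx))
      }
    }
    out
  }
  cond_names <- function(ci) CONDITIONS[ci]

  # warm-start caseload: patients mid-regimen, mixed over treatment years
  if (n0 > 0) {
    idx <- seq_len(n0); n_pat <- n0
    cond[idx] <- with_stream(streams, "init",
                             sample.int(3L, n0, replace = TRUE,
                                        prob = params$condition_mix))
    ym <- params$conditions[[1]]$year_mix
    year[idx] <- with_stream(streams, "init",
                             sample.int(3L, n0, replace = TRUE, prob = ym))
    fu_total[idx] <- sample_regimen(cond_names(cond[idx]), year[idx])
    fu_done[idx] <- with_stream(streams, "init",
                                floor(stats::runif(n0) * fu_total[idx]))
    state[idx] <- STATE_ACTIVE
    # spread initial due dates so the opening appointment flow matches the
    # sustainable operating point rather than the nominal regimen rate
    mean_fu_year <- sum(vapply(CONDITIONS, function(cn) {
      cp <- params$conditions[[cn]]
      params$condition_mix[[cn]] * sum(cp$year_mix * cp$followups_per_year)
    }, numeric(1)))
    stretch_a <- max(1, (n0 * mean_fu_year / 12) /
                       (bk$active_flow_frac * fu_forecast_mean))
    next_due[idx] <- with_stream(
      streams, "init",
      stats::runif(n0, 1, 1 + stretch_a * 12 / fu_total[idx]))
  }
  if (nm0 > 0) {
    idx <- n_pat + seq_len(nm0); n_pat <- n_pat + nm0
    cond[idx] <- with_stream(streams, "init",
                             sample.int(3L, nm0, replace = TRUE,
                                        prob = params$condition_mix))
    year[idx] <- 3L
    state[idx] <- STATE_MONITORING
    stretch_m <- max(1, (nm0 / params$monitoring$review_interval_months) /
                       bk$review_slots_per_month)
    mon_next[idx] <- with_stream(
      streams, "init",
      stats::runif(nm0, 1, 1 + stretch_m *
                     params$monitoring$review_interval_months))
  }

  # waiting list (FIFO)
  wl_cond <- with_stream(streams, "init",
                         sample.int(3L, bk$initial_waiting_list,
                                    replace = TRUE,
                                    prob = params$condition_mix))
  wl_arrival <- rep(0, bk$initial_waiting_list)
  wl_streak <- integer(bk$initial_waiting_list)

  monthly <- vector("list", n_months)
  ledgers <- vector("list", n_months)
  t_month_start <- 0

  draw_minutes <- function(n, mean) {
    if (n == 0L) return(numeric(0))
    with_stream(streams, "durations", rlnorm_mean_cv(n, mean, st$duration_cv))
  }

  for (m in seq_len(n_months)) {
    w <- weeks_in_month(m)
    open_min <- week_min * w
    session_min <- session_week_min * w
    dmi <- dm_idx(m)

    # --- referral arrivals ---------------------------------------------------
    for (ci in seq_along(CONDITIONS)) {
      inst <- arrivals_for_month(params$demand, dmi, CONDITIONS[ci], streams,
                                 working_minutes = open_min)
      n_new <- length(inst)
      if (n_new) {
        wl_cond <- c(wl_cond, rep(ci, n_new))
        wl_arrival <- c(wl_arrival, rep(m, n_new) - 1 + inst / open_min)
        wl_streak <- c(wl_streak, integer(n_new))
      }
    }

    # --- booking -------------------------------------------------------------
    budget <- bk$capacity_fraction * rs$staff_counts[["consultant"]] * open_min
    due_a <- which(state == STATE_ACTIVE & next_due < m + 1)
    due_a <- due_a[order(next_due[due_a])]
    loads <- att_p * fu_exp_cons[cond[due_a]]
    cum <- cumsum(loads)
    n_act <- sum(cum <= budget)
    booked_fu <- due_a[seq_len(n_act)]
    resid <- budget - if (n_act > 0) cum[n_act] else 0

    # consultant minutes released by nurse injectors are re-invested in the
    # slot template: mostly new-patient slots (released capacity is consumed
    # by the waiting list), the rest as review catch-up slots
    freed_inj <- share * att_p * st$injection_consultant_min *
      sum(p_inj[cond[booked_fu]])
    fshare <- bk$released_capacity_first_share
    slot_load <- min(resid, bk$new_slot_share * max(0, resid - freed_inj) +
                       fshare * freed_inj)
    slots <- floor(max(0, slot_load) / (att_p * first_exp_cons))
    n_first_booked <- min(length(wl_cond), max(0L, slots))
    first_pick <- seq_len(n_first_booked)

    resid2 <- resid - n_first_booked * att_p * first_exp_cons
    due_m <- which(state == STATE_MONITORING & mon_next < m + 1)
    due_m <- due_m[order(mon_next[due_m])]
    if (scenario$virtual_clinic) {
      n_virt <- min(length(due_m), v_cap)
      booked_virt <- due_m[seq_len(n_virt)]
      deferred_m <- due_m[-seq_len(n_virt)]
      booked_mon <- integer(0)
    } else {
      review_slots <- bk$review_slots_per_month +
        floor((1 - fshare) * freed_inj / (att_p * mon_exp_cons))
      n_sh <- min(length(due_m), review_slots,
                  max(0L, floor(resid2 / (att_p * mon_exp_cons))))
      booked_mon <- due_m[seq_len(n_sh)]
      deferred_m <- due_m[-seq_len(n_sh)]
      booked_virt <- integer(0)
    }
    if (length(deferred_m)) mon_next[deferred_m] <- mon_next[deferred_m] + 1

    # --- hospital attendances: DNA realisation -------------------------------
    n_fu <- length(booked_fu); n_fi <- n_first_booked
    n_mo <- length(booked_mon)
    n_hosp <- n_fu + n_fi + n_mo
    u_dna <- with_stream(streams, "dna", stats::runif(n_hosp))
    streaks <- c(dna_streak[booked_fu], wl_streak[first_pick],
                 dna_streak[booked_mon])
    is_dna <- u_dna < st$dna_rate & streaks < st$max_rebooks
    dna_fu <- is_dna[seq_len(n_fu)]
    dna_fi <- is_dna[n_fu + seq_len(n_fi)]
    dna_mo <- is_dna[n_fu + n_fi + seq_len(n_mo)]

    # DNA bookkeeping: missed appointments stay due and rebook next month
    dna_streak[booked_fu[dna_fu]] <- dna_streak[booked_fu[dna_fu]] + 1L
    dna_streak[booked_fu[!dna_fu]] <- 0L
    dna_streak[booked_mon[dna_mo]] <- dna_streak[booked_mon[dna_mo]] + 1L
    dna_streak[booked_mon[!dna_mo]] <- 0L
    mon_next[booked_mon[dna_mo]] <- m + 0.99  # rebook next month
    att_fu <- booked_fu[!dna_fu]
    att_mon <- booked_mon[!dna_mo]

    # first attendances: admit the attendees, re-queue the DNAs at the head
    att_first_cond <- wl_cond[first_pick][!dna_fi]
    att_first_arr <- wl_arrival[first_pick][!dna_fi]
    n_fa <- length(att_first_cond)
    keep_head_cond <- wl_cond[first_pick][dna_fi]
    keep_head_arr <- wl_arrival[first_pick][dna_fi]
    keep_head_streak <- wl_streak[first_pick][dna_fi] + 1L
    if (n_first_booked > 0) {
      wl_cond <- c(keep_head_cond, wl_cond[-first_pick])
      wl_arrival <- c(keep_head_arr, wl_arrival[-first_pick])
      wl_streak <- c(keep_head_streak, wl_streak[-first_pick])
    }
    new_ids <- integer(0)
    if (n_fa > 0) {
      if (n_pat + n_fa > cap) stop("patient capacity exceeded")
      new_ids <- n_pat + seq_len(n_fa)
      n_pat <- n_pat + n_fa
      cond[new_ids] <- att_first_cond
      year[new_ids] <- 1L
      fu_total[new_ids] <- sample_regimen(cond_names(att_first_cond),
                                          rep(1L, n_fa))
      fu_done[new_ids] <- 0L
      state[new_ids] <- STATE_ACTIVE
      next_due[new_ids] <- m + 12 / fu_total[new_ids]
    }

    # --- attended hospital activity ------------------------------------------
    att_ids <- c(att_fu, new_ids, att_mon)
    att_type <- c(rep("followup", length(att_fu)), rep("first", n_fa),
                  rep("monitoring", length(att_mon)))
    n_att <- length(att_ids)

    diag_mat <- if (n_att) diagnostics_battery(params$diagnostics, streams,
                                               n = n_att)
      else matrix(FALSE, 0, 4, dimnames = list(NULL, DIAG_TESTS))
    # actual minutes per performed test
    diag_min <- matrix(0, n_att, 4, dimnames = list(NULL, DIAG_TESTS))
    for (tst in DIAG_TESTS) {
      idx <- which(diag_mat[, tst])
      diag_min[idx, tst] <- draw_minutes(
        length(idx), params$diagnostics$minutes_per_test[[tst]])
    }
    consult_mean <- ifelse(att_type == "first", st$first_consult_min,
                           st$followup_consult_min)
    consult_min <- draw_minutes(n_att, 1) * consult_mean

    treatment <- rep("none", n_att)
    injector <- rep(NA_character_, n_att)
    idx_fu <- which(att_type == "followup")
    if (length(idx_fu)) {
      tr <- draw_treatment(cond_names(cond[att_ids[idx_fu]]), params,
                           streams, nurse_injection_share = share,
                           n = length(idx_fu))
      treatment[idx_fu] <- tr$treatment
      injector[idx_fu] <- tr$injector
    }
    inj_min <- numeric(n_att); laser_min <- numeric(n_att)
    pdt_min <- numeric(n_att)
    ic <- which(treatment == "injection" & injector == "consultant")
    inj_min[ic] <- draw_minutes(length(ic), st$injection_consultant_min)
    inn <- which(treatment == "injection" & injector == "nurse")
    inj_min[inn] <- draw_minutes(length(inn), st$injection_nurse_min)
    il <- which(treatment == "laser")
    laser_min[il] <- draw_minutes(length(il), st$laser_min)
    ip <- which(treatment == "pdt")
    pdt_min[ip] <- draw_minutes(length(ip), st$pdt_min)

    # --- virtual community reviews -------------------------------------------
    n_virt_att <- length(booked_virt)
    virt_min <- draw_minutes(n_virt_att, st$virtual_review_min)
    virt_oct <- draw_minutes(n_virt_att,
                             params$diagnostics$minutes_per_test[["oct"]])

    # --- patient-state updates -----------------------------------------------
    if (length(att_fu)) {
      fu_done[att_fu] <- fu_done[att_fu] + 1L
      yend <- att_fu[fu_done[att_fu] >= fu_total[att_fu]]
      ongoing <- setdiff(att_fu, yend)
      next_due[ongoing] <- m + 12 / fu_total[ongoing]
      if (length(yend)) {
        yr3 <- pmin(year[yend], 3L)
        p_dis <- vapply(seq_along(yend), function(i) {
          params$conditions[[cond[yend[i]]]]$
            discharge_prob_at_year_end[[yr3[i]]]
        }, numeric(1))
        u <- with_stream(streams, "routing", stats::runif(length(yend)))
        dis <- u < p_dis
        tomon <- !dis & u < p_dis + params$monitoring$transition_prob
        adv <- !dis & !tomon
        state[yend[dis]] <- STATE_DISCHARGED
        next_due[yend[dis]] <- Inf
        state[yend[tomon]] <- STATE_MONITORING
        next_due[yend[tomon]] <- Inf
        mon_next[yend[tomon]] <- m + params$monitoring$review_interval_months
        if (any(adv)) {
          ids <- yend[adv]
          year[ids] <- year[ids] + 1L
          fu_total[ids] <- sample_regimen(cond_names(cond[ids]),
                                          pmin(year[ids], 3L))
          fu_done[ids] <- 0L
          next_due[ids] <- m + 12 / fu_total[ids]
        }
      }
    }
    mon_seen <- c(att_mon, booked_virt)
    if (length(mon_seen)) {
      u <- with_stream(streams, "routing", stats::runif(length(mon_seen)))
      react <- u < params$monitoring$reactivation_prob
      mdis <- !react & u < params$monitoring$reactivation_prob +
        params$monitoring$discharge_prob
      stay <- !react & !mdis
      if (any(react)) {
        ids <- mon_seen[react]
        state[ids] <- STATE_ACTIVE
        year[ids] <- 3L
        fu_total[ids] <- sample_regimen(cond_names(cond[ids]),
                                        rep(3L, length(ids)))
        fu_done[ids] <- 0L
        next_due[ids] <- m + 12 / fu_total[ids]
        mon_next[ids] <- Inf
      }
      state[mon_seen[mdis]] <- STATE_DISCHARGED
      mon_next[mon_seen[mdis]] <- Inf
      mon_next[mon_seen[stay]] <- m +
        params$monitoring$review_interval_months
    }

    # --- resource accounting -------------------------------------------------
    busy <- stats::setNames(numeric(length(POOL_NAMES)), POOL_NAMES)
    staff_min <- matrix(0, max(n_att, 1L), length(STAFF_ROLES),
                        dimnames = list(NULL, STAFF_ROLES))
    if (n_att) {
      for (tst in DIAG_TESTS) {
        role <- params$diagnostics$staffing[[tst]]
        staff_min[, role] <- staff_min[, role] + diag_min[, tst]
      }
      staff_min[, "consultant"] <- staff_min[, "consultant"] + consult_min
      staff_min[ic, "consultant"] <- staff_min[ic, "consultant"] +
        inj_min[ic]
      staff_min[inn, "nurse"] <- staff_min[inn, "nurse"] + inj_min[inn]
      # lasers and PDT are consultant-delivered theatre procedures
      staff_min[, "consultant"] <- staff_min[, "consultant"] + laser_min +
        pdt_min
      busy["consultant"] <- sum(staff_min[, "consultant"])
      busy["technician"] <- sum(staff_min[, "technician"])
      busy["hca"] <- sum(staff_min[, "hca"])
      busy["photographer"] <- sum(staff_min[, "photographer"])
      busy["slitlamp"] <- sum(diag_min[, "slitlamp"])
      busy["angiography"] <- sum(diag_min[, "angiography"])
      busy["oct"] <- sum(diag_min[, "oct"])
      busy["injection_bed"] <- sum(inj_min)
      busy["theatre"] <- sum(laser_min) + sum(pdt_min)
      busy["consultation_room"] <- sum(consult_min)
    }
    nurse_clinic <- st$nurse_session_cover * session_min
    busy["nurse"] <- nurse_clinic + sum(inj_min[inn]) + sum(virt_min)
    busy["oct"] <- busy["oct"] + sum(virt_oct)

    open_by_pool <- c(
      consultant = rs$staff_counts[["consultant"]],
      nurse = rs$staff_counts[["nurse"]],
      technician = rs$staff_counts[["technician"]],
      hca = rs$staff_counts[["hca"]],
      photographer = rs$staff_counts[["photographer"]],
      slitlamp = params$diagnostics$equipment_count[["slitlamp"]],
      angiography = params$diagnostics$equipment_count[["angiography"]],
      oct = params$diagnostics$equipment_count[["oct"]],
      injection_bed = rs$physical_counts[["injection_bed"]],
      theatre = rs$physical_counts[["theatre"]],
      consultation_room = rs$physical_counts[["consultation_room"]]
    ) * open_min
    util <- ifelse(open_by_pool > 0, busy / open_by_pool, NA_real_)

    # --- ledger and financials -----------------------------------------------
    rate_pmin <- params$costs$hourly * 100 / 60  # pence per minute
    tariff_p <- params$tariffs * 100
    cost_p <- integer(0); rev_p <- integer(0)
    if (n_att) {
      cost_mat <- sweep(staff_min, 2L, rate_pmin[STAFF_ROLES], "*")
      cost_p <- as.integer(rowSums(round_half_up(cost_mat)))
      rev_p <- as.integer(
        ifelse(att_type == "first", tariff_p[["first"]],
               tariff_p[["followup"]]) +
          ifelse(treatment == "laser", tariff_p[["laser"]],
                 ifelse(treatment == "pdt", tariff_p[["pdt"]],
                        ifelse(treatment == "bsc", tariff_p[["bsc"]], 0))))
    }
    virt_cost_p <- as.integer(round_half_up(virt_min *
                                              rate_pmin[["nurse"]]))
    virt_rev_p <- rep(as.integer(tariff_p[["followup"]]), n_virt_att)
    setup_p <- if (scenario$virtual_clinic) {
      as.integer(round_half_up(100 * scenario$virtual_setup_cost_monthly))
    } else 0L

    n_dna <- sum(is_dna)
    led <- NULL
    if (keep_ledger) {
      # attendance rows (attended + DNA), then virtual reviews
      dna_ids <- c(booked_fu[dna_fu],
                   rep(NA_integer_, sum(dna_fi)), booked_mon[dna_mo])
      dna_type <- c(rep("followup", sum(dna_fu)),
                    rep("first", sum(dna_fi)),
                    rep("monitoring", sum(dna_mo)))
      dna_cond_i <- c(cond[booked_fu[dna_fu]], keep_head_cond,
                      cond[booked_mon[dna_mo]])
      slot_t <- if (n_att + n_dna + n_virt_att > 0) {
        t_month_start + session_min *
          (seq_len(n_att + n_dna + n_virt_att) - 1) /
          max(1L, n_att + n_dna + n_virt_att)
      } else numeric(0)
      led <- data.frame(
        month = rep(m, n_att + n_dna + n_virt_att),
        time_min = slot_t,
        patient = c(att_ids, dna_ids, booked_virt),
        appt_type = c(att_type, dna_type, rep("virtual", n_virt_att)),
        mode = c(rep("FaceToFace", n_att + n_dna),
                 rep("VirtualCommunity", n_virt_att)),
        condition = CONDITIONS[c(cond[att_ids], dna_cond_i,
                                 cond[booked_virt])],
        outcome = c(rep("Attended", n_att), rep("DNA", n_dna),
                    rep("Attended", n_virt_att)),
        treatment = c(treatment, rep("none", n_dna),
                      rep("none", n_virt_att)),
        injector = c(injector, rep(NA_character_, n_dna + n_virt_att)),
        consultant_min = c(if (n_att) staff_min[, "consultant"] else
          numeric(0), numeric(n_dna), numeric(n_virt_att)),
        nurse_min = c(if (n_att) staff_min[, "nurse"] else numeric(0),
                      numeric(n_dna), virt_min),
        technician_min = c(if (n_att) staff_min[, "technician"] else
          numeric(0), numeric(n_dna), numeric(n_virt_att)),
        hca_min = c(if (n_att) staff_min[, "hca"] else numeric(0),
                    numeric(n_dna), numeric(n_virt_att)),
        photographer_min = c(if (n_att) staff_min[, "photographer"] else
          numeric(0), numeric(n_dna), numeric(n_virt_att)),
        cost_pence = c(cost_p, integer(n_dna), virt_cost_p),
        revenue_pence = c(rev_p, integer(n_dna), virt_rev_p),
        stringsAsFactors = FALSE
      )
    }

    wait_days <- if (n_fa > 0) mean(m - att_first_arr) * 365.25 / 12 else
      NA_real_
    monthly[[m]] <- data.frame(
      month = m, reporting = m > params$warmup_months, weeks = w,
      first_att = n_fa,
      fu_att = length(att_fu) + length(att_mon),
      fu_active_att = length(att_fu),
      fu_monitoring_att = length(att_mon),
      virtual_att = n_virt_att,
      dna = n_dna,
      demand_active_due = length(due_a),
      demand_monitoring_due = length(due_m),
      deferred_active = length(due_a) - n_act,
      deferred_reviews = length(deferred_m),
      waiting_list = length(wl_cond),
      wait_days = wait_days,
      diag_logmar = sum(diag_mat[, "logmar"]),
      diag_slitlamp = sum(diag_mat[, "slitlamp"]),
      diag_angiography = sum(diag_mat[, "angiography"]),
      diag_oct = sum(diag_mat[, "oct"]) + n_virt_att,
      inj_consultant = length(ic), inj_nurse = length(inn),
      laser = length(il), pdt = length(ip),
      bsc = sum(treatment == "bsc"),
      util_consultant = util[["consultant"]],
      util_nurse = util[["nurse"]],
      util_technician = util[["technician"]],
      util_hca = util[["hca"]],
      util_photographer = util[["photographer"]],
      util_slitlamp = util[["slitlamp"]],
      util_angiography = util[["angiography"]],
      util_oct = util[["oct"]],
      util_injection_bed = util[["injection_bed"]],
      util_theatre = util[["theatre"]],
      util_consultation_room = util[["consultation_room"]],
      active_patients = sum(state == STATE_ACTIVE),
      monitoring_patients = sum(state == STATE_MONITORING),
      discharged_patients = sum(state == STATE_DISCHARGED),
      admitted = n_fa,
      cost_pence = sum(cost_p) + sum(virt_cost_p) + setup_p,
      revenue_pence = sum(rev_p) + sum(virt_rev_p)
    )
    ledgers[[m]] <- led
    t_month_start <- t_month_start + open_min
  }

  out <- list(monthly = do.call(rbind, monthly),
              ledger = if (keep_ledger) do.call(rbind, ledgers) else NULL,
              scenario = scenario, seed = seed)
  class(out) <- "rs_run"
  out
}

#' @export
print.rs_run <- function(x, ...) {
  rep_m <- x$monthly[x$monthly$reporting, ]
  cat("<rs_run> scenario", x$scenario$id, "seed", x$seed, "\n")
  cat(sprintf("  mean monthly: %.1f first, %.1f follow-up, %.1f virtual\n",
              mean(rep_m$first_att), mean(rep_m$fu_att),
              mean(rep_m$virtual_att)))
  cat(sprintf("  utilisation: consultant %.1f%%, nurse %.1f%%\n",
              100 * mean(rep_m$util_consultant),
              100 * mean(rep_m$util_nurse)))
  invisible(x)
}

#' Run replicated simulations of one scenario
#'
#' @param params A parameter set.
#' @param scenario A scenario specification.
#' @param n_reps Number of replications.
#' @param seed Master seed; replication r uses substreams derived from
#'   `seed` and `r`, identical across scenarios (common random numbers).
#' @param keep_ledger Keep per-replication attendance ledgers.
#' @return A list of class `rs_reps` with `runs` (list of `rs_run`) and
#'   `summary` (data frame of replication-level aggregates from
#'   [kpi_aggregate()]).
#' @export
run_scenario <- function(params, scenario = scenario_spec("SC0"),
                         n_reps = 30L, seed = 20230401, keep_ledger = FALSE) {
  runs <- lapply(seq_len(n_reps), function(r) {
    simulate_replication(params, scenario,
                         seed = rep_seed(seed, r),
                         keep_ledger = keep_ledger)
  })
  summ <- do.call(rbind, lapply(seq_along(runs), function(r) {
    cbind(rep = r, kpi_aggregate(runs[[r]]))
  }))
  structure(list(runs = runs, summary = summ, scenario = scenario),
            class = "rs_reps")
}

# replication seeds stay below 2^31
rep_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + r * 104729) %% 2147483647)
}

#' Aggregate a replication's monthly KPIs over the reporting horizon
#'
#' Warm-up months are excluded. Count KPIs are averaged per month;
#' utilisations are averaged over months; cost and revenue are reported as
#' 12-month totals in GBP.
#'
#' @param run An `rs_run` from [simulate_replication()].
#' @return One-row data frame of aggregate KPIs.
#' @export
kpi_aggregate <- function(run) {
  d <- run$monthly[run$monthly$reporting, ]
  data.frame(
    first_att = mean(d$first_att),
    fu_att = mean(d$fu_att),
    virtual_att = mean(d$virtual_att),
    total_att = mean(d$first_att + d$fu_att + d$virtual_att),
    dna = mean(d$dna),
    diag_oct = mean(d$diag_oct),
    diag_angiography = mean(d$diag_angiography),
    injections = mean(d$inj_consultant + d$inj_nurse),
    inj_nurse = mean(d$inj_nurse),
    laser = mean(d$laser),
    pdt = mean(d$pdt),
    util_consultant = mean(d$util_consultant),
    util_nurse = mean(d$util_nurse),
    util_oct = mean(d$util_oct),
    util_injection_bed = mean(d$util_injection_bed),
    wait_days = mean(d$wait_days, na.rm = TRUE),
    waiting_list = mean(d$waiting_list),
    fu_due = mean(d$demand_active_due + d$demand_monitoring_due),
    fu_active_att = mean(d$fu_active_att),
    deferred = mean(d$deferred_reviews),
    deferred_active = mean(d$deferred_active),
    monitoring_patients = mean(d$monitoring_patients),
    cost_gbp = sum(d$cost_pence) / 100,
    revenue_gbp = sum(d$revenue_pence) / 100
  )
}
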