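---
title: "Modelling a hospital retinal service: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a hospital retinal service: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`retinasim` simulates the operation of an NHS hospital retinal service —
the outpatient pathway treating age-related macular degeneration (AMD),
diabetic retinopathy (DR) and retinal vein occlusion (RVO) — inside an
integrated care system, and evaluates service-redesign scenarios: nurse
injectors, growth in DR referrals, and a nurse-led community virtual clinic
for stable patients. This vignette describes the model, its assumptions,
the calibration procedure and the design decisions a reader needs in order
to interpret (and to distrust, where appropriate) its outputs.

## The service model

Patients are referred by optometrists and GPs onto a waiting list. A first
appointment delivers a diagnostics battery (LogMAR visual acuity and slit
lamp on every attendance; fundus angiography for 20% and OCT imaging for
70% of attendances) and a consultant consultation, after which the patient
starts a condition-specific treatment regimen: AMD patients need on average
5, 4 and 4 follow-up appointments in treatment years 1–3, DR and RVO
patients 4, 3 and 3 (lognormal variation, coefficient of variation 0.3,
rounded, at least one). Follow-up attendances deliver treatment —
intravitreal injections for most AMD/RVO attendances, a mix of injections,
laser and photodynamic therapy for DR — on an injection bed or in the
theatre. At the end of each treatment year a small fraction of patients is
discharged (5%, 2%, 1% for years 1–3); of the remainder, some advance to
the next treatment year and re-draw a regimen, and some become *stable*
and move to periodic monitoring, the population a community virtual clinic
can serve. Booked appointments are missed ("did not attend", DNA) with
probability 0.08 and rebook after about two weeks, at most twice in a row.

Time advances in a monthly booking cycle over a weekly clinic template (33
four-hour sessions across five working days). Each month the service:

1. books every active-treatment follow-up that has come due, up to a
   consultant-capacity ceiling (98.5% of consultant minutes);
2. books new patients from the waiting list into new-patient slots — a
   configurable share of the consultant capacity remaining after treatment
   work;
3. books stable-monitoring reviews into a fixed template of review slots,
   deferring the surplus to the following month (or diverts them to the
   virtual clinic when a scenario enables it).

Attended appointments draw lognormal service times, seize the diagnostics
equipment, consultation rooms, injection bed or theatre, and post
staff-minute costs (PSSRU hourly rates) and national-tariff revenue (first
appointment £112, follow-up £63, laser £292, photodynamic therapy £107,
best supportive care £112; injections earn the attendance tariff only) to
an attendance-level ledger held in integer pence. Utilisation is busy time
over capacity × open time per resource pool.

This booking-cycle design reflects how outpatient clinics actually operate
— appointments are booked into templated sessions, queues live on booking
lists rather than in corridors — and makes the model fast enough for
replicated scenario analysis. The package's discrete-event kernel
(`sim_new()`, `schedule()`, `seize()`) provides minute-level FIFO queueing
with busy-time accounting and is exercised directly by the test suite
(single-server hand traces, an independent queue-recursion oracle, a
Little's-law check); the service pathway books capacity at the session
level rather than queueing minute by minute.

## Demand, forecasting and the latent-demand structure

Referral demand is monthly and seasonal. The packaged series has a mean of
106 first-appointment referrals per month (range roughly 90–122) split
AMD/DR/RVO = 50/30/20, and a forecast follow-up volume averaging 1,088 per
month. Arrivals are Poisson with the month's expected count, drawn by
inverse transform so that scenario runs sharing a seed remain coupled.

The forecasting module reproduces the demand-estimation stage a service
analyst would run: `generate_synthetic_history()` emulates a 36-month
hospital extract (trend + seasonality + multiplicative noise, partitioned
by condition, age band and first/follow-up type);
`fit_and_select_forecast()` fits seasonal-naive, linear-trend and Holt
exponential-smoothing candidates per partition, scores them by MAPE on a
holdout window, and carries the winner's 12-month forecast forward
(ties break in that order; negative forecasts clip to zero). Age bands are
carried through forecasting but collapsed before simulation. ARIMA is
deliberately not in the default candidate set; the interface accepts
additional fitted forecasts.

Three structural assumptions encode the environment of a service under
pressure; they are set once, from flow-balance algebra, and are not tuned
per scenario:

* **Referral demand exceeds first-appointment capacity.** Demand averages
  106/month while the calibrated baseline serves about 94, so the waiting
  list grows at baseline — the mechanism by which released consultant
  capacity later converts into additional new attendances.
* **Stable-review demand exceeds review capacity.** Year-end transitions
  feed the monitoring pool faster than the review-slot template (184
  booked slots/month) drains it, so a backlog of deferred reviews
  accumulates at baseline.
* **Released capacity is re-invested.** When nurse injectors free
  consultant minutes, 88% become new-patient slots and the rest review
  catch-up slots — the booking-policy statement of "released consultant
  capacity is consumed by the waiting list".

The monitoring rates (transition into monitoring 0.46 per year-end
survivor, reactivation 0.10 and discharge 0.37 per review, reviews every 4
months) were chosen so that the active caseload is stationary at the
baseline operating point: admissions (referrals plus reactivations)
balance exits (discharges plus transitions), and the stable-review flow
equilibrates near the review template. Without this balance the simulated
year is dominated by an initialisation transient rather than the service's
steady operation.

## Scenarios

* **SC0** — baseline, no changes.
* **SC1** — nurse injectors perform 30% of intravitreal injections
  (15 minutes of nurse time each, releasing the consultant's 11.35
  minutes), plus a constant, non-compounding +5% on every month's DR
  referrals.
* **SC2** — community virtual clinic: stable-monitoring reviews move to a
  nurse-led remote service (10-minute nurse review, one OCT slot, no
  consultant, billed at the follow-up tariff), with monthly capacity equal
  to 7% of the forecast follow-up volume (76 patients/month at the default
  demand); reviews beyond that capacity defer. A monthly infrastructure
  cost (telehealth platform, remote monitoring) of £5,118 enters the
  ledger.
* **SC3** — SC1 and SC2 together.

Scenario application is compositional: applying SC1 and then SC2 to a
configuration equals applying SC3. With its parameters zeroed, SC1
reproduces the baseline event log draw for draw, which is the foundation
of the common-random-numbers comparison (`compare_scenarios()` runs every
scenario with identical substream seeds per replication and reports paired
deltas with 95% confidence intervals).

The +5% DR uplift is interpreted as the same +5% applied to every month
(non-compounding); compounding monthly would imply a ~34% annual-average
uplift, far beyond the reported overall activity change.

## Calibration

Service times, the DNA rate and staffing details of the real service are
not public; `calibrate_baseline()` therefore adjusts only declared free
parameters — consultant-facing service-time means, the new-patient slot
share, the nurse clinic-cover level, and the initial caseload (with the
review-slot template and monitoring pool derived from it) — by damped
iterative search until the simulated baseline reproduces four targets:
about 94 first and 1,088 follow-up attendances per month, 98% consultant
and 59% nurse utilisation. All fixed inputs (regimens, routing and
discharge probabilities, resource counts, costs, tariffs) are untouched. A
configuration that already meets the targets is returned unchanged. The
packaged defaults are the output of this calibration: first consultation
18.34 min, follow-up consultation 8.73 min, consultant-delivered injection
11.35 min, nurse-delivered injection 15 min, nurse clinic cover 0.715
nurses per running session, initial caseload 3,122 with a monitoring pool
of ~1,180.

Two calibrated values deserve comment. First, the consultant injection
time (11.35 min) exceeds the follow-up consultation time (8.73 min): the
reported joint scenario response — two points of consultant utilisation
released while follow-ups rise 10% and new attendances 16% — is only
reachable when injections carry more consultant time than reviews, which
matches clinical practice (an injection is a sterile procedure; a stable
review is brief). Second, the virtual-clinic setup cost is itself
calibrated (`calibrate_setup_cost()`): with staff-time costs responding
only weakly to the combined scenario, the infrastructure cost is the free
parameter that places the combined scenario's total-cost increase near the
reported +21%; £5,118/month is the value that does so.

Nurse workload is modelled as clinic-session support (a fixed nurse
presence per running session) plus injections and virtual reviews, rather
than per-attendance time; this makes baseline nurse utilisation stable at
59% and lets nurse-injector and virtual-clinic work move it, which is the
behaviour the reported figures describe.

## What the model reproduces, and what it does not

With 30 replications and the packaged configuration the model reproduces
the baseline operating point (≈94 first attendances, ≈1,068–1,072
follow-ups, 97% consultant and 59% nurse utilisation), the nurse-injector
responses (follow-ups +12%, nurse utilisation 67%, consultant utilisation
≈97%), the combined scenario's +14–16% new attendances, 76 virtual
patients/month and ≈+21% cost.

Two reported figures sit in tension with each other under any coherent
flow model: follow-ups rising 10% under nurse injectors alone, yet
hospital follow-ups falling to 1,012 — with only 76 patients/month moved
to the community — when the virtual clinic is added on top. Since the
combined scenario contains the nurse-injector scenario, both cannot hold
exactly at once. The model resolves the tension in favour of conserving
patient flow: the combined scenario's hospital follow-up volume comes out
near 1,045 (about 3% above 1,012), and its revenue increase near +7%
rather than +10%, because total follow-up volume (hospital + virtual) is
approximately conserved while tariffs are fixed. These residuals are
documented rather than tuned away.

## Numerical choices and degenerate inputs

* Months are uniform accounting periods of 52/12 weeks (12 months = 52
  weeks exactly); integer-week months would make capacity alternate by
  25% month to month.
* Service-time draws are lognormal with CV 0.3; setting any CV to zero
  makes the corresponding draw exactly its mean, which the deterministic
  single-patient trace tests exploit.
* Money is integer pence throughout the ledger, rounded half-up per entry,
  so ledger totals re-aggregate exactly.
* All randomness flows through named substreams keyed by a master seed;
  runs are bit-reproducible and scenario runs sharing a seed are coupled.
* Warm-up is 3 months by default; `determine_warmup()` (Welch's
  moving-average rule, 5% band, floor one month) errors when a series
  fails to settle within half the pilot horizon.
* Replication sizing uses the t-based half-width rule (floor 10, cap 200).
* The initial population spreads due dates so the opening appointment flow
  matches the sustainable operating point; otherwise the first months of
  every run would be an artificial surge.

## Problem sizes used by the packaged tests

Unit and property tests run a scaled-down service (caseload ≈320, six
reporting months) or deterministic single-patient configurations;
Monte-Carlo frequency checks use 10,000–100,000 draws; the acceptance
suite runs the full configuration (caseload 3,122, 12 reporting months +
3 warm-up) at 30 replications for three scenarios under common random
numbers. A full three-scenario comparison takes well under a minute on a
single CPU.

## Known limitations

The model is operational, not clinical: no visual-acuity outcomes, no
bilateral-eye logic, no drug costs (anti-VEGF drug costs dwarf staff costs
in reality but are outside the tariff-and-salary scope modelled here), no
bank holidays or staff rosters beyond the weekly template, and no
modelling of optometry or primary care beyond the referral stream. The
synthetic demand history emulates trend, seasonality and noise but not
calendar effects, referral-source mix or data-quality artefacts of real
hospital extracts, so passing forecast-selection tests demonstrates
correctness of the selection machinery, not forecasting skill on real
data. The condition mix (50/30/20) and the treatment mix within DR
attendances are assumptions exposed in the configuration, not published
inputs.
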