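horizon_months: 12
warmup_months: 3
conditions:
  AMD:
    followups_per_year:
      year1: 5.0
      year2: 4.0
      year3: 4.0
    followup_cv: 0.3
    year_mix:
      year1: 0.72
      year2: 0.18
      year3: 0.1
    discharge_prob_at_year_end:
      year1: 0.05
      year2: 0.02
      year3: 0.01
  DR:
    followups_per_year:
      year1: 4.0
      year2: 3.0
      year3: 3.0
    followup_cv: 0.3
    year_mix:
      year1: 0.72
      year2: 0.18
      year3: 0.1
    discharge_prob_at_year_end:
      year1: 0.05
      year2: 0.02
      year3: 0.01
  RVO:
    followups_per_year:
      year1: 4.0
      year2: 3.0
      year3: 3.0
    followup_cv: 0.3
    year_mix:
      year1: 0.72
      year2: 0.18
      year3: 0.1
    discharge_prob_at_year_end:
      year1: 0.05
      year2: 0.02
      year3: 0.01
condition_mix:
  AMD: 0.5
  DR: 0.3
  RVO: 0.2
monitoring:
  transition_prob: 0.46
  review_interval_months: 4.0
  reactivation_prob: 0.1
  discharge_prob: 0.37
  pool_ratio: 0.3786
diagnostics:
  usage_prob:
    logmar: 1.0
    slitlamp: 1.0
    angiography: 0.2
    oct: 0.7
  equipment_count:
    slitlamp: 2
    angiography: 1
    oct: 2
  minutes_per_test:
    logmar: 10.0
    slitlamp: 10.0
    angiography: 10.0
    oct: 10.0
  staffing:
    logmar: hca
    slitlamp: technician
    angiography: photographer
    oct: technician
resources:
  staff_counts:
    consultant: 2
    photographer: 1
    nurse: 4
    technician: 2
    hca: 5
    optometrist: 0
  physical_counts:
    injection_bed: 1
    theatre: 1
    consultation_room: 4
  clinics_per_week: 33
  session_length_hours: 4.0
  working_days_per_week: 5
  day_length_hours: 8.0
costs:
  hourly:
    consultant: 48.640000000000001
    photographer: 17.66
    nurse: 14.27
    technician: 14.27
    hca: 9.85
    optometrist: 17.66
  virtual_setup_cost_monthly: 5118.0
tariffs:
  first: 112.0
  followup: 63.0
  laser: 292.0
  pdt: 107.0
  bsc: 112.0
service_times:
  first_consult_min: 18.34
  followup_consult_min: 8.73
  injection_consultant_min: 11.35
  injection_nurse_min: 15.0
  laser_min: 30.0
  pdt_min: 30.0
  virtual_review_min: 10.0
  duration_cv: 0.3
  nurse_session_cover: 0.715
  dna_rate: 0.08
  rebook_delay_days: 14.0
  max_rebooks: 2
treatment_mix:
  AMD:
    injection: 0.8
    laser: 0.0
    pdt: 0.0
    bsc: 0.05
  DR:
    injection: 0.5
    laser: 0.15
    pdt: 0.05
    bsc: 0.0
  RVO:
    injection: 0.8
    laser: 0.0
    pdt: 0.0
    bsc: 0.05
booking:
  capacity_fraction: 0.985
  new_slot_share: 0.55
  initial_waiting_list: 40
  initial_caseload: 3122
  virtual_diversion_rate: 0.07
  active_flow_frac: 0.84
  review_slots_per_month: 184
  released_capacity_first_share: 0.88
scenario:
  id: SC0
  nurse_injectors: no
  nurse_injection_share: 0.0
  dr_uplift: 0.0
  virtual_clinic: no
  virtual_diversion_rate: 0.0
  virtual_setup_cost_monthly: 0.0
demand:
  first_appts:
    month:
    - 1
    - 1
    - 1
    - 2
    - 2
    - 2
    - 3
    - 3
    - 3
    - 4
    - 4
    - 4
    - 5
    - 5
    - 5
    - 6
    - 6
    - 6
    - 7
    - 7
    - 7
    - 8
    - 8
    - 8
    - 9
    - 9
    - 9
    - 10
    - 10
    - 10
    - 11
    - 11
    - 11
    - 12
    - 12
    - 12
    condition:
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    count:
    - 50.0
    - 29.0
    - 19.0
    - 54.0
    - 31.0
    - 21.0
    - 58.0
    - 34.0
    - 22.0
    - 60.0
    - 36.0
    - 24.0
    - 62.0
    - 36.0
    - 24.0
    - 60.0
    - 36.0
    - 24.0
    - 58.0
    - 34.0
    - 22.0
    - 54.0
    - 31.0
    - 21.0
    - 50.0
    - 29.0
    - 19.0
    - 47.0
    - 27.0
    - 18.0
    - 45.0
    - 27.0
    - 18.0
    - 47.0
    - 27.0
    - 18.0
  followup_appts:
    month:
    - 1
    - 1
    - 1
    - 2
    - 2
    - 2
    - 3
    - 3
    - 3
    - 4
    - 4
    - 4
    - 5
    - 5
    - 5
    - 6
    - 6
    - 6
    - 7
    - 7
    - 7
    - 8
    - 8
    - 8
    - 9
    - 9
    - 9
    - 10
    - 10
    - 10
    - 11
    - 11
    - 11
    - 12
    - 12
    - 12
    condition:
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    - AMD
    - DR
    - RVO
    count:
    - 515.0
    - 308.0
    - 205.0
    - 545.0
    - 326.0
    - 217.0
    - 575.0
    - 344.0
    - 229.0
    - 597.0
    - 357.0
    - 238.0
    - 605.0
    - 362.0
    - 241.0
    - 597.0
    - 357.0
    - 238.0
    - 575.0
    - 344.0
    - 229.0
    - 545.0
    - 326.0
    - 217.0
    - 515.0
    - 308.0
    - 205.0
    - 493.0
    - 295.0
    - 196.0
    - 485.0
    - 290.0
    - 193.0
    - 493.0
    - 295.0
    - 196.0
  dna_expected:
    month:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    - 7
    - 8
    - 9
    - 10
    - 11
    - 12
    count:
    - 90.0
    - 96.0
    - 101.0
    - 105.0
    - 106.0
    - 105.0
    - 101.0
    - 96.0
    - 90.0
    - 86.0
    - 85.0
    - 86.0
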