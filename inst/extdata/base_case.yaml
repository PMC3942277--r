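event_rates_vka:
  ischemic_stroke: 0.004
  myocardial_infarction: 0.0028
  systemic_embolism: 0.0005
  intracranial_bleed: 0.0019
  minor_extracranial_bleed: 0.0297
  major_extracranial_bleed: 0.0069
event_rates_secondline:
  ischemic_stroke: 0.008
  myocardial_infarction: 0.0028
  systemic_embolism: 0.001
  intracranial_bleed: 0.00095
  minor_extracranial_bleed: 0.01485
  major_extracranial_bleed: 0.00345
effect:
  population: SOT
  rr_is:
    point: 0.94
    lower: 0.75
    upper: 1.17
  rr_mi:
    point: 0.81
    lower: 0.63
    upper: 1.06
  rr_se:
    point: 0.23
    lower: 0.09
    upper: 0.61
  rr_ic:
    point: 0.67
    lower: 0.47
    upper: 0.93
  rr_major_ec:
    point: 1.14
    lower: 0.98
    upper: 1.33
  rr_minor_ec:
    point: 1.04
    lower: 0.96
    upper: 1.13
  itt:
    rr_is:
      point: 0.99
      lower: 0.82
      upper: 1.2
    rr_mi:
      point: 0.91
      lower: 0.72
      upper: 1.16
    rr_se:
      point: 0.74
      lower: 0.42
      upper: 1.32
mortality:
  case_fatality:
    major_is: 0.126
    minor_is: 0.0
    major_ec: 0.016
    minor_ec: 0.0
    ic: 0.388
    se: 0.0
    mi: 0.0969
  post_excess:
    major_is: 0.026
    minor_is: 0.0
    ic: 0.026
    mi: 0.0268
  start_age: 75.0
  life_table:
    ages:
    - 75
    - 76
    - 77
    - 78
    - 79
    - 80
    - 81
    - 82
    - 83
    - 84
    - 85
    - 86
    - 87
    - 88
    - 89
    - 90
    - 91
    - 92
    - 93
    - 94
    - 95
    - 96
    - 97
    - 98
    - 99
    - 100
    - 101
    - 102
    - 103
    - 104
    - 105
    - 106
    - 107
    - 108
    - 109
    - 110
    qx:
    - 0.0342
    - 0.037608
    - 0.041356
    - 0.045478
    - 0.05001
    - 0.054994
    - 0.060475
    - 0.066502
    - 0.073129
    - 0.080417
    - 0.088431
    - 0.097244
    - 0.106935
    - 0.117593
    - 0.129312
    - 0.142199
    - 0.15637
    - 0.171954
    - 0.18909
    - 0.207935
    - 0.228658
    - 0.251445
    - 0.276504
    - 0.30406
    - 0.334362
    - 0.367685
    - 0.404328
    - 0.444623
    - 0.488933
    - 0.53766
    - 0.591242
    - 0.650165
    - 0.714959
    - 0.786211
    - 0.864564
    - 1.0
utilities:
  baseline: 0.779
  vka_multiplier: 0.95
  acute:
    major_is: 0.189
    minor_is: 0.641
    mi: 0.68
    minor_ec: 0.776
    major_ec: 0.598
    ic: 0.6
    se: 0.66
  post:
    minor_is: 0.72
    major_is: 0.48
    mi: 0.69
    ic: 0.74
costs:
  drug_daily:
    riva: 2.16
    vka: 0.05
    secondline: 0.0
  visit:
    vka_first: 32.0
    vka_subsequent: 22.0
    other: 10.0
  acute:
    minor_is: 900.0
    moderate_is: 1625.0
    severe_is: 2475.0
    se: 1567.0
    ic: 2475.0
    minor_ec: 257.0
    major_ec: 654.0
    mi: 1783.0
  followup:
    major_is: 1093.0
    ic: 1093.0
    mi: 1296.0
  transport:
    cost_per_visit: 70.0
    uptake: 0.5
  rebate:
    entry: 0.0
    volume: 0.0
  copay_rate: 0.25
  inr_test: 4.31
  visits_per_cycle:
    vka_maintenance: 3.0
    other: 0.25
    secondline: 0.0
persistence:
  disc_first_cycle:
    riva: 0.089
    vka: 0.08
  disc_subsequent:
    riva: 0.0439
    vka: 0.0446
  disc_horizon_cycles: 14.0
  second_line: aspirin
  ic_bleed_discontinuation_prob: 1.0
settings:
  cycle_length_days: 91.3125
  discount_rate_annual: 0.035
  terminal_age: 110.0
  wtp_grid:
  - 0.0
  - 5000.0
  - 10000.0
  - 15000.0
  - 20000.0
  - 25000.0
  - 30000.0
  - 35000.0
  - 40000.0
  - 45000.0
  - 50000.0
  - 55000.0
  - 60000.0
  stroke_major_fraction: 0.4
  stroke_major_cost_weights:
    moderate: 0.5
    severe: 0.5
  half_cycle_correction: no
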