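triage:
  arm: pinpoint
  sensitivity: 0.98
  specificity: 0.2
  gp_override: 0.2
  delayed_return_cancer: 1.0
  delayed_return_noncancer: 0.1
  delay_weeks: 6.0
  test_turnaround_min: 10080.0
disable_sessions: []
annual_volume: 10542.0
demand_multiplier: 1.0
prevalence: 0.0476
pathway:
  probs_noncancer:
  - 0.012766012766
  - 0.272533272533
  - 0.035168035168
  - 0.394921394921
  - 0.181688181688
  - 0.023445023445
  - 0.060947060947
  - 0.017845017845
  - 0.000686000686
  probs_cancer:
  - 0.005525005525
  - 0.038122038122
  - 0.510497510498
  - 0.013812013812
  - 0.025414025414
  - 0.340331340331
  - 0.035912035912
  - 0.027624027624
  - 0.002762002762
  mammogram_first: 0.6
  discharge_noncancer: 0.25
durations:
  initial_assessment: 10.0
  mammogram: 20.0
  ultrasound: 20.0
  biopsy:
  - 30.0
  - 45.0
  biopsy_long_prob: 0.5
  dispersion: 0.25
  prep: 5.0
booking_rule:
  threshold: 380.0
  step: 15.0
  max: 34.0
  include_returns: yes
  rounding: floor
rooms:
  initial_assessment: 4
  mammogram: 3
  ultrasound: 4
  biopsy: 4
roster_full:
  counts:
    consultant: 2
    nurse_practitioner: 1
    physician_associate: 1
    band7_sonographer: 2
    band6_sonographer: 1
    band6_non_sonographer: 1
    grade2_assistant: 2
  availability:
    consultant: 0.672
    nurse_practitioner: 0.672
    physician_associate: 0.672
    band7_sonographer: 0.672
    band6_sonographer: 0.672
    band6_non_sonographer: 0.672
    grade2_assistant: 0.672
roster_addon:
  counts:
    consultant: 1
    nurse_practitioner: 1
    physician_associate: 1
    band7_sonographer: 1
    band6_sonographer: 1
    band6_non_sonographer: 1
    grade2_assistant: 1
  availability:
    consultant: 0.672
    nurse_practitioner: 0.672
    physician_associate: 0.672
    band7_sonographer: 0.672
    band6_sonographer: 0.672
    band6_non_sonographer: 0.672
    grade2_assistant: 0.672
warmup_weeks: 12.0
collection_weeks: 52.0
arrival_convention: poisson
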