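# Default 23-item MetS spectrum scoring matrix (South Asian cutoffs).
#
# Tier weights: high-impact clinical factors score 2 points, moderate-impact
# lifestyle / history factors 1 point, demographic factors 0-1 point.
# Band cutoffs close the printed gaps downward/upward so the intervals are
# contiguous: low <=9, moderate 10-17, high 18-25, very high >=26.
version: "1.0"
bands:
  - {band: low,       min: 0,  max: 9}
  - {band: moderate,  min: 10, max: 17}
  - {band: high,      min: 18, max: 25}
  - {band: very_high, min: 26, max: .inf}
items:
  - id: wc
    domain: anthropometric
    tier: high
    applies_to_sex: all
    rule: {kind: threshold, field: wc_cm, op: ">=", cutoff: {male: 90, female: 80}}
  - id: fbg
    domain: biochemical
    tier: high
    applies_to_sex: all
    rule: {kind: threshold, field: fbg, op: ">=", cutoff: 100}
  - id: tg
    domain: biochemical
    tier: high
    applies_to_sex: all
    rule: {kind: threshold, field: tg, op: ">=", cutoff: 150}
  - id: hdl
    domain: biochemical
    tier: high
    applies_to_sex: all
    rule: {kind: threshold, field: hdl, op: "<", cutoff: {male: 40, female: 50}}
  - id: bp
    domain: blood_pressure
    tier: high
    applies_to_sex: all
    rule:
      kind: any_of
      conditions:
        - {field: sbp_mmhg, op: ">=", cutoff: 130}
        - {field: dbp_mmhg, op: ">=", cutoff: 85}
  - id: bmi
    domain: anthropometric
    tier: moderate
    applies_to_sex: all
    rule: {kind: threshold, field: bmi, op: ">=", cutoff: 23}
  - id: whr
    domain: anthropometric
    tier: moderate
    applies_to_sex: all
    rule: {kind: threshold, field: whr, op: ">", cutoff: {male: 0.90, female: 0.85}}
  - id: activity
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: activity_days, points: {d0_1: 1}}
  - id: fruit
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: fruit_days, points: {rarely: 1}}
  - id: vegetables
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: veg_days, points: {d0_1: 1}}
  - id: high_fat
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: high_fat_meals, points: {frequent: 1}}
  - id: sleep_duration
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: sleep_duration, points: {lt6: 1}}
  - id: sleep_quality
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: sleep_quality, points: {poor: 1}}
  - id: smoking
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: smoking, points: {occasional: 1, daily: 1}}
  - id: alcohol
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: alcohol, points: {weekly: 1, daily: 1}}
  - id: stress
    domain: lifestyle
    tier: moderate
    applies_to_sex: all
    rule: {kind: categorical, field: stress, points: {high: 1}}
  - id: fam_diabetes
    domain: family_history
    tier: moderate
    applies_to_sex: all
    rule: {kind: flag, field: fam_diabetes}
  - id: fam_htn_cvd
    domain: family_history
    tier: moderate
    applies_to_sex: all
    rule: {kind: flag, field: fam_htn_cvd}
  - id: gdm
    domain: female_specific
    tier: moderate
    applies_to_sex: female
    rule: {kind: flag, field: gdm}
  - id: pcos
    domain: female_specific
    tier: moderate
    applies_to_sex: female
    rule: {kind: flag, field: pcos}
  - id: postmenopausal
    domain: female_specific
    tier: moderate
    applies_to_sex: female
    rule: {kind: flag, field: postmenopausal}
  - id: age_over_40
    domain: demographic
    tier: demographic
    applies_to_sex: all
    rule: {kind: threshold, field: age, op: ">", cutoff: 40}
  - id: male_sex
    domain: demographic
    tier: demographic
    applies_to_sex: all
    rule: {kind: categorical, field: sex, points: {male: 1}}
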