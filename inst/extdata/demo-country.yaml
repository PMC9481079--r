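schema_version: '1.0'
kind: profile
region: demo-country
demography:
  base_year: 2020
  horizon: 5
  live_births:
  - 100000.0
  - 100000.0
  - 100000.0
  - 100000.0
  - 100000.0
  - 100000.0
  pregnancies:
  - 103000.0
  - 103000.0
  - 103000.0
  - 103000.0
  - 103000.0
  - 103000.0
envelopes:
- group: child_1_59m
  base_rate: 60.0
  cause_fractions:
    diarrhea: 0.2
    pneumonia: 0.25
    malaria: 0.15
    measles: 0.05
    other: 0.35
- group: neonatal
  base_rate: 25.0
  cause_fractions:
    sepsis: 0.3
    asphyxia: 0.3
    prematurity: 0.3
    other: 0.1
risk_factors:
- id: breastfeeding
  states:
  - none
  - partial
  - exclusive
  baseline_prevalence:
    none: 0.2
    partial: 0.45
    exclusive: 0.35
  relative_risks:
  - state: none
    group: child_1_59m
    cause: diarrhea
    rr: 2.4
  - state: partial
    group: child_1_59m
    cause: diarrhea
    rr: 1.7
  - state: exclusive
    group: child_1_59m
    cause: diarrhea
    rr: 1.0
  - state: none
    group: child_1_59m
    cause: pneumonia
    rr: 1.9
  - state: partial
    group: child_1_59m
    cause: pneumonia
    rr: 1.4
  - state: exclusive
    group: child_1_59m
    cause: pneumonia
    rr: 1.0
interventions:
- id: ebf_promotion
  name: Exclusive breastfeeding promotion
  baseline_coverage: 0.3
  effects:
  - target_kind: risk_factor
    target: breastfeeding
    efficacy: 0.6
    affected_fraction: 0.9
- id: ors
  name: Oral rehydration solution
  baseline_coverage: 0.4
  effects:
  - target_kind: cause
    target: diarrhea
    efficacy: 0.93
    affected_fraction: 0.9
    group: child_1_59m
- id: pneumonia_abx
  name: Antibiotics for pneumonia
  baseline_coverage: 0.35
  effects:
  - target_kind: cause
    target: pneumonia
    efficacy: 0.7
    affected_fraction: 0.85
    group: child_1_59m
- id: clean_delivery
  name: Clean delivery practices
  baseline_coverage: 0.45
  effects:
  - target_kind: cause
    target: sepsis
    efficacy: 0.25
    affected_fraction: 0.7
    group: neonatal
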