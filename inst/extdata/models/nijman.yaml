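name: nijman
label: "Nijman (2013)"
form: logistic
source: "Nijman et al., febrile children 1 m - 15 y, Dutch ED"
provenance: >
  SYNTHETIC PLACEHOLDER COEFFICIENTS. Predictor set (age, sex, duration of
  fever, temperature, respiratory rate, heart rate, oxygen saturation,
  capillary refill, retractions, ill appearance, CRP) is the published one;
  the numeric coefficients are plausibility choices, not the published model.
derivation_prevalence: 0.063
# derivation-population means, used when a predictor is wholly unrecorded
# at a site (mean imputation); the retractions value is a prevalence, so
# the filled column becomes fractional
derivation_constants:
  fever_duration_days: 3.0
  retractions: 0.35
intercept: -5.5
terms:
  - variable: age_months
    transform: log1p
    coefficient: -0.10
  - variable: sex
    transform: equals
    value: male
    coefficient: 0.15
  - variable: fever_duration_days
    coefficient: 0.10
  - variable: temperature_c
    coefficient: 0.20
  - variable: resp_rate
    coefficient: 0.030
  - variable: heart_rate
    coefficient: 0.005
  - variable: spo2_pct
    coefficient: -0.080
  - variable: cap_refill_prolonged
    coefficient: 0.60
  - variable: retractions
    coefficient: 0.40
  - variable: ill_appearance
    coefficient: 0.50
  - variable: crp_mg_l
    transform: log1p
    coefficient: 0.50
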