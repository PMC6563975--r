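name: oostenbrink
label: "Oostenbrink (2013)"
form: logistic
source: "Oostenbrink et al., children 1 m - 16 y with fever and cough, Dutch ED"
provenance: >
  SYNTHETIC PLACEHOLDER COEFFICIENTS. Predictor set (ill appearance,
  tachypnea, oxygen saturation < 94%, CRP) is the published one; the
  numeric coefficients are plausibility choices, not the published model.
derivation_prevalence: 0.155
intercept: -4.0
terms:
  - variable: ill_appearance
    coefficient: 0.8
  - variable: tachypnea
    coefficient: 0.9
  - variable: spo2_pct
    transform: threshold
    op: lt
    value: 94
    coefficient: 1.1
  - variable: crp_mg_l
    transform: log1p
    coefficient: 0.45
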