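name: irwin
label: "Irwin (2017)"
form: logistic
source: "Irwin et al., febrile children < 16 y, US ED"
provenance: >
  SYNTHETIC PLACEHOLDER COEFFICIENTS. Predictor set (CRP, respiratory rate,
  air entry, resistin, procalcitonin) is the published one; the numeric
  coefficients are plausibility choices, not the published model. Resistin
  and procalcitonin are typically unmeasured in routine ED data; their
  derivation constants implement mean imputation from the derivation cohort.
derivation_prevalence: 0.12
intercept: -5.0
terms:
  - variable: crp_mg_l
    transform: log1p
    coefficient: 0.50
  - variable: resp_rate
    coefficient: 0.040
  - variable: decreased_breath_sounds
    coefficient: 0.50
  - variable: resistin_ng_ml
    coefficient: 0.020
  - variable: procalcitonin_ng_ml
    transform: log1p
    coefficient: 0.30
derivation_constants:
  resistin_ng_ml: 5.0
  procalcitonin_ng_ml: 0.3
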