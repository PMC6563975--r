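name: lynch
label: "Lynch (2004)"
form: logistic
source: "Lynch et al., children 1-16 y with chest x-ray for suspected pneumonia, US ED"
provenance: >
  SYNTHETIC PLACEHOLDER COEFFICIENTS. The original coefficients are not
  printed in the validation literature this package accompanies; signs and
  magnitudes below are plausibility choices so the spec is runnable, not the
  published model. Replace from the source publication before any real use.
derivation_prevalence: 0.358
intercept: -1.0
terms:
  - variable: temperature_c
    transform: threshold
    op: ge
    value: 38
    coefficient: 1.0
  - variable: decreased_breath_sounds
    coefficient: 0.9
  - variable: crackles
    coefficient: 0.8
  - variable: tachypnea
    coefficient: 0.7
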