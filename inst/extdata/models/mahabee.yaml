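name: mahabee
label: "Mahabee-Gittens (2005)"
form: rule_any_of
source: "Mahabee-Gittens et al., derivation cohort 2 months - 5 years, US ED"
provenance: >
  Published as a regression model, but the coefficients were never released
  by the authors; only the any-of rule over the included variables is usable,
  classifying a child at high risk when one or more predicates hold.
derivation_prevalence: 0.086
# mode of nasal flaring in the derivation population, used only when the
# predictor is wholly unrecorded at a site (binary predicates need a
# type-consistent fill, so the mode stands in for the mean)
derivation_constants:
  nasal_flaring: 0
predicates:
  - variable: age_months
    op: ge
    value: 12
  - variable: resp_rate
    op: ge
    value: 50
  - variable: spo2_pct
    op: le
    value: 96
  - variable: nasal_flaring
    op: is_true
    when:
      variable: age_months
      op: lt
      value: 12
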