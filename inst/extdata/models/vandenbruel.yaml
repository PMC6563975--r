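name: vandenbruel
label: "Van den Bruel (2007), pneumonia model"
form: rule_tree
source: "Van den Bruel et al., acutely ill children < 17 y, Belgian primary care + ED"
provenance: "Published decision rule: high risk if dyspnoea or clinician gestalt 'something is wrong'."
derivation_prevalence: 0.004
predicates:
  - variable: dyspnoea
    op: is_true
  - variable: something_wrong
    op: is_true
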