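name: neuman
label: "Neuman (2011), first split"
form: rule_tree
source: "Neuman et al., children < 21 y with chest x-ray for suspected pneumonia, US ED"
provenance: >
  Full model is a three-class decision tree; in an all-febrile population the
  history-of-fever split is uninformative, leaving the first split only.
  The cutoff is printed both as <=92% and <92% in the source material; the
  inclusive form is used here and both cutoff and comparator are editable.
derivation_prevalence: 0.164
predicates:
  - variable: spo2_pct
    op: le
    value: 92
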