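# Shared fixtures: tiny in-code cohorts and CSV writers.

# a small complete cohort spanning several reference categories
make_complete_cohort <- function(n = 12) {
  set.seed(42)
  df <- data.frame(
    patient_id = sprintf("C%03d", seq_len(n)),
    age_months = rep(c(8, 20, 30, 45), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    temperature_c = rep(c(38.5, 39.2, 37.8), length.out = n),
    fever_duration_days = rep(c(2, 3, 4), length.out = n),
    resp_rate = rep(c(35, 55, 42), length.out = n),
    heart_rate = rep(c(120, 170, 140), length.out = n),
    spo2_pct = rep(c(99, 91, 97), length.out = n),
    ill_appearance = rep(c(TRUE, FALSE), length.out = n),
    dyspnoea = rep(c(TRUE, FALSE, FALSE), length.out = n),
    retractions = rep(c(TRUE, FALSE), length.out = n),
    nasal_flaring = rep(c(FALSE, TRUE), length.out = n),
    crackles = rep(c(FALSE, TRUE, FALSE), length.out = n),
    focal_rales = rep(c(TRUE, FALSE), length.out = n),
    decreased_breath_sounds = rep(FALSE, n),
    wheeze = rep(c(TRUE, FALSE), length.out = n),
    chest_pain = rep(FALSE, n),
    cap_refill_prolonged = rep(c(FALSE, FALSE, TRUE), length.out = n),
    something_wrong = rep(c(FALSE, TRUE), length.out = n),
    fever_history = rep(TRUE, n),
    crp_mg_l = rep(c(120, 15, 40, 8), length.out = n),
    working_diagnosis = rep(c("pneumonia", "bronchiolitis",
                              "complicated_pneumonia", "viral_uri"),
                            length.out = n),
    bacterial_pathogen_detected = rep(c(FALSE, FALSE, FALSE, TRUE),
                                      length.out = n),
    viral_pathogen_detected = rep(c(FALSE, TRUE, FALSE, FALSE),
                                  length.out = n),
    antibiotics_prescribed = rep(c(TRUE, FALSE, TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE)
  as_cohort_data(df, name = "fixture")
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# brute-force ORC oracle: explicit double loops over record pairs,
# independent of the midrank implementation
orc_oracle <- function(scores, categories, weighting = "unweighted_pairs") {
  cats <- sort(unique(categories))
  pair_aucs <- c()
  pair_wts <- c()
  for (i in seq_along(cats)) for (j in seq_along(cats)) {
    if (j <= i) next
    a <- scores[categories == cats[i]]  # more bacterial
    b <- scores[categories == cats[j]]
    conc <- 0
    for (x in a) for (y in b)
      conc <- conc + (x > y) + 0.5 * (x == y)
    pair_aucs <- c(pair_aucs, conc / (length(a) * length(b)))
    pair_wts <- c(pair_wts, length(a) * length(b))
  }
  if (weighting == "unweighted_pairs") mean(pair_aucs)
  else sum(pair_aucs * pair_wts) / sum(pair_wts)
}
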