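specs <- load_model_dir()

test_that("the seven shipped model specs load with their published forms", {
  expect_setequal(names(specs), c("mahabee", "vandenbruel", "neuman", "lynch",
                                  "oostenbrink", "nijman", "irwin"))
  expect_equal(specs$mahabee$form, "rule_any_of")
  expect_equal(specs$vandenbruel$form, "rule_tree")
  expect_length(specs$vandenbruel$predicates, 2)
  expect_equal(specs$nijman$form, "logistic")
  expect_length(specs$nijman$terms, 11)
  expect_true(all(unlist(lapply(specs, model_predictors)) %in%
                    cohort_dictionary()$variable))
})

test_that("malformed specs are rejected with informative errors", {
  good <- list(name = "m", form = "logistic", intercept = 0,
               terms = list(list(variable = "crp_mg_l", coefficient = 1)))
  bad_var <- good
  bad_var$terms[[1]]$variable <- "not_a_variable"
  expect_error(validate_model_spec(bad_var), "unknown variable")
  bad_coef <- good
  bad_coef$terms[[1]]$coefficient <- NULL
  expect_error(validate_model_spec(bad_coef), "coefficient")
  bad_rule <- list(name = "r", form = "rule_tree",
                   predicates = list(list(variable = "dyspnoea")))
  expect_error(validate_model_spec(bad_rule), "op")
  mixed <- list(name = "x", form = "rule_any_of",
                predicates = list(list(variable = "dyspnoea", op = "is_true")),
                terms = list(list(variable = "crp_mg_l", coefficient = 1)))
  expect_error(validate_model_spec(mixed), "predicates, not terms")
})

test_that("CRP truncation caps at 225 mg/L and rejects negatives", {
  expect_equal(truncate_crp(300), 225)
  expect_equal(truncate_crp(225), 225)
  expect_equal(truncate_crp(16), 16)
  expect_error(truncate_crp(-1), "CRP")
})

make_record <- function(...) {
  args <- list(...)
  df <- data.frame(patient_id = "R1", working_diagnosis = "pneumonia",
                   stringsAsFactors = FALSE)
  for (nm in names(args)) df[[nm]] <- args[[nm]]
  as_cohort_data(df)
}

test_that("rule models reproduce their published decision logic", {
  # any-of rule: age >= 12 months alone puts a child at high risk
  co <- make_record(age_months = 20, resp_rate = 40, spo2_pct = 99,
                    nasal_flaring = FALSE)
  expect_equal(evaluate_rule_model(specs$mahabee, co)$risk_class, "high")
  # nasal flaring only counts under 12 months
  co2 <- make_record(age_months = 8, resp_rate = 40, spo2_pct = 99,
                     nasal_flaring = TRUE)
  expect_equal(evaluate_rule_model(specs$mahabee, co2)$risk_class, "high")
  co3 <- make_record(age_months = 8, resp_rate = 40, spo2_pct = 99,
                     nasal_flaring = FALSE)
  expect_equal(evaluate_rule_model(specs$mahabee, co3)$risk_class, "low")

  vdb <- function(d, s) evaluate_rule_model(
    specs$vandenbruel, make_record(dyspnoea = d, something_wrong = s))$risk_class
  expect_equal(vdb(FALSE, FALSE), "low")
  expect_equal(vdb(TRUE, FALSE), "high")
  expect_equal(vdb(FALSE, TRUE), "high")

  neu <- function(s) evaluate_rule_model(specs$neuman,
                                         make_record(spo2_pct = s))$risk_class
  expect_equal(neu(91), "high")
  expect_equal(neu(92), "high")  # inclusive cutoff
  expect_equal(neu(95), "low")
})

test_that("unresolved predictors are an error naming the variable", {
  co <- make_record(age_months = 20, resp_rate = NA, spo2_pct = 99,
                    nasal_flaring = FALSE)
  expect_error(evaluate_rule_model(specs$mahabee, co), "resp_rate")
  co2 <- make_record(crp_mg_l = NA)
  expect_error(evaluate_logistic_model(specs$oostenbrink, co2), "ill_appearance")
})

test_that("logistic evaluation matches closed-form inverse-logit values", {
  null_spec <- validate_model_spec(list(
    name = "null", form = "logistic", intercept = 0,
    terms = list(list(variable = "crp_mg_l", coefficient = 0))))
  co <- make_record(crp_mg_l = 50)
  expect_equal(evaluate_logistic_model(null_spec, co)$risk, 0.5)

  odds9 <- validate_model_spec(list(
    name = "odds9", form = "logistic", intercept = log(9),
    terms = list(list(variable = "crp_mg_l", coefficient = 0))))
  expect_equal(evaluate_logistic_model(odds9, co)$risk, 0.9)

  one_term <- validate_model_spec(list(
    name = "one", form = "logistic", intercept = -1,
    terms = list(list(variable = "dyspnoea", coefficient = 1))))
  expect_equal(evaluate_logistic_model(one_term,
                                       make_record(dyspnoea = TRUE))$risk, 0.5)
  expect_equal(evaluate_logistic_model(one_term,
                                       make_record(dyspnoea = FALSE))$risk,
               plogis(-1), tolerance = 1e-12)
})

test_that("logistic risks agree with a brute-force linear predictor to 1e-12", {
  set.seed(9)
  g <- generate_cohort(preset("rotterdam_like"), n = 40, seed = 5)
  co <- g$cohort
  co$data$crp_mg_l[is.na(co$data$crp_mg_l)] <- 30
  co$data$spo2_pct[is.na(co$data$spo2_pct)] <- 96
  for (rep in 1:20) {
    beta <- round(rnorm(3), 3)
    intercept <- round(rnorm(1), 3)
    spec <- validate_model_spec(list(
      name = "rand", form = "logistic", intercept = intercept,
      terms = list(
        list(variable = "age_months", coefficient = beta[1]),
        list(variable = "crp_mg_l", transform = "log1p", coefficient = beta[2]),
        list(variable = "spo2_pct", coefficient = beta[3]))))
    got <- evaluate_logistic_model(spec, co)$risk
    lp <- intercept + beta[1] * co$data$age_months +
      beta[2] * log1p(pmin(co$data$crp_mg_l, 225)) +
      beta[3] * co$data$spo2_pct
    expect_equal(got, 1 / (1 + exp(-lp)), tolerance = 1e-12)
  }
})

test_that("risk is increasing in a positive-coefficient predictor and capped CRP", {
  spec <- validate_model_spec(list(
    name = "crp_only", form = "logistic", intercept = -3,
    terms = list(list(variable = "crp_mg_l", transform = "log1p",
                      coefficient = 0.5))))
  risks <- vapply(c(5, 20, 80, 200),
                  function(v) evaluate_logistic_model(spec,
                                                      make_record(crp_mg_l = v))$risk,
                  numeric(1))
  expect_true(all(diff(risks) > 0))
  # truncation: CRP 300 and 225 give identical risk
  expect_equal(evaluate_logistic_model(spec, make_record(crp_mg_l = 300))$risk,
               evaluate_logistic_model(spec, make_record(crp_mg_l = 225))$risk)
})

test_that("rule models are invariant to predicate order", {
  flipped <- specs$mahabee
  flipped$predicates <- rev(flipped$predicates)
  g <- generate_cohort(preset("rotterdam_like"), n = 30, seed = 3)
  co <- g$cohort
  for (v in c("age_months", "resp_rate", "spo2_pct"))
    co$data[[v]][is.na(co$data[[v]])] <- mean(co$data[[v]], na.rm = TRUE)
  co$data$nasal_flaring[is.na(co$data$nasal_flaring)] <- FALSE
  expect_equal(evaluate_rule_model(flipped, co)$risk_class,
               evaluate_rule_model(specs$mahabee, co)$risk_class)
})

test_that("the availability gate is strict at one half", {
  # 2 of 4 predictors available: fraction 0.5 excludes the model
  df <- data.frame(patient_id = c("A", "B"),
                   temperature_c = c(38, 39), tachypnea = c(TRUE, FALSE),
                   working_diagnosis = "pneumonia", stringsAsFactors = FALSE)
  co <- as_cohort_data(df)
  av <- predictor_availability(specs$lynch, co)
  expect_equal(av$fraction, 0.5)
  expect_false(av$include)
  # all predictors available: include
  full <- make_complete_cohort(6)
  full <- derive_vital_flags(full)
  av2 <- predictor_availability(specs$lynch, full)
  expect_equal(av2$fraction, 1)
  expect_true(av2$include)
})

test_that("tachypnea/tachycardia derive from age-banded cutoffs without overwriting", {
  df <- data.frame(patient_id = c("A", "B", "C", "D"),
                   age_months = c(6, 6, 30, 30),
                   resp_rate = c(52, 45, 45, 35),
                   heart_rate = c(165, 150, 145, 130),
                   tachypnea = c(NA, NA, FALSE, NA),
                   working_diagnosis = "pneumonia", stringsAsFactors = FALSE)
  co <- derive_vital_flags(as_cohort_data(df))
  # infant cutoff 50/min, toddler cutoff 40/min
  expect_identical(co$data$tachypnea, c(TRUE, FALSE, FALSE, FALSE))
  # the recorded FALSE for record C is kept even though 45 >= 40
  expect_equal(co$provenance$tachypnea[3], "raw")
  expect_identical(co$data$tachycardia, c(TRUE, FALSE, TRUE, FALSE))
})
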