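make_missing_cohort <- function(n = 60, seed = 31) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("M%03d", seq_len(n)),
    age_months = runif(n, 2, 59),
    temperature_c = rnorm(n, 38.5, 0.8),
    resp_rate = rnorm(n, 45, 9),
    spo2_pct = pmin(100, rnorm(n, 97, 2)),
    dyspnoea = runif(n) < 0.6,
    crp_mg_l = rlnorm(n, log(25), 1),
    working_diagnosis = "pneumonia",
    antibiotics_prescribed = runif(n) < 0.3,
    stringsAsFactors = FALSE)
  df$resp_rate[sample(n, 15)] <- NA
  df$crp_mg_l[sample(n, 20)] <- NA
  df$dyspnoea[sample(n, 18)] <- NA
  as_cohort_data(df)
}

test_that("a complete cohort yields m identical completed cohorts", {
  co <- make_complete_cohort(10)
  imps <- impute_multiple(co, variables = c("crp_mg_l", "resp_rate"),
                          m = 10, seed = 4)
  expect_equal(imps$m, 10)
  for (i in 1:10) expect_identical(imps$completed_cohorts[[i]]$data, co$data)
})

test_that("imputation is deterministic given the seed and never alters observed cells", {
  co <- make_missing_cohort()
  a <- impute_multiple(co, m = 4, seed = 99)
  b <- impute_multiple(co, m = 4, seed = 99)
  expect_identical(lapply(a$completed_cohorts, `[[`, "data"),
                   lapply(b$completed_cohorts, `[[`, "data"))
  c2 <- impute_multiple(co, m = 4, seed = 100)
  expect_false(identical(a$completed_cohorts[[1]]$data,
                         c2$completed_cohorts[[1]]$data))
  obs_mask <- !is.na(co$data$crp_mg_l)
  for (i in 1:4) {
    done <- a$completed_cohorts[[i]]$data
    expect_identical(done$crp_mg_l[obs_mask], co$data$crp_mg_l[obs_mask])
    expect_false(anyNA(done$crp_mg_l))
    expect_false(anyNA(done$dyspnoea))
    # provenance marks exactly the filled cells
    expect_equal(a$completed_cohorts[[i]]$provenance$crp_mg_l[!obs_mask],
                 rep("imputed:chained_equations", sum(!obs_mask)))
  }
})

test_that("extending m reuses the earlier substreams (reproducible extension)", {
  co <- make_missing_cohort()
  small <- impute_multiple(co, m = 2, seed = 7)
  large <- impute_multiple(co, m = 5, seed = 7)
  expect_identical(small$completed_cohorts[[1]]$data,
                   large$completed_cohorts[[1]]$data)
  expect_identical(small$completed_cohorts[[2]]$data,
                   large$completed_cohorts[[2]]$data)
})

test_that("hot-deck imputation of a binary variable preserves the observed rate", {
  n <- 400
  set.seed(11)
  df <- data.frame(patient_id = sprintf("H%03d", 1:n),
                   dyspnoea = runif(n) < 0.6,
                   working_diagnosis = "pneumonia", stringsAsFactors = FALSE)
  miss <- sample(n, round(0.3 * n))
  true_rate <- mean(df$dyspnoea[-miss])
  df$dyspnoea[miss] <- NA
  co <- as_cohort_data(df)
  imps <- impute_multiple(co, variables = "dyspnoea", m = 50, seed = 21,
                          method = "marginal_hotdeck")
  imputed_rates <- vapply(imps$completed_cohorts, function(c)
    mean(c$data$dyspnoea[miss]), numeric(1))
  se <- sqrt(true_rate * (1 - true_rate) / length(miss))
  expect_lt(abs(mean(imputed_rates) - true_rate), 3 * se)
})

test_that("a variable with no observed values directs to constant imputation", {
  df <- data.frame(patient_id = c("A", "B"), resistin_ng_ml = NA,
                   working_diagnosis = "pneumonia", stringsAsFactors = FALSE)
  co <- as_cohort_data(df)
  expect_error(impute_multiple(co, variables = "resistin_ng_ml", m = 2),
               "constant_impute")
})

test_that("constant imputation fills only absent cells and validates its input", {
  df <- data.frame(patient_id = c("A", "B", "C"),
                   resistin_ng_ml = c(NA, NA, NA),
                   crp_mg_l = c(10, NA, 30),
                   working_diagnosis = "pneumonia", stringsAsFactors = FALSE)
  co <- as_cohort_data(df)
  out <- constant_impute(co, "resistin_ng_ml", 5.0)
  expect_identical(out$data$resistin_ng_ml, rep(5.0, 3))
  expect_equal(unique(out$provenance$resistin_ng_ml), "imputed:constant")
  out2 <- constant_impute(co, "crp_mg_l", 99)
  expect_identical(out2$data$crp_mg_l, c(10, 99, 30))
  expect_error(constant_impute(co, "crp_mg_l", NaN), "finite")
})

test_that("a fractional prevalence constant turns a binary column numeric", {
  df <- data.frame(patient_id = c("A", "B"), retractions = NA,
                   working_diagnosis = "pneumonia", stringsAsFactors = FALSE)
  co <- as_cohort_data(df)
  out <- constant_impute(co, "retractions", 0.35)
  expect_type(out$data$retractions, "double")
  expect_identical(out$data$retractions, c(0.35, 0.35))
})

test_that("pooling averages per-imputation values with their SD", {
  p <- pool_results(c(0.6, 0.6, 0.6))
  expect_equal(p$mean, 0.6)
  expect_equal(p$sd, 0)
  expect_equal(pool_results(c(0.5, 0.7))$mean, 0.6)
  expect_equal(pool_results(0.42)$sd, 0)
  expect_error(pool_results(numeric(0)), "empty")
  expect_error(pool_results(c(0.1, NA)), "finite")
})

test_that("pooled ORC over imputations matches an independent summation oracle", {
  co <- make_missing_cohort(n = 80, seed = 17)
  cl_df <- data.frame(
    patient_id = co$data$patient_id,
    category = rep(c(1L, 3L, 5L), length.out = 80))
  imps <- impute_multiple(co, m = 10, seed = 55)
  orcs <- vapply(imps$completed_cohorts, function(c)
    as.numeric(orc(log1p(c$data$crp_mg_l), cl_df$category)), numeric(1))
  p <- pool_results(orcs)
  # independent summation (Kahan-style accumulation not needed at m = 10)
  acc <- 0
  for (v in orcs) acc <- acc + v
  expect_equal(p$mean, acc / 10, tolerance = 1e-12)
})

test_that("pooled ORC converges to the complete-data ORC as missingness vanishes", {
  n <- 300
  set.seed(12)
  base <- data.frame(
    patient_id = sprintf("Z%03d", 1:n),
    crp_mg_l = rlnorm(n, log(30), 1),
    resp_rate = rnorm(n, 45, 8),
    working_diagnosis = "pneumonia", stringsAsFactors = FALSE)
  category <- rep(c(1L, 3L, 5L), length.out = n)
  base$crp_mg_l <- base$crp_mg_l * exp(0.6 * (3 - category) / 2)
  complete_orc <- as.numeric(orc(log1p(base$crp_mg_l), category))
  for (rate in c(0, 0.01)) {
    df <- base
    if (rate > 0) df$crp_mg_l[sample(n, n * rate)] <- NA
    imps <- impute_multiple(as_cohort_data(df), m = 5, seed = 3)
    pooled <- pool_results(vapply(imps$completed_cohorts, function(c)
      as.numeric(orc(log1p(c$data$crp_mg_l), category)), numeric(1)))
    expect_lt(abs(pooled$mean - complete_orc), 0.02)
  }
})
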