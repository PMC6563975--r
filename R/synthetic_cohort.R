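# Synthetic emergency-department cohort generator.
#
# Emulates the statistical structure the validation pipeline assumes: a
# latent five-category aetiology (bacterial -> viral) drives category-level
# shifts in CRP, vitals and examination findings; a single latent severity
# factor per child correlates the vitals; diagnosis codes and pathogen
# detections are drawn consistently with the latent category, so the
# observable reference classifier recovers it; missingness is MCAR at
# configurable per-variable rates. Nothing here reproduces any real cohort
# record-for-record — marginal targets (medians, IQRs, rates) are the only
# points of contact.
#
# Construction note: "unknown" (category 3) children are generated with CRP
# not measured — in the reference standard a measured CRP would resolve
# them to category 2 or 4, so an unknown outcome and a measured CRP cannot
# coexist. The overall CRP-measured target is met by scaling the
# per-category measurement probability among the other categories.

# per-category severity score: +1 (definite bacterial) .. -1 (definite viral)
category_severity <- function(category) (3 - category) / 2

# shift of each binary finding (logit scale) per unit severity
BINARY_SHIFTS <- c(dyspnoea = 0.8, ill_appearance = 0.8, retractions = 0.6,
                   nasal_flaring = 0.4, crackles = 0.6, focal_rales = 0.6,
                   decreased_breath_sounds = 0.8, cap_refill_prolonged = 0.6,
                   something_wrong = 0.8, wheeze = -0.6, chest_pain = 0.3,
                   fever_history = 0)
# binaries also loaded on the latent severity factor z
BINARY_Z_LOADING <- c(dyspnoea = 0.5, ill_appearance = 0.5, retractions = 0.5,
                      something_wrong = 0.5)

#' Cohort generation profile presets
#'
#' Two presets emulate the marginal structure of the study populations:
#' \code{rotterdam_like} (n = 248; age median 14 months, CRP median 16 mg/L
#' measured in 38\%, antibiotics 21\%, category mixture 7/2/38/24/29\%) and
#' \code{coventry_like} (n = 301; age median 19 months, CRP median 45 mg/L
#' measured in 36\%, antibiotics 35\%, mixture 12/5/41/24/18\%, several
#' examination findings wholly unrecorded).
#'
#' @param name \code{"rotterdam_like"} or \code{"coventry_like"}.
#' @param n Cohort size override.
#' @param effect_size Scalar multiplier on every bacterial-vs-viral shift;
#'   0 removes all category-predictor association (null construction), 1 is
#'   the default, realistic separation.
#' @param seed Default seed stored in the profile.
#' @return A \code{cohort_profile} list.
#' @export
preset <- function(name = c("rotterdam_like", "coventry_like"), n = NULL,
                   effect_size = 1, seed = 1L) {
  name <- match.arg(name)
  p <- if (name == "rotterdam_like") list(
    name = name, n = 248,
    category_mixture = c(0.07, 0.02, 0.38, 0.24, 0.29),
    age = list(median = 14, iqr = c(7, 27)),
    crp = list(median = 16, iqr = c(7, 42), measured_rate = 0.38,
               severity_shift = 1.1),
    fever_duration = list(median = 3, iqr = c(2, 4)),
    vitals = list(
      temperature_c = list(mean = 38.2, sd = 1.25, shift = 0.4, z = 0.2,
                           lo = 35, hi = 42),
      resp_rate     = list(mean = 42, sd = 10, shift = 8, z = 3,
                           lo = 15, hi = 120),
      heart_rate    = list(mean = 140, sd = 20, shift = 10, z = 5,
                           lo = 60, hi = 240),
      spo2_pct      = list(mean = 98, sd = 2, shift = -1.5, z = -0.5,
                           lo = 60, hi = 100)),
    binary_rates = c(dyspnoea = 0.43, ill_appearance = 0.23,
                     retractions = 0.64, nasal_flaring = 0.50,
                     crackles = 0.24, focal_rales = 0.44,
                     decreased_breath_sounds = 0.09,
                     cap_refill_prolonged = 0.19, something_wrong = 0.10,
                     wheeze = 0.35, chest_pain = 0.10, fever_history = 0.95),
    male_rate = 0.60,
    missingness = c(resp_rate = 0.26, heart_rate = 0.17, spo2_pct = 0.05,
                    temperature_c = 0.02, fever_duration_days = 0.05,
                    ill_appearance = 0.40, decreased_breath_sounds = 0.45,
                    crackles = 0.49, focal_rales = 0.39, retractions = 0.57,
                    nasal_flaring = 0.77, cap_refill_prolonged = 0.79,
                    wheeze = 0.30, chest_pain = 0.50, something_wrong = 0.30,
                    fever_history = 0.05, dyspnoea = 0),
    rx = list(base_by_category = c(0.85, 0.70, 0.25, 0.10, 0.08),
              crp_coef = 0.3, target_rate = 0.21),
    targets = c(tachypnea = 0.44, tachycardia = 0.32)
  ) else list(
    name = name, n = 301,
    category_mixture = c(0.12, 0.05, 0.41, 0.24, 0.18),
    age = list(median = 19, iqr = c(12, 31)),
    crp = list(median = 45, iqr = c(19, 122), measured_rate = 0.36,
               severity_shift = 1.1),
    fever_duration = NULL,  # not recorded at this site
    vitals = list(
      temperature_c = list(mean = 38.2, sd = 1.2, shift = 0.4, z = 0.2,
                           lo = 35, hi = 42),
      resp_rate     = list(mean = 44, sd = 10, shift = 8, z = 3,
                           lo = 15, hi = 120),
      heart_rate    = list(mean = 155, sd = 22, shift = 10, z = 5,
                           lo = 60, hi = 240),
      spo2_pct      = list(mean = 97, sd = 2, shift = -1.5, z = -0.5,
                           lo = 60, hi = 100)),
    binary_rates = c(dyspnoea = 0.27, ill_appearance = 0.003,
                     cap_refill_prolonged = 0.31, something_wrong = 0.05,
                     wheeze = 0.35, fever_history = 0.95),
    male_rate = 0.58,
    missingness = c(resp_rate = 0.14, heart_rate = 0.02, spo2_pct = 0.05,
                    temperature_c = 0.02, ill_appearance = 0,
                    cap_refill_prolonged = 0.38, wheeze = 0.30,
                    something_wrong = 0.30, fever_history = 0.05,
                    dyspnoea = 0,
                    # wholly unrecorded at this site
                    decreased_breath_sounds = 1, crackles = 1,
                    focal_rales = 1, retractions = 1, nasal_flaring = 1,
                    chest_pain = 1),
    rx = list(base_by_category = c(0.85, 0.70, 0.25, 0.10, 0.08),
              crp_coef = 0.3, target_rate = 0.35),
    targets = c(tachypnea = 0.60, tachycardia = 0.65)
  )
  if (!is.null(n)) p$n <- n
  p$effect_size <- effect_size
  p$seed <- as.integer(seed)
  structure(p, class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile>", x$name, "n =", x$n,
      "effect_size =", x$effect_size, "\n")
  invisible(x)
}

# lognormal sdlog from a median/IQR target
sdlog_from_iqr <- function(iqr) log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))

# offset c such that the lognormal mixture with meanlogs mu + c has the
# target median (solved exactly, so the marginal target is met by design)
solve_median_offset <- function(target_log_median, mu, sdlog, weights) {
  f <- function(c)
    sum(weights * stats::pnorm((target_log_median - (mu + c)) / sdlog)) - 0.5
  stats::uniroot(f, c(-10, 10), tol = 1e-10)$root
}

diagnosis_codes_for <- function(category) {
  switch(category,
         `1` = c("pneumonia", "lrti"),                       # unknown codes;
         `2` = c("complicated_pneumonia", "pleural_effusion", "sepsis"),
         `3` = c("pneumonia", "lrti", "fever_unknown_source"),
         `4` = c("bronchiolitis", "viral_uri", "croup"),
         `5` = c("bronchiolitis", "viral_uri", "influenza_like"))
}

#' Generate a synthetic ED cohort with latent truth
#'
#' @param profile A \code{cohort_profile} from [preset()] (or hand-built
#'   with the same fields).
#' @param n,seed Optional overrides of the profile's size and seed.
#' @return List with \code{cohort} (a \code{cohort} object) and
#'   \code{truth} (data.frame: \code{patient_id}, \code{category} — the
#'   latent aetiology category of each record).
#' @export
generate_cohort <- function(profile, n = NULL, seed = NULL) {
  stopifnot(inherits(profile, "cohort_profile") || is.list(profile))
  mix <- profile$category_mixture
  if (length(mix) != 5 || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("category_mixture must be 5 non-negative probabilities summing to 1")
  if (is.null(n)) n <- profile$n
  if (is.null(seed)) seed <- profile$seed
  es <- profile$effect_size
  if (is.null(es)) es <- 1
  if (es < 0) stop("effect_size must be >= 0")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  category <- sample.int(5, n, replace = TRUE, prob = mix)
  s <- category_severity(category) * es
  z <- stats::rnorm(n)  # latent severity factor, correlates the vitals

  age_sdlog <- sdlog_from_iqr(profile$age$iqr)
  age_months <- stats::rlnorm(n, log(profile$age$median), age_sdlog)
  age_months <- pmax(1, pmin(60, age_months))
  sex <- ifelse(stats::runif(n) < profile$male_rate, "male", "female")

  # CRP: lognormal per category; baseline solved so the median among
  # *measured* CRP (categories != 3) hits the profile target exactly
  crp_sdlog <- sdlog_from_iqr(profile$crp$iqr)
  crp_shift <- profile$crp$severity_shift * es
  sev_levels <- category_severity(1:5)
  w_measured <- mix[-3] / sum(mix[-3])
  offset <- solve_median_offset(log(profile$crp$median),
                                crp_shift * sev_levels[-3], crp_sdlog,
                                w_measured)
  # z-loading of 0.3 on log-CRP; residual scaled so total sdlog stays on target
  crp_resid_sdlog <- sqrt(max(crp_sdlog^2 - 0.3^2, 0.01))
  crp_true <- stats::rlnorm(n, offset + crp_shift * category_severity(category) +
                              0.3 * z, crp_resid_sdlog)

  vit <- function(v) {
    sd_resid <- sqrt(max(v$sd^2 - v$z^2, 0.01))
    x <- v$mean + v$shift * s + v$z * z + stats::rnorm(n, 0, sd_resid)
    pmax(v$lo, pmin(v$hi, x))
  }
  temperature_c <- vit(profile$vitals$temperature_c)
  resp_rate <- vit(profile$vitals$resp_rate)
  heart_rate <- vit(profile$vitals$heart_rate)
  spo2_pct <- vit(profile$vitals$spo2_pct)

  fever_duration_days <- if (is.null(profile$fever_duration)) rep(NA_real_, n)
    else pmax(0.5, stats::rlnorm(n, log(profile$fever_duration$median),
                                 sdlog_from_iqr(profile$fever_duration$iqr)))

  binaries <- list()
  for (b in names(profile$binary_rates)) {
    rate <- profile$binary_rates[[b]]
    lo <- stats::qlogis(min(max(rate, 1e-6), 1 - 1e-6)) +
      BINARY_SHIFTS[[b]] * s
    if (b %in% names(BINARY_Z_LOADING)) lo <- lo + BINARY_Z_LOADING[[b]] * z
    binaries[[b]] <- stats::runif(n) < stats::plogis(lo)
  }

  # diagnosis codes and pathogen detections, consistent with the category
  working_diagnosis <- character(n)
  for (k in 1:5) {
    idx <- which(category == k)
    codes <- diagnosis_codes_for(as.character(k))
    working_diagnosis[idx] <- sample(codes, length(idx), replace = TRUE)
  }
  bacterial_pathogen_detected <- category == 1
  viral_pathogen_detected <- category == 5
  # some bacterial cases carry a viral co-detection; still bacterial
  co <- category == 1 & stats::runif(n) < 0.2
  viral_pathogen_detected[co] <- TRUE

  # CRP measurement: never for "unknown" children, scaled up elsewhere
  pm <- min(1, profile$crp$measured_rate / sum(mix[-3]))
  crp_measured <- category != 3 & stats::runif(n) < pm
  crp_mg_l <- ifelse(crp_measured, crp_true, NA_real_)

  # prescription model: category base rate + CRP effect, intercept
  # calibrated so the expected marginal rate equals the site target
  rx <- profile$rx
  base_logit <- stats::qlogis(rx$base_by_category[category])
  crp_term <- ifelse(crp_measured,
                     rx$crp_coef * (log1p(crp_true) -
                                      log1p(profile$crp$median)), 0)
  lp <- base_logit + crp_term
  delta <- stats::uniroot(function(d) mean(stats::plogis(lp + d)) -
                            rx$target_rate, c(-10, 10), tol = 1e-10)$root
  antibiotics_prescribed <- stats::runif(n) < stats::plogis(lp + delta)

  df <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                   age_months = age_months, sex = sex,
                   temperature_c = temperature_c,
                   fever_duration_days = fever_duration_days,
                   resp_rate = resp_rate, heart_rate = heart_rate,
                   spo2_pct = spo2_pct,
                   working_diagnosis = working_diagnosis,
                   bacterial_pathogen_detected = bacterial_pathogen_detected,
                   viral_pathogen_detected = viral_pathogen_detected,
                   crp_mg_l = crp_mg_l,
                   antibiotics_prescribed = antibiotics_prescribed,
                   stringsAsFactors = FALSE)
  for (b in names(binaries)) df[[b]] <- binaries[[b]]

  # MCAR missingness, applied after value generation
  for (v in names(profile$missingness)) {
    rate <- profile$missingness[[v]]
    if (rate > 0 && v %in% names(df))
      df[[v]][stats::runif(n) < rate] <- NA
  }

  cohort <- as_cohort_data(df, name = profile$name)
  truth <- data.frame(patient_id = df$patient_id, category = category,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}
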