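# Declarative prediction-model specifications and their evaluation.
#
# Two families of models are supported:
#   * rule models (rule_any_of, rule_tree) emit a binary high/low risk class
#     from predicates over predictors;
#   * logistic models emit a predicted probability via
#     inverse-logit(intercept + sum coefficient * transform(predictor)).
# Specs are plain YAML files; the ones shipped under
# inst/extdata/models/ describe the seven validated pneumonia models.

RULE_FORMS <- c("rule_any_of", "rule_tree")
MODEL_FORMS <- c(RULE_FORMS, "logistic")
PREDICATE_OPS <- c("ge", "gt", "le", "lt", "eq", "is_true", "is_false")
TRANSFORMS <- c("identity", "log", "log1p", "threshold", "equals")

#' Load and validate a prediction-model specification
#'
#' @param path Path to a YAML model spec with fields \code{name},
#'   \code{form} (\code{rule_any_of}, \code{rule_tree} or \code{logistic}),
#'   \code{predicates} (rule forms) or \code{intercept} + \code{terms}
#'   (logistic), and optional \code{derivation_constants},
#'   \code{derivation_prevalence}, \code{source} and \code{provenance}.
#' @param schema Data dictionary the predictor variables must belong to.
#' @return A validated \code{model_spec} object.
#' @export
load_model_spec <- function(path, schema = cohort_dictionary()) {
  spec <- yaml::read_yaml(path)
  validate_model_spec(spec, schema)
}

#' Validate an in-memory model specification
#'
#' Checks the structural contract of a model spec list: known form, every
#' predictor in the data dictionary, predicates with valid operators for
#' rule forms, finite intercept and coefficients for logistic forms.
#'
#' @param spec A list with the fields described in [load_model_spec()].
#' @param schema Data dictionary.
#' @return The spec, classed \code{model_spec}.
#' @export
validate_model_spec <- function(spec, schema = cohort_dictionary()) {
  if (is.null(spec$name)) stop("model spec lacks a name")
  if (is.null(spec$form) || !spec$form %in% MODEL_FORMS)
    stop("model '", spec$name, "': form must be one of ",
         paste(MODEL_FORMS, collapse = ", "))
  known <- schema$variable
  check_var <- function(v, what) {
    if (is.null(v) || !v %in% known)
      stop("model '", spec$name, "': ", what, " names unknown variable '",
           if (is.null(v)) "<missing>" else v, "'")
  }
  if (spec$form %in% RULE_FORMS) {
    if (length(spec$predicates) == 0)
      stop("model '", spec$name, "': rule form requires predicates")
    for (p in spec$predicates) {
      check_var(p$variable, "predicate")
      if (is.null(p$op) || !p$op %in% PREDICATE_OPS)
        stop("model '", spec$name, "': predicate on '", p$variable,
             "' lacks a valid op")
      if (!p$op %in% c("is_true", "is_false") && is.null(p$value))
        stop("model '", spec$name, "': predicate on '", p$variable,
             "' lacks a value")
      if (!is.null(p$when)) {
        check_var(p$when$variable, "predicate condition")
        if (is.null(p$when$op) || !p$when$op %in% PREDICATE_OPS)
          stop("model '", spec$name, "': condition on '", p$when$variable,
               "' lacks a valid op")
      }
    }
    if (!is.null(spec$terms))
      stop("model '", spec$name, "': rule forms take predicates, not terms")
  } else {
    if (length(spec$terms) == 0)
      stop("model '", spec$name, "': logistic form requires terms")
    if (is.null(spec$intercept) || !is.finite(spec$intercept))
      stop("model '", spec$name, "': logistic form requires a finite intercept")
    for (t in spec$terms) {
      check_var(t$variable, "term")
      if (is.null(t$coefficient) || !is.finite(t$coefficient))
        stop("model '", spec$name, "': coefficient missing for term on '",
             t$variable, "'")
      tr <- if (is.null(t$transform)) "identity" else t$transform
      if (!tr %in% TRANSFORMS)
        stop("model '", spec$name, "': unknown transform '", tr, "'")
      if (tr %in% c("threshold", "equals") && is.null(t$value))
        stop("model '", spec$name, "': transform '", tr, "' on '",
             t$variable, "' requires a value")
    }
  }
  for (v in names(spec$derivation_constants)) check_var(v, "derivation constant")
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "(", x$form, ")\n")
  cat("predictors:", paste(model_predictors(x), collapse = ", "), "\n")
  invisible(x)
}

#' Predictor variables used by a model
#'
#' Includes predicate condition variables and constant-imputed predictors.
#'
#' @param spec A \code{model_spec}.
#' @return Character vector of variable names.
#' @export
model_predictors <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$form %in% RULE_FORMS) {
    vars <- unlist(lapply(spec$predicates, function(p)
      c(p$variable, p$when$variable)))
  } else {
    vars <- vapply(spec$terms, function(t) t$variable, character(1))
  }
  unique(c(vars, names(spec$derivation_constants)))
}

#' Truncate CRP at the modelling cap
#'
#' CRP values entering a prediction model are capped at 225 mg/L. The raw
#' value is still used by the reference-standard classifier.
#'
#' @param value Numeric CRP in mg/L (NA passed through).
#' @param cap Truncation level, default 225 mg/L.
#' @return \code{pmin(value, cap)}.
#' @export
truncate_crp <- function(value, cap = 225) {
  if (any(!is.na(value) & value < 0)) stop("CRP must be >= 0")
  pmin(value, cap)
}

eval_predicate <- function(p, data) {
  x <- data[[p$variable]]
  res <- switch(p$op,
    ge = x >= p$value, gt = x > p$value,
    le = x <= p$value, lt = x < p$value,
    eq = x == p$value,
    is_true = x, is_false = !x)
  if (!is.null(p$when)) {
    cond <- eval_predicate(p$when, data)
    # a gated predicate only fires when its condition holds
    res <- res & cond
  }
  res
}

#' Evaluate a rule-classification model on a cohort
#'
#' A record is classified high risk if any predicate holds (for both
#' \code{rule_any_of} and single-split \code{rule_tree} forms this is the
#' published decision logic). All predicate variables must be resolved
#' (raw, proxy or imputed) for every record.
#'
#' @param spec A rule-form \code{model_spec}.
#' @param cohort A \code{cohort} object.
#' @return data.frame with \code{patient_id}, \code{model},
#'   \code{risk_class} (\code{"high"}/\code{"low"}).
#' @export
evaluate_rule_model <- function(spec, cohort) {
  stopifnot(inherits(spec, "model_spec"), inherits(cohort, "cohort"))
  if (!spec$form %in% RULE_FORMS)
    stop("model '", spec$name, "' is not a rule model")
  data <- cohort$data
  high <- rep(FALSE, nrow(data))
  for (p in spec$predicates) {
    needed <- c(p$variable, p$when$variable)
    for (v in needed) if (anyNA(data[[v]]))
      stop("model '", spec$name, "': predictor '", v,
           "' unresolved (absent) for some records")
    high <- high | eval_predicate(p, data)
  }
  data.frame(patient_id = data$patient_id, model = spec$name,
             risk_class = ifelse(high, "high", "low"),
             stringsAsFactors = FALSE)
}

apply_transform <- function(x, term) {
  tr <- if (is.null(term$transform)) "identity" else term$transform
  switch(tr,
    identity = as.numeric(x),
    log = log(x),
    log1p = log1p(x),
    threshold = {
      op <- if (is.null(term$op)) "ge" else term$op
      as.numeric(switch(op, ge = x >= term$value, gt = x > term$value,
                        le = x <= term$value, lt = x < term$value))
    },
    equals = as.numeric(x == term$value))
}

#' Evaluate a logistic prediction model on a cohort
#'
#' Computes risk = inverse-logit(intercept + sum coefficient * transformed
#' predictor). CRP is passed through [truncate_crp()] before any transform.
#' Every term's predictor must be resolved for every record.
#'
#' @param spec A logistic-form \code{model_spec}.
#' @param cohort A \code{cohort} object.
#' @return data.frame with \code{patient_id}, \code{model}, \code{risk}
#'   (probability in (0,1)).
#' @export
evaluate_logistic_model <- function(spec, cohort) {
  stopifnot(inherits(spec, "model_spec"), inherits(cohort, "cohort"))
  if (spec$form != "logistic")
    stop("model '", spec$name, "' is not a logistic model")
  data <- cohort$data
  lp <- rep(spec$intercept, nrow(data))
  for (term in spec$terms) {
    x <- data[[term$variable]]
    if (anyNA(x))
      stop("model '", spec$name, "': predictor '", term$variable,
           "' unresolved (absent) for some records")
    if (term$variable == "crp_mg_l") x <- truncate_crp(x)
    lp <- lp + term$coefficient * apply_transform(x, term)
  }
  if (any(!is.finite(lp)))
    stop("model '", spec$name, "': non-finite linear predictor")
  data.frame(patient_id = data$patient_id, model = spec$name,
             risk = stats::plogis(lp), stringsAsFactors = FALSE)
}

#' Evaluate any model on a cohort
#'
#' Dispatches on the spec's form to [evaluate_rule_model()] or
#' [evaluate_logistic_model()].
#'
#' @inheritParams evaluate_rule_model
#' @return Tidy data.frame of predictions.
#' @export
evaluate_model <- function(spec, cohort) {
  if (spec$form %in% RULE_FORMS) evaluate_rule_model(spec, cohort)
  else evaluate_logistic_model(spec, cohort)
}

#' Predictor availability and the inclusion gate
#'
#' A predictor counts as available if it is present (directly or via an
#' already-applied proxy) for at least one record. A model is validated
#' only when strictly more than half of its predictors are available;
#' exactly half excludes it.
#'
#' @param spec A \code{model_spec}.
#' @param cohort A \code{cohort} object (after proxy substitution).
#' @return List with \code{n_predictors}, \code{n_available},
#'   \code{fraction}, \code{include} (logical), \code{unavailable}
#'   (character vector).
#' @export
predictor_availability <- function(spec, cohort) {
  stopifnot(inherits(spec, "model_spec"), inherits(cohort, "cohort"))
  vars <- model_predictors(spec)
  avail <- vapply(vars, function(v) any(!is.na(cohort$data[[v]])), logical(1))
  list(n_predictors = length(vars),
       n_available = sum(avail),
       fraction = sum(avail) / length(vars),
       include = (sum(avail) / length(vars)) > 0.5,
       unavailable = vars[!avail])
}

#' Age-banded tachypnea and tachycardia flags
#'
#' Derives the binary tachypnea/tachycardia predictors from respiratory and
#' heart rate using age-banded cutoffs (APLS-style bands by default).
#' Recorded binary values are never overwritten; only absent flags with a
#' present rate and age are filled, with provenance \code{"derived:<rate>"}.
#'
#' @param cohort A \code{cohort} object.
#' @param rr_cutoffs,hr_cutoffs data.frames with columns \code{age_lo}
#'   (months, inclusive) and \code{cutoff} (rate at or above which the flag
#'   is true).
#' @return The cohort with \code{tachypnea}/\code{tachycardia} filled in.
#' @export
derive_vital_flags <- function(cohort,
                               rr_cutoffs = data.frame(
                                 age_lo = c(0, 12, 60), cutoff = c(50, 40, 30)),
                               hr_cutoffs = data.frame(
                                 age_lo = c(0, 12, 24, 60),
                                 cutoff = c(160, 150, 140, 120))) {
  stopifnot(inherits(cohort, "cohort"))
  banded <- function(age, rate, cuts) {
    idx <- findInterval(age, cuts$age_lo)
    rate >= cuts$cutoff[idx]
  }
  d <- cohort$data
  fill <- function(flag, rate_var, cuts) {
    can <- is.na(d[[flag]]) & !is.na(d[[rate_var]]) & !is.na(d$age_months)
    if (any(can)) {
      cohort$data[[flag]][can] <<- banded(d$age_months[can],
                                          d[[rate_var]][can], cuts)
      cohort$provenance[[flag]][can] <<- paste0("derived:", rate_var)
    }
  }
  fill("tachypnea", "resp_rate", rr_cutoffs)
  fill("tachycardia", "heart_rate", hr_cutoffs)
  cohort
}

#' Load all model specs from a directory
#'
#' @param dir Directory containing \code{*.yaml} model specs; defaults to
#'   the seven specs shipped with the package.
#' @param schema Data dictionary.
#' @return Named list of \code{model_spec} objects.
#' @export
load_model_dir <- function(dir = system.file("extdata", "models",
                                             package = "ordival"),
                           schema = cohort_dictionary()) {
  paths <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (length(paths) == 0) stop("no model specs found in ", dir)
  specs <- lapply(paths, load_model_spec, schema = schema)
  stats::setNames(specs, vapply(specs, function(s) s$name, character(1)))
}
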