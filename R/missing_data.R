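# Multiple imputation of partially missing predictors and pooling of
# downstream statistics across completed datasets.
#
# Two imputers are provided:
#   * chained_equations — fully conditional specification: each partially
#     missing variable is regressed on the other cohort variables;
#     continuous variables are imputed by predictive-mean matching
#     (k nearest donors on the predicted scale), binary variables by draws
#     from a logistic model. This is the default, matching standard
#     practice for ED cohort data.
#   * marginal_hotdeck — each absent cell is replaced by a draw from the
#     variable's observed marginal; dependency-light, used as a fallback
#     and in stress tests.
# Pooling is simple averaging of the downstream statistic across the m
# completed datasets (mean and SD); Rubin's variance rules are deliberately
# not applied, because the analyses report mean +/- SD of the statistic only.

IMPUTE_METHODS <- c("chained_equations", "marginal_hotdeck")

# numeric design matrix from cohort columns usable as imputation predictors
imputation_design <- function(data, exclude) {
  cols <- setdiff(names(data), c("patient_id", "working_diagnosis", exclude))
  mats <- list(`(Intercept)` = rep(1, nrow(data)))
  for (v in cols) {
    col <- data[[v]]
    if (is.logical(col)) mats[[v]] <- as.numeric(col)
    else if (is.numeric(col)) mats[[v]] <- col
    else if (v == "sex") mats[["sex_male"]] <- as.numeric(col == "male")
  }
  do.call(cbind, mats)
}

fit_and_predict_lm <- function(X, y, obs) {
  keep <- colSums(is.na(X)) == 0
  Xc <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xc[obs, , drop = FALSE], y[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  drop(Xc %*% beta)
}

pmm_draw <- function(pred, y, obs, miss, k = 5) {
  oy <- y[obs]
  op <- pred[obs]
  vapply(pred[miss], function(p) {
    d <- abs(op - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    oy[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}

logistic_draw <- function(X, y, obs, miss) {
  keep <- colSums(is.na(X)) == 0
  Xc <- X[, keep, drop = FALSE]
  p <- tryCatch({
    fit <- suppressWarnings(stats::glm.fit(Xc[obs, , drop = FALSE],
                                           as.numeric(y[obs]),
                                           family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    stats::plogis(drop(Xc[miss, , drop = FALSE] %*% beta))
  }, error = function(e) rep(mean(y[obs]), sum(miss)))
  p[!is.finite(p)] <- mean(y[obs])
  stats::runif(length(p)) < p
}

impute_once_chained <- function(data, imp_vars, maxit = 5, pmm_k = 5) {
  miss_idx <- lapply(imp_vars, function(v) which(is.na(data[[v]])))
  names(miss_idx) <- imp_vars
  # initialise by marginal draws
  for (v in imp_vars) {
    obs <- data[[v]][!is.na(data[[v]])]
    data[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                       replace = TRUE)
  }
  model_vars <- imp_vars[vapply(imp_vars, function(v)
    is.numeric(data[[v]]) || is.logical(data[[v]]), logical(1))]
  for (iter in seq_len(maxit)) {
    for (v in model_vars) {
      miss <- seq_len(nrow(data)) %in% miss_idx[[v]]
      if (!any(miss)) next
      obs <- !miss
      X <- imputation_design(data, exclude = v)
      y <- data[[v]]
      if (is.logical(y)) {
        data[[v]][miss] <- logistic_draw(X, y, obs, miss)
      } else {
        pred <- fit_and_predict_lm(X, as.numeric(y), obs)
        data[[v]][miss] <- pmm_draw(pred, y, obs, miss, k = pmm_k)
      }
    }
  }
  data
}

impute_once_hotdeck <- function(data, imp_vars) {
  for (v in imp_vars) {
    miss <- is.na(data[[v]])
    obs <- data[[v]][!miss]
    data[[v]][miss] <- sample(obs, sum(miss), replace = TRUE)
  }
  data
}

#' Multiply impute partially missing variables
#'
#' Produces m completed cohorts. Observed cells are never altered; only
#' absent cells among \code{variables} are filled, with provenance
#' \code{"imputed:<method>"}. One master seed spawns per-imputation
#' substreams, so results are deterministic given the seed and m is
#' reproducibly extensible.
#'
#' @param cohort A \code{cohort} object.
#' @param variables Variables to impute (default: every dictionary variable
#'   with at least one absent and one observed value).
#' @param m Number of imputations (default 10).
#' @param seed Integer master seed.
#' @param method \code{"chained_equations"} (default) or
#'   \code{"marginal_hotdeck"}.
#' @param maxit Sweeps of the chained-equations sampler (default 5).
#' @return An \code{imputation_set}: list with \code{completed_cohorts}
#'   (list of m cohorts), \code{m}, \code{seed}, \code{method}.
#' @export
impute_multiple <- function(cohort, variables = NULL, m = 10, seed = 1,
                            method = c("chained_equations", "marginal_hotdeck"),
                            maxit = 5) {
  stopifnot(inherits(cohort, "cohort"), m >= 1)
  method <- match.arg(method)
  data <- cohort$data
  if (is.null(variables)) {
    variables <- names(data)[vapply(names(data), function(v)
      anyNA(data[[v]]) && any(!is.na(data[[v]])), logical(1))]
  }
  for (v in variables) {
    if (!v %in% names(data)) stop("unknown variable: ", v)
    if (all(is.na(data[[v]])))
      stop("variable '", v, "' has no observed values; use constant_impute ",
           "(derivation constant) or a proxy instead of multiple imputation")
  }
  imp_vars <- variables[vapply(variables, function(v) anyNA(data[[v]]),
                               logical(1))]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, m)
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(sub_seeds[i])
    di <- if (length(imp_vars) == 0) data
          else if (method == "chained_equations")
            impute_once_chained(data, imp_vars, maxit = maxit)
          else impute_once_hotdeck(data, imp_vars)
    prov <- cohort$provenance
    for (v in imp_vars) {
      filled <- is.na(data[[v]]) & !is.na(di[[v]])
      prov[[v]][filled] <- paste0("imputed:", method)
    }
    completed[[i]] <- new_cohort(di, paste0(cohort$name, " [imputation ", i, "]"),
                                 prov)
  }
  structure(list(completed_cohorts = completed, m = m, seed = seed,
                 method = method), class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m =", x$m, "method =", x$method, "seed =", x$seed, "\n")
  invisible(x)
}

#' Constant imputation from a derivation-population value
#'
#' Fills every absent cell of one variable with a single constant — the
#' variable's mean or prevalence in the prediction model's original
#' derivation population. Used for predictors that are wholly unmeasured in
#' the validation cohort, where multiple imputation is impossible.
#'
#' @param cohort A \code{cohort} object.
#' @param variable Variable name.
#' @param derivation_value Finite numeric (or logical) constant.
#' @return The cohort with absent cells filled, provenance
#'   \code{"imputed:constant"}.
#' @export
constant_impute <- function(cohort, variable, derivation_value) {
  stopifnot(inherits(cohort, "cohort"))
  if (!variable %in% names(cohort$data)) stop("unknown variable: ", variable)
  if (length(derivation_value) != 1 || !is.finite(as.numeric(derivation_value)))
    stop("derivation_value must be a single finite number")
  miss <- is.na(cohort$data[[variable]])
  if (is.logical(cohort$data[[variable]])) {
    v <- as.numeric(derivation_value)
    if (v %in% c(0, 1)) {
      derivation_value <- as.logical(v)
    } else {
      # fractional prevalence: mean imputation turns the column numeric
      cohort$data[[variable]] <- as.numeric(cohort$data[[variable]])
      derivation_value <- v
    }
  }
  cohort$data[[variable]][miss] <- derivation_value
  cohort$provenance[[variable]][miss] <- "imputed:constant"
  cohort
}

#' Pool a statistic across imputations
#'
#' Simple averaging: the pooled estimate is the arithmetic mean of the
#' per-imputation values and the reported uncertainty their standard
#' deviation (0 when m = 1).
#'
#' @param per_imputation_values Non-empty numeric vector of finite values.
#' @return A \code{pooled_estimate}: list with \code{mean}, \code{sd},
#'   \code{per_imputation_values}.
#' @export
pool_results <- function(per_imputation_values) {
  x <- as.numeric(per_imputation_values)
  if (length(x) == 0) stop("cannot pool an empty set of values")
  if (any(!is.finite(x))) stop("per-imputation values must all be finite")
  structure(list(mean = mean(x),
                 sd = if (length(x) == 1) 0 else stats::sd(x),
                 per_imputation_values = x),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate: %.4f (SD %.4f, m = %d)\n",
              x$mean, x$sd, length(x$per_imputation_values)))
  invisible(x)
}
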