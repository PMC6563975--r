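# Reading, validating and normalising patient-level cohort tables.

#' Canonical cohort data dictionary
#'
#' Returns the data dictionary used throughout the package: one entry per
#' canonical column, giving its type and whether it is mandatory. Optional
#' fields distinguish "absent / not recorded" (\code{NA}) from \code{FALSE}
#' or \code{0}; that distinction is what drives proxy substitution,
#' imputation and the predictor-availability gate.
#'
#' @return A data.frame with columns \code{variable}, \code{type}
#'   (\code{"character"}, \code{"numeric"}, \code{"logical"}) and
#'   \code{mandatory}.
#' @export
cohort_dictionary <- function() {
  dict <- rbind(
    c("patient_id",                 "character", TRUE),
    c("age_months",                 "numeric",   FALSE),
    c("sex",                        "character", FALSE),
    c("temperature_c",              "numeric",   FALSE),
    c("fever_duration_days",        "numeric",   FALSE),
    c("resp_rate",                  "numeric",   FALSE),
    c("heart_rate",                 "numeric",   FALSE),
    c("spo2_pct",                   "numeric",   FALSE),
    c("ill_appearance",             "logical",   FALSE),
    c("dyspnoea",                   "logical",   FALSE),
    c("retractions",                "logical",   FALSE),
    c("nasal_flaring",              "logical",   FALSE),
    c("crackles",                   "logical",   FALSE),
    c("focal_rales",                "logical",   FALSE),
    c("decreased_breath_sounds",    "logical",   FALSE),
    c("wheeze",                     "logical",   FALSE),
    c("chest_pain",                 "logical",   FALSE),
    c("cap_refill_prolonged",       "logical",   FALSE),
    c("something_wrong",            "logical",   FALSE),
    c("tachypnea",                  "logical",   FALSE),
    c("tachycardia",                "logical",   FALSE),
    c("fever_history",              "logical",   FALSE),
    c("crp_mg_l",                   "numeric",   FALSE),
    c("resistin_ng_ml",             "numeric",   FALSE),
    c("procalcitonin_ng_ml",        "numeric",   FALSE),
    c("working_diagnosis",          "character", TRUE),
    c("bacterial_pathogen_detected","logical",   FALSE),
    c("viral_pathogen_detected",    "logical",   FALSE),
    c("antibiotics_prescribed",     "logical",   FALSE)
  )
  data.frame(variable = dict[, 1], type = dict[, 2],
             mandatory = as.logical(dict[, 3]), stringsAsFactors = FALSE)
}

parse_logical_cell <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

parse_numeric_cell <- function(x) {
  suppressWarnings(as.numeric(trimws(x)))
}

new_cohort <- function(data, name, provenance) {
  stopifnot(is.data.frame(data), nrow(data) == nrow(provenance))
  structure(list(data = data, name = name, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", x$name, "-", nrow(x$data), "records,",
      ncol(x$data), "variables\n")
  miss <- missingness_summary(x)
  miss <- miss[miss$missing > 0, , drop = FALSE]
  if (nrow(miss) > 0) {
    cat("variables with missing values:\n")
    for (i in seq_len(nrow(miss)))
      cat(sprintf("  %-26s %d/%d (%.0f%%)\n", miss$variable[i],
                  miss$missing[i], miss$n[i], 100 * miss$fraction[i]))
  }
  invisible(x)
}

#' Read a patient-level cohort table
#'
#' Reads a delimited text file (CSV with header) against the data dictionary.
#' Cells that are empty, literal \code{"NA"}, or unparseable under the
#' column's declared type become "absent" (\code{NA}); columns missing from
#' the file are created as 100\% absent so downstream availability logic sees
#' them. A per-column missingness summary is attached.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Data dictionary, as returned by [cohort_dictionary()].
#' @param name Cohort name (defaults to the file name).
#' @param rename_map Optional named character vector mapping file column
#'   names to canonical dictionary names (\code{c(file_name = "canonical")}).
#' @return A \code{cohort} object: list with \code{data} (typed data.frame),
#'   \code{name}, and \code{provenance} (character data.frame, \code{"raw"}
#'   where observed, \code{"absent"} where not recorded).
#' @export
read_cohort <- function(path, schema = cohort_dictionary(),
                        name = basename(path), rename_map = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!is.null(rename_map)) {
    hit <- names(raw) %in% names(rename_map)
    names(raw)[hit] <- unname(rename_map[names(raw)[hit]])
  }
  mandatory <- schema$variable[schema$mandatory]
  absent_cols <- setdiff(mandatory, names(raw))
  if (length(absent_cols) > 0)
    stop("mandatory column(s) missing from ", path, ": ",
         paste(absent_cols, collapse = ", "))
  as_cohort_data(raw, schema, name)
}

#' Build a cohort from an in-memory data.frame
#'
#' Same typing and validation rules as [read_cohort()], for programmatic use
#' (e.g. the synthetic generator).
#'
#' @param df A data.frame; character columns are parsed per the dictionary.
#' @inheritParams read_cohort
#' @return A \code{cohort} object.
#' @export
as_cohort_data <- function(df, schema = cohort_dictionary(), name = "cohort") {
  n <- nrow(df)
  data <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(schema))) {
    var <- schema$variable[i]
    type <- schema$type[i]
    if (var %in% names(df)) {
      col <- df[[var]]
      if (is.character(col)) {
        col[trimws(col) %in% c("", "NA")] <- NA
        col <- switch(type,
                      character = trimws(col),
                      numeric   = parse_numeric_cell(col),
                      logical   = parse_logical_cell(col))
      } else {
        col <- switch(type,
                      character = as.character(col),
                      numeric   = as.numeric(col),
                      logical   = as.logical(col))
      }
    } else {
      col <- rep(switch(type, character = NA_character_,
                        numeric = NA_real_, logical = NA), n)
    }
    data[[var]] <- col
  }
  if (anyNA(data$patient_id))
    stop("patient_id contains absent values")
  if (anyDuplicated(data$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(data$patient_id[duplicated(data$patient_id)]),
               collapse = ", "))
  if (anyNA(data$working_diagnosis))
    stop("working_diagnosis contains absent values")
  bad_age <- !is.na(data$age_months) & data$age_months <= 0
  if (any(bad_age)) stop("age_months must be > 0")
  bad_spo2 <- !is.na(data$spo2_pct) & (data$spo2_pct < 0 | data$spo2_pct > 100)
  if (any(bad_spo2)) stop("spo2_pct must lie in [0, 100]")
  bad_crp <- !is.na(data$crp_mg_l) & data$crp_mg_l < 0
  if (any(bad_crp)) stop("crp_mg_l must be >= 0 when present")

  prov <- as.data.frame(
    lapply(data, function(col) ifelse(is.na(col), "absent", "raw")),
    stringsAsFactors = FALSE)
  new_cohort(data, name, prov)
}

#' Per-column missingness summary
#'
#' @param cohort A \code{cohort} object.
#' @return A data.frame with \code{variable}, \code{n}, \code{missing},
#'   \code{fraction} (missing / n).
#' @export
missingness_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$data)
  miss <- vapply(cohort$data, function(col) sum(is.na(col)), integer(1))
  data.frame(variable = names(miss), n = n, missing = unname(miss),
             fraction = unname(miss) / n, stringsAsFactors = FALSE)
}

#' Write a cohort back to CSV
#'
#' Inverse of [read_cohort()]: absent values are written as empty cells, so a
#' read/write/read round trip preserves both values and missingness flags.
#'
#' @param cohort A \code{cohort} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- cohort$data
  for (v in names(out)) {
    if (is.logical(out[[v]])) out[[v]] <- ifelse(is.na(out[[v]]), "",
                                                 ifelse(out[[v]], "true", "false"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Substitute proxy variables for completely unrecorded predictors
#'
#' For every record where the target variable is absent and the source
#' variable is present, the target takes the source's value and its
#' provenance is marked \code{"proxy:<source>"}. Present target values are
#' never overwritten. Substitution happens before imputation and before
#' model evaluation.
#'
#' @param cohort A \code{cohort} object.
#' @param proxy_map Named character vector or list: \code{c(target = "source")},
#'   e.g. \code{c(dyspnoea = "retractions")}.
#' @return The cohort with substituted values and updated provenance.
#' @export
apply_proxy_map <- function(cohort, proxy_map) {
  stopifnot(inherits(cohort, "cohort"))
  proxy_map <- unlist(proxy_map)
  if (length(proxy_map) == 0) return(cohort)
  vars <- names(cohort$data)
  unknown <- setdiff(c(names(proxy_map), unname(proxy_map)), vars)
  if (length(unknown) > 0)
    stop("proxy map names unknown variable(s): ", paste(unknown, collapse = ", "))
  # cycle detection by walking each chain target -> source -> ...
  for (start in names(proxy_map)) {
    seen <- start
    cur <- unname(proxy_map[[start]])
    while (cur %in% names(proxy_map)) {
      if (cur %in% seen)
        stop("proxy cycle involving: ", paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- unname(proxy_map[[cur]])
    }
    if (cur %in% seen)
      stop("proxy cycle involving: ", paste(c(seen, cur), collapse = " -> "))
  }
  for (target in names(proxy_map)) {
    source <- unname(proxy_map[[target]])
    fill <- is.na(cohort$data[[target]]) & !is.na(cohort$data[[source]])
    if (any(fill)) {
      cohort$data[[target]][fill] <- cohort$data[[source]][fill]
      cohort$provenance[[target]][fill] <- paste0("proxy:", source)
    }
  }
  cohort
}
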