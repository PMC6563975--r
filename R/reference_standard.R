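# Ordinal clinical reference standard: bacterial -> viral, five categories.
#
# The classifier works in two steps. First the working diagnosis (the
# attending clinician's diagnosis at the end of the ED visit) maps to one of
# three initial classes: bacterial_syndrome, viral_syndrome, or unknown.
# Second, pathogen identification and the CRP level (>60 vs <=60 mg/L)
# refine the initial class into a five-category ordinal outcome:
#   1 definite/probable bacterial, 2 bacterial syndrome, 3 unknown,
#   4 viral syndrome, 5 definite/probable viral.
# Pathogen detection outranks everything else; bacterial/viral co-detection
# counts as bacterial, given the consequences for treatment.

#' Ordinal reference category labels
#' @return Named character vector mapping category values 1..5 to labels.
#' @export
reference_categories <- function() {
  c(`1` = "definite_probable_bacterial",
    `2` = "bacterial_syndrome",
    `3` = "unknown",
    `4` = "viral_syndrome",
    `5` = "definite_probable_viral")
}

INITIAL_CLASSES <- c("bacterial_syndrome", "viral_syndrome", "unknown")

#' Default working-diagnosis map
#'
#' A pre-specified mapping from working-diagnosis codes to the initial class
#' of the reference classifier. A focal diagnosis such as pneumonia is
#' aetiologically ambiguous ("unknown"); bronchiolitis and other typical
#' viral presentations map to the viral syndrome; classically bacterial
#' presentations map to the bacterial syndrome. Unmapped codes in a cohort
#' are an error, never silently dropped, so site-specific codes must be made
#' explicit (via [load_diagnosis_map()] or by extending this vector).
#'
#' @return Named character vector: \code{c(code = initial_class)}.
#' @export
default_diagnosis_map <- function() {
  c(pneumonia            = "unknown",
    lrti                 = "unknown",
    fever_unknown_source = "unknown",
    bronchiolitis        = "viral_syndrome",
    viral_uri            = "viral_syndrome",
    croup                = "viral_syndrome",
    influenza_like       = "viral_syndrome",
    complicated_pneumonia = "bacterial_syndrome",
    pleural_effusion     = "bacterial_syndrome",
    sepsis               = "bacterial_syndrome")
}

#' Load a diagnosis map from YAML or JSON
#'
#' @param path File holding a flat mapping \code{code: initial_class}.
#' @return Named character vector, validated against the three initial classes.
#' @export
load_diagnosis_map <- function(path) {
  m <- unlist(yaml::read_yaml(path))
  bad <- setdiff(unique(m), INITIAL_CLASSES)
  if (length(bad) > 0)
    stop("diagnosis map contains invalid initial class(es): ",
         paste(bad, collapse = ", "))
  m
}

#' Map working diagnoses to the initial class
#'
#' @param code Character vector of working-diagnosis codes.
#' @param dx_map Named character vector \code{c(code = initial_class)}.
#' @return Character vector of initial classes.
#' @export
map_working_diagnosis <- function(code, dx_map = default_diagnosis_map()) {
  unmapped <- setdiff(unique(code), names(dx_map))
  if (length(unmapped) > 0)
    stop("working diagnosis code(s) not in diagnosis map: ",
         paste(unmapped, collapse = ", "))
  unname(dx_map[code])
}

#' Refine the initial class into the five-category ordinal outcome
#'
#' Vectorised. Precedence: (a) a bacterial pathogen (alone or with viral
#' co-detection) gives category 1; (b) a viral pathogen only gives
#' category 5; (c) otherwise the initial class decides — bacterial syndrome
#' gives 2 and viral syndrome gives 4 regardless of CRP, while "unknown" is
#' resolved by CRP: >60 mg/L gives 2, <=60 mg/L gives 4 (60 itself is on the
#' low side), and no CRP measured leaves category 3. The CRP used here is
#' the raw measured value, not the 225 mg/L-truncated modelling value.
#'
#' @param initial Character vector of initial classes.
#' @param bacterial_detected,viral_detected Logical vectors (NA treated as
#'   FALSE: no documented identification).
#' @param crp Numeric vector of CRP in mg/L; \code{NA} = not measured.
#' @return Integer vector of categories 1..5.
#' @export
refine_category <- function(initial, bacterial_detected, viral_detected, crp) {
  n <- length(initial)
  stopifnot(length(bacterial_detected) == n, length(viral_detected) == n,
            length(crp) == n)
  bad <- setdiff(unique(initial), INITIAL_CLASSES)
  if (length(bad) > 0)
    stop("invalid initial class: ", paste(bad, collapse = ", "))
  if (any(!is.na(crp) & crp < 0)) stop("crp must be >= 0 when present")
  bact <- !is.na(bacterial_detected) & bacterial_detected
  vir <- !is.na(viral_detected) & viral_detected

  out <- integer(n)
  out[bact] <- 1L
  out[!bact & vir] <- 5L
  rest <- !bact & !vir
  out[rest & initial == "bacterial_syndrome"] <- 2L
  out[rest & initial == "viral_syndrome"] <- 4L
  unk <- rest & initial == "unknown"
  out[unk & !is.na(crp) & crp > 60] <- 2L
  out[unk & !is.na(crp) & crp <= 60] <- 4L
  out[unk & is.na(crp)] <- 3L
  out
}

#' Classify an entire cohort against the reference standard
#'
#' @param cohort A \code{cohort} object.
#' @param dx_map Diagnosis map (see [default_diagnosis_map()]).
#' @return List with \code{category} (integer per record, in record order)
#'   and \code{counts} (named integer vector of length 5, summing to the
#'   cohort size).
#' @export
classify_cohort <- function(cohort, dx_map = default_diagnosis_map()) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  initial <- map_working_diagnosis(d$working_diagnosis, dx_map)
  category <- refine_category(initial, d$bacterial_pathogen_detected,
                              d$viral_pathogen_detected, d$crp_mg_l)
  counts <- table(factor(category, levels = 1:5))
  counts <- stats::setNames(as.integer(counts), reference_categories())
  list(category = category, counts = counts)
}

#' Bacterial-infection flag
#'
#' Collapses the ordinal outcome to the binary endpoint used in the
#' harm/benefit analysis: categories 1 (definite/probable bacterial) and
#' 2 (bacterial syndrome) count as bacterial infection.
#'
#' @param category Integer vector of categories 1..5.
#' @return Logical vector.
#' @export
bacterial_flag <- function(category) {
  if (any(!category %in% 1:5)) stop("category must be in 1..5")
  category <= 2
}
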