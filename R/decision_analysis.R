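# Threshold-based harm/benefit analysis of antibiotic-prescription policies.
#
# Policy under evaluation: withhold antibiotics in children whose predicted
# risk of bacterial pneumonia falls strictly below a threshold (the low-risk
# group), otherwise leave observed care unchanged. Benefit is the reduction
# in overall prescription; harm ("under-treatment") is the number of
# children with a bacterial-category outcome who were actually treated but
# whom the policy labels low risk.

#' Low-risk group mask
#'
#' @param risks Per-record predicted probabilities in [0, 1].
#' @param threshold Risk threshold in (0, 1] (1 allowed as a degenerate
#'   case for testing).
#' @param comparator \code{"lt"} (default, strictly below threshold) or
#'   \code{"le"}, for sensitivity analysis of the boundary convention.
#' @return Logical mask, TRUE where low risk.
#' @export
low_risk_group <- function(risks, threshold, comparator = c("lt", "le")) {
  comparator <- match.arg(comparator)
  stopifnot(all(risks >= 0 & risks <= 1), threshold > 0, threshold <= 1)
  if (comparator == "lt") risks < threshold else risks <= threshold
}

#' Expected prescriptions under a threshold policy
#'
#' Observed prescriptions minus those withheld in the low-risk group.
#'
#' @param rx Logical per-record observed antibiotic prescription.
#' @param low_mask Logical low-risk mask, same length.
#' @return Integer count of expected prescriptions.
#' @export
expected_prescriptions <- function(rx, low_mask) {
  if (length(rx) != length(low_mask)) stop("rx and low_mask lengths differ")
  sum(rx & !low_mask)
}

#' Under-treatment (harm) count
#'
#' Children with a bacterial-category outcome (categories 1-2) who were
#' treated with antibiotics but whom the policy labels low risk.
#'
#' @param low_mask Logical low-risk mask.
#' @param bacterial Logical per-record bacterial flag (see [bacterial_flag()]).
#' @param rx Logical per-record observed prescription.
#' @return Integer count.
#' @export
undertreatment <- function(low_mask, bacterial, rx) {
  if (length(low_mask) != length(bacterial) || length(low_mask) != length(rx))
    stop("mask lengths differ")
  sum(low_mask & bacterial & rx)
}

#' Full threshold report for one model
#'
#' One row per threshold: size of the low-risk group, observed and expected
#' prescriptions, and under-treatment, each also as an integer percentage of
#' the cohort (rounded half away from zero).
#'
#' @param model_name Model label for the output.
#' @param risks Per-record predicted probabilities.
#' @param rx Logical observed prescriptions.
#' @param bacterial Logical bacterial-outcome flags.
#' @param thresholds Numeric vector of risk thresholds (default 0.10, 0.15).
#' @param comparator Boundary convention, see [low_risk_group()].
#' @return data.frame with columns \code{model}, \code{threshold}, \code{n},
#'   \code{n_low_risk}, \code{observed_rx}, \code{expected_rx},
#'   \code{undertreated} and the corresponding \code{pct_*} integer
#'   percentages.
#' @export
threshold_report <- function(model_name, risks, rx, bacterial,
                             thresholds = c(0.10, 0.15),
                             comparator = "lt") {
  n <- length(risks)
  stopifnot(length(rx) == n, length(bacterial) == n)
  rows <- lapply(thresholds, function(t) {
    low <- low_risk_group(risks, t, comparator)
    exp_rx <- expected_prescriptions(rx, low)
    harm <- undertreatment(low, bacterial, rx)
    data.frame(model = model_name, threshold = t, n = n,
               n_low_risk = sum(low),
               observed_rx = sum(rx),
               expected_rx = exp_rx,
               undertreated = harm,
               pct_low_risk = round_half_away(100 * sum(low) / n),
               pct_observed_rx = round_half_away(100 * sum(rx) / n),
               pct_expected_rx = round_half_away(100 * exp_rx / n),
               pct_undertreated = round_half_away(100 * harm / n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
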