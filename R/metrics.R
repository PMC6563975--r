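# Performance metrics: the ordinal c-statistic against the five-category
# reference standard, and binary diagnostic-test arithmetic
# (sensitivity, specificity, likelihood ratios, prevalence).

#' Round half away from zero
#'
#' Reporting convention used for all printed percentages and ratios:
#' ties are rounded away from zero (2.65 -> 2.7 at 1 d.p.), unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Pairwise AUC between two outcome categories
#'
#' The probability that a randomly drawn case from the more-bacterial
#' category a receives a higher score than one from category b, ties
#' counting 1/2 — the Mann-Whitney statistic scaled to [0, 1]. Computed via
#' midranks, so ties are exact.
#'
#' @param scores_a Scores of cases in the more-bacterial category.
#' @param scores_b Scores of cases in the less-bacterial category.
#' @return AUC in [0, 1].
#' @export
pairwise_auc <- function(scores_a, scores_b) {
  na <- length(scores_a); nb <- length(scores_b)
  if (na == 0 || nb == 0) stop("both categories must be non-empty")
  r <- rank(c(scores_a, scores_b))
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}

#' Ordinal c-statistic
#'
#' Extends the AUC to an ordinal outcome: the probability that two cases of
#' randomly selected outcome categories are correctly ranked by the score.
#' Orientation: a higher score is expected for the more-bacterial (lower
#' numbered) category. Two estimators are offered:
#' \describe{
#'   \item{unweighted_pairs (default)}{mean of the pairwise AUCs over all
#'     observed category pairs — each pair of categories counts equally,
#'     matching the "randomly selected outcome categories" reading.}
#'   \item{pooled_pairs}{concordant fraction over all cross-category case
#'     pairs — pairs of categories weighted by their case counts.}
#' }
#' Category pairs with an empty side are dropped from the average and
#' reported via the \code{"dropped_pairs"} attribute.
#'
#' @param scores Numeric score per record (higher = more bacterial risk).
#' @param categories Integer reference category (1..5) per record; 1 is the
#'   most bacterial.
#' @param weighting \code{"unweighted_pairs"} or \code{"pooled_pairs"}.
#' @return ORC in [0, 1], with attribute \code{dropped_pairs}.
#' @export
orc <- function(scores, categories,
                weighting = c("unweighted_pairs", "pooled_pairs")) {
  weighting <- match.arg(weighting)
  stopifnot(length(scores) == length(categories))
  cats <- sort(unique(categories))
  if (length(cats) < 2)
    stop("ORC requires at least two distinct outcome categories")
  pairs <- utils::combn(cats, 2)
  aucs <- numeric(ncol(pairs))
  wts <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- scores[categories == pairs[1, j]]  # more bacterial
    b <- scores[categories == pairs[2, j]]
    aucs[j] <- pairwise_auc(a, b)
    wts[j] <- length(a) * length(b)
  }
  out <- if (weighting == "unweighted_pairs") mean(aucs)
         else sum(aucs * wts) / sum(wts)
  attr(out, "dropped_pairs") <- character(0)
  out
}

#' Pairwise AUC matrix across all categories
#'
#' @param scores,categories As in [orc()].
#' @return 5x5 matrix with AUC(i, j) in the upper triangle (i more
#'   bacterial than j), NA elsewhere and for unobserved pairs.
#' @export
pairwise_auc_matrix <- function(scores, categories) {
  m <- matrix(NA_real_, 5, 5,
              dimnames = list(reference_categories(), reference_categories()))
  for (i in 1:4) for (j in (i + 1):5) {
    a <- scores[categories == i]
    b <- scores[categories == j]
    if (length(a) > 0 && length(b) > 0) m[i, j] <- pairwise_auc(a, b)
  }
  m
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return List with \code{sensitivity} = tp/(tp+fn) and
#'   \code{specificity} = tn/(tn+fp), as fractions.
#' @export
binary_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (tp + fn == 0) stop("no positive cases: sensitivity undefined")
  if (tn + fp == 0) stop("no negative cases: specificity undefined")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Positive likelihood ratio
#'
#' LR+ = sensitivity / (1 - specificity). A specificity of exactly 1 gives
#' \code{Inf}, returned as such (not an error) so callers can report it
#' distinctly.
#'
#' @param sens,spec Fractions in [0, 1].
#' @return LR+ (possibly \code{Inf}).
#' @export
lr_positive <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  if (spec == 1) return(Inf)
  sens / (1 - spec)
}

#' Negative likelihood ratio
#'
#' LR- = (1 - sensitivity) / specificity.
#'
#' @param sens,spec Fractions in [0, 1]; \code{spec} must be > 0.
#' @return LR-.
#' @export
lr_negative <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  if (spec == 0) stop("specificity 0: LR- undefined")
  (1 - sens) / spec
}

#' Prevalence as a percentage
#'
#' @param k Event count.
#' @param n Total count (> 0).
#' @param digits Decimal places for reporting (half away from zero);
#'   \code{NULL} for the unrounded value.
#' @return 100 * k / n.
#' @export
prevalence <- function(k, n, digits = NULL) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- 100 * k / n
  if (is.null(digits)) p else round_half_away(p, digits)
}

#' Cross-tabulate a rule model's risk classes against the reference standard
#'
#' Rule models emit only high/low classes; their per-category behaviour is
#' summarised as a category-by-class contingency table (the histogram-style
#' view), rather than by ORC alone.
#'
#' @param risk_class Character vector (\code{"high"}/\code{"low"}).
#' @param categories Integer reference categories (1..5).
#' @return 5x2 contingency table (category x risk class).
#' @export
class_by_category <- function(risk_class, categories) {
  table(category = factor(categories, levels = 1:5,
                          labels = reference_categories()),
        risk = factor(risk_class, levels = c("low", "high")))
}
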