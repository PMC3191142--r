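#' One-tailed two-sample comparison of the hub index
#'
#' Welch's unequal-variance t test with a one-sided alternative, used to
#' test whether the hub-communication index is larger in one cohort than
#' the other.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @param direction `"greater"` tests mean(a) > mean(b); `"less"` the
#'   reverse.
#' @return One-tailed p-value.
#' @export
one_tailed_two_sample_test <- function(group_a, group_b,
                                       direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      stop("both groups have zero variance and equal means")
    # degenerate but decidable: complete separation
    better <- if (direction == "greater") mean(group_a) > mean(group_b)
              else mean(group_a) < mean(group_b)
    return(if (better) 0 else 1)
  }
  stats::t.test(group_a, group_b, alternative = direction,
                var.equal = FALSE)$p.value
}

#' One-way analysis of variance across groups
#'
#' Classical equal-variance one-way ANOVA F test of equality of group
#' means.  With two groups the p-value coincides with the two-sided pooled
#' t test (F = t^2).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   n >= 2).
#' @return The ANOVA p-value.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups),
                       vapply(groups, length, 1L)))
  if (stats::sd(values) == 0) stop("all observations identical")
  stats::oneway.test(values ~ labels, var.equal = TRUE)$p.value
}

#' ROC curve of a score separating two cohorts
#'
#' Sweeps candidate thresholds — the midpoints between adjacent pooled
#' unique scores plus -Inf and +Inf — and records sensitivity (true-positive
#' rate among `scores_positives`) and specificity (true-negative rate among
#' `scores_negatives`) at each.  With `positive_when = "low"` (the default
#' convention here: patients score lower on the hub index) a subject is
#' called positive when its score falls strictly below the threshold.
#'
#' @param scores_negatives Scores of the negative class (e.g. controls).
#' @param scores_positives Scores of the positive class (e.g. patients).
#' @param positive_when `"low"` or `"high"`: which side of the threshold is
#'   called positive.
#' @return Data frame of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`.
#' @seealso [optimal_cutoff()]
#' @export
roc_curve <- function(scores_negatives, scores_positives,
                      positive_when = c("low", "high")) {
  positive_when <- match.arg(positive_when)
  if (length(scores_negatives) == 0 || length(scores_positives) == 0)
    stop("both score sets must be nonempty")
  u <- sort(unique(c(scores_negatives, scores_positives)))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thresholds <- c(-Inf, mids, Inf)
  call_positive <- function(score, thr) {
    if (positive_when == "low") score < thr else score > thr
  }
  sens <- vapply(thresholds, function(thr)
    mean(call_positive(scores_positives, thr)), 1.0)
  spec <- vapply(thresholds, function(thr)
    mean(!call_positive(scores_negatives, thr)), 1.0)
  out <- data.frame(threshold = thresholds, sensitivity = sens,
                    specificity = spec)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Optimal ROC cutoff by Youden's J
#'
#' Selects the threshold maximizing J = sensitivity + specificity - 1.
#' Ties are broken in favour of higher specificity, then lower threshold.
#'
#' @param roc A [roc_curve()] result.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @examples
#' r <- roc_curve(c(0.7, 0.8, 0.75), c(0.5, 0.55, 0.6), "low")
#' optimal_cutoff(r)  # perfect separation: J = 1
#' @export
optimal_cutoff <- function(roc) {
  if (NROW(roc) == 0) stop("empty ROC curve")
  j <- roc$sensitivity + roc$specificity - 1
  ord <- order(-j, -roc$specificity, roc$threshold)
  best <- ord[1]
  list(threshold = roc$threshold[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       youden_j = j[best])
}
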