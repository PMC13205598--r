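# Internal helpers shared across the metric suites.

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with the standard mid-rank treatment of
#' ties. Used throughout the privacy, bias and predictive-utility suites.
#'
#' @param scores numeric vector of classifier scores (higher = more positive).
#' @param labels logical or 0/1 vector, same length as `scores`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("auroc needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - as.numeric(n1) * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

# Orientation-invariant membership-attack summaries: the attacker score can be
# arbitrarily oriented, so AUROC below 0.5 means an inverted ranking, not
# improved leakage.

#' @rdname mia_orient
#' @export
auroc_star <- function(a) pmax(a, 1 - a)

#' Orientation correction for membership-inference AUROC
#'
#' `auroc_star(a)` = max(a, 1 - a) is the orientation-invariant attack
#' performance; `mia_delta(a)` = |a - 0.5| is the absolute advantage over
#' random guessing.
#'
#' @param a raw attacker AUROC in `[0, 1]`.
#' @return a number in `[0.5, 1]` (`auroc_star`) or `[0, 0.5]` (`mia_delta`).
#' @name mia_orient
#' @export
mia_delta <- function(a) abs(a - 0.5)

# deterministic child seeds (kept < 2^31)
child_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)

`%||%` <- function(a, b) if (is.null(a)) b else a
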