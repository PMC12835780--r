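# Cox partial-likelihood objectives. Risk sets follow the Breslow tie
# convention: R(t) = {j : o_j >= t}, so tied events share one risk set
# that includes each other. All three objectives are invariant to adding
# a constant to every score.

# Internal workhorse: value and (optionally) gradient of
#   -(1/nE) * sum_{i event, i in subset} [ f_i - log sum_{j in R(o_i)} exp f_j ]
# where the risk sets always run over ALL supplied subjects and the
# subset mask restricts only the numerator events.
npll_terms <- function(scores, time, event, subset = NULL,
                       gradient = FALSE) {
  n <- length(scores)
  if (any(!is.finite(scores))) stop("non-finite score")
  if (is.null(subset)) subset <- rep(TRUE, n)
  ev <- event == 1 & subset
  nE <- sum(ev)
  if (nE == 0L) stop("no events in the evaluation subset")

  ord <- order(time)
  ts <- time[ord]; ss <- scores[ord]; es <- ev[ord]
  M <- max(ss)
  suffix <- rev(cumsum(rev(exp(ss - M))))          # sum over {j : pos >= i}
  # map each position to the start of its tie block: risk set of a
  # subject is every position from its block start onward
  block_start <- seq_len(n)
  if (n > 1L) {
    same <- c(FALSE, ts[-1L] == ts[-n])
    for (i in which(same)) block_start[i] <- block_start[i - 1L]
  }
  denom_log <- M + log(suffix[block_start])        # log-denominator per pos
  value <- -(sum(ss[es] - denom_log[es])) / nE

  if (!gradient) return(value)

  # dL/df_j = -(1/nE) [ 1(j event in subset) - exp(f_j) * B_j ],
  # B_j = sum over events i with o_i <= o_j of 1/D_i (j in R(o_i))
  contrib <- ifelse(es, exp(-(denom_log)), 0)
  csum <- cumsum(contrib)
  block_end <- seq_len(n)
  if (n > 1L) {
    same_next <- c(ts[-1L] == ts[-n], FALSE)
    for (i in rev(which(same_next))) block_end[i] <- block_end[i + 1L]
  }
  B <- csum[block_end]
  g_sorted <- -(as.numeric(es) - exp(ss) * B) / nE
  grad <- numeric(n)
  grad[ord] <- g_sorted
  list(value = value, grad = grad)
}

#' Negative Cox partial log-likelihood of a score vector
#'
#' The mean negative log partial likelihood over observed events,
#' `-(1/nE) * sum_i [ f_i - log sum_{j in R(o_i)} exp f_j ]`, with risk
#' sets `R(o_i) = {j : o_j >= o_i}` taken over the *entire* supplied
#' cohort even when `subset` restricts the numerator to one group's
#' events. Numerically stabilised by a max-shift inside the
#' log-sum-exp. Tied event times share a risk set (Breslow convention).
#'
#' @param scores Numeric log-hazard scores, aligned with the cohort.
#' @param cohort A [survival_cohort()].
#' @param subset Optional logical mask; only events inside the mask enter
#'   the sum (risk sets are unaffected).
#' @return A nonnegative scalar.
#' @examples
#' ch <- survival_cohort(1:3, c(1, 1, 1), rep(1, 3), NULL)
#' neg_partial_log_likelihood(rep(0, 3), ch)  # log(3!)/3
#' @export
neg_partial_log_likelihood <- function(scores, cohort, subset = NULL) {
  stopifnot(length(scores) == length(cohort$time))
  npll_terms(scores, cohort$time, cohort$event, subset)
}

#' Group-mean fairness penalty
#'
#' `sum_k (mean score in group k - overall mean score)^2` over the groups
#' present in the input. Added (times `fair_lambda`) to the baseline
#' partial-likelihood loss, it discourages the network from separating
#' groups in mean predicted log-hazard.
#'
#' @param scores Numeric log-hazard scores.
#' @param group Integer/factor group labels aligned with `scores`.
#' @return A nonnegative scalar.
#' @export
fair_penalty <- function(scores, group) {
  if (length(scores) == 0L) stop("empty input")
  if (any(!is.finite(scores))) stop("non-finite score")
  m <- mean(scores)
  gm <- tapply(scores, group, mean)
  sum((gm - m)^2)
}

# gradient of fair_penalty wrt scores
fair_penalty_grad <- function(scores, group) {
  n <- length(scores)
  m <- mean(scores)
  g <- as.character(group)
  gm <- tapply(scores, g, mean)
  gn <- tapply(scores, g, length)
  dev <- gm - m
  as.numeric(2 * dev[g] / gn[g] - (2 / n) * sum(dev))
}

#' Group distributionally robust Cox objective
#'
#' The worst case, over groups, of the group-restricted negative partial
#' log-likelihood: for group `k` the numerator sums over events with
#' `s_i = k` (normalised by that group's event count) while the risk sets
#' still run over the whole cohort; an augmented group `k = 0` is the
#' unrestricted full-cohort loss, so the maximum can never fall below the
#' baseline objective. Groups with zero events cannot form their term and
#' are skipped (recorded in the `"skipped"` attribute).
#'
#' @param scores Numeric log-hazard scores.
#' @param cohort A [survival_cohort()].
#' @return The worst-group loss, with attributes `worst_group` (0 = the
#'   augmented full-cohort group) and `skipped` (group codes with no
#'   events).
#' @export
groupdro_objective <- function(scores, cohort) {
  terms <- groupdro_terms(scores, cohort$time, cohort$event, cohort$group)
  out <- terms$value
  attr(out, "worst_group") <- terms$worst_group
  attr(out, "skipped") <- terms$skipped
  out
}

# internal: all group terms, the max, and optionally the gradient of the
# argmax term (hard-max rule: gradient flows through the worst group)
groupdro_terms <- function(scores, time, event, group,
                           gradient = FALSE) {
  ks <- sort(unique(group))
  vals <- c(`0` = npll_terms(scores, time, event))
  skipped <- integer(0)
  for (k in ks) {
    if (sum(event[group == k]) == 0L) { skipped <- c(skipped, k); next }
    vals[as.character(k)] <- npll_terms(scores, time, event,
                                        subset = group == k)
  }
  worst <- names(vals)[which.max(vals)]
  out <- list(value = unname(max(vals)),
              worst_group = as.integer(worst),
              terms = vals, skipped = skipped)
  if (gradient) {
    sub <- if (worst == "0") NULL else group == as.integer(worst)
    out$grad <- npll_terms(scores, time, event, subset = sub,
                           gradient = TRUE)$grad
  }
  out
}
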