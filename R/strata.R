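# Risk stratification, Kaplan-Meier curves and pairwise log-rank audits.

#' Stratify subjects by predicted risk
#'
#' Assigns each subject to `"low"` (bottom `q_low` of scores), `"high"`
#' (top `1 - q_high`) or `"mid"` (the remainder). Defaults `(0.25, 0.75)`
#' give the high = top 25% / mid = 25-75% / low = bottom 25% scheme; the
#' alternative high 25% / mid 25-50% / low bottom 50% scheme is
#' `cutpoints = c(0.50, 0.75)`. Assignment is rank-based so stratum sizes
#' are within 1 of `n * (q_low, q_high - q_low, 1 - q_high)` when scores
#' are distinct; ties at a boundary are broken by stable subject order.
#' If every score is identical all subjects are assigned to `"mid"` with
#' a warning.
#'
#' @param scores Predicted risk scores (higher = higher risk).
#' @param cutpoints Quantile pair `(q_low, q_high)` with
#'   `0 < q_low < q_high < 1`.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
stratify <- function(scores, cutpoints = c(0.25, 0.75)) {
  q_low <- cutpoints[1]; q_high <- cutpoints[2]
  stopifnot(q_low > 0, q_high < 1, q_low < q_high)
  n <- length(scores)
  if (n < 3L) stop("fewer subjects than strata")
  if (diff(range(scores)) == 0) {
    warning("all scores identical: every subject assigned to 'mid'")
    return(factor(rep("mid", n), levels = c("low", "mid", "high")))
  }
  r <- rank(scores, ties.method = "first")  # stable subject order on ties
  n_low <- round(n * q_low)
  n_high <- round(n * (1 - q_high))
  lab <- rep("mid", n)
  lab[r <= n_low] <- "low"
  lab[r > n - n_high] <- "high"
  factor(lab, levels = c("low", "mid", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with right censoring, with at-risk and event
#' counts at each event time.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event).
#' @return A data.frame with `time`, `surv`, `n_risk`, `n_event`
#'   (event times only; `surv = 1` throughout when there are no events).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], surv = fit$surv[keep],
             n_risk = fit$n.risk[keep], n_event = fit$n.event[keep])
}

#' Two-sample log-rank test
#'
#' Standard two-sided log-rank chi-squared test (1 df) comparing the
#' survival distributions of two groups.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level grouping vector.
#' @return A list with `statistic` and `p_value`; both `NA` with a
#'   `reason` element when the two samples carry no events.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("logrank_test compares exactly two groups")
  if (sum(event) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                reason = "no events in either group"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Risk-stratified fairness audit
#'
#' Stratifies subjects into low/mid/high predicted-risk categories, then
#' checks whether observed survival is comparable across groups *within*
#' each stratum: a fair model should assign subjects with similar true
#' risk to the same stratum regardless of group, so per-group
#' Kaplan-Meier curves inside a stratum should coincide. Every group pair
#' in every stratum is tested with a two-sided log-rank test; a stratum's
#' verdict lists the significant pairs (optionally Bonferroni-adjusted)
#' or declares no significant pairwise difference.
#'
#' @param fit A [dcph()] model, or a numeric score vector aligned with
#'   `cohort`.
#' @param cohort Evaluation [survival_cohort()] (raw covariate scale when
#'   `fit` is a model).
#' @param cutpoints Passed to [stratify()].
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Adjust p-values for the number of pairs per stratum.
#' @return A `stratification_result`: list with `strata` (factor per
#'   subject), `km` (per stratum x group KM curves), `tests` (data.frame
#'   of pairwise log-rank results), `verdicts` (named character) and
#'   `cutpoints`.
#' @export
audit <- function(fit, cohort, cutpoints = c(0.25, 0.75), alpha = 0.05,
                  bonferroni = FALSE) {
  scores <- if (inherits(fit, "dcph")) predict.dcph(fit, cohort)
            else as.numeric(fit)
  stopifnot(length(scores) == length(cohort$time))
  strata <- stratify(scores, cutpoints)
  K <- length(cohort$group_names)
  km <- list(); tests <- list(); verdicts <- character(0)
  for (s in levels(strata)) {
    in_s <- strata == s
    km[[s]] <- lapply(seq_len(K), function(k) {
      sel <- in_s & cohort$group == k
      if (!any(sel)) return(NULL)
      kaplan_meier(cohort$time[sel], cohort$event[sel])
    })
    names(km[[s]]) <- cohort$group_names
    present <- which(vapply(km[[s]], Negate(is.null), logical(1)))
    if (length(present) < 2L) {
      verdicts[s] <- "fewer than 2 groups represented"
      next
    }
    prs <- utils::combn(present, 2)
    n_pairs <- ncol(prs)
    sig <- character(0)
    for (cix in seq_len(n_pairs)) {
      k1 <- prs[1, cix]; k2 <- prs[2, cix]
      sel <- in_s & cohort$group %in% c(k1, k2)
      lt <- logrank_test(cohort$time[sel], cohort$event[sel],
                         cohort$group[sel])
      p_adj <- if (bonferroni) min(1, lt$p_value * n_pairs) else lt$p_value
      tests[[length(tests) + 1L]] <- data.frame(
        stratum = s, group1 = cohort$group_names[k1],
        group2 = cohort$group_names[k2],
        statistic = lt$statistic, p_value = lt$p_value,
        p_adjusted = p_adj)
      if (!is.na(p_adj) && p_adj < alpha)
        sig <- c(sig, paste(cohort$group_names[k1],
                            cohort$group_names[k2], sep = " vs "))
    }
    verdicts[s] <- if (length(sig))
      paste0("significant pairwise difference: ",
             paste(sig, collapse = "; "))
    else paste0("no significant pairwise difference at alpha = ", alpha)
  }
  structure(list(strata = strata, km = km,
                 tests = do.call(rbind, tests), verdicts = verdicts,
                 cutpoints = cutpoints, alpha = alpha,
                 bonferroni = bonferroni),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat("Risk-stratified audit (cutpoints ",
      paste(x$cutpoints, collapse = "/"),
      if (x$bonferroni) ", Bonferroni-adjusted" else "", ")\n", sep = "")
  cat("  strata sizes:",
      paste(sprintf("%s=%d", names(table(x$strata)), table(x$strata)),
            collapse = ", "), "\n")
  for (s in names(x$verdicts))
    cat(sprintf("  %-5s %s\n", s, x$verdicts[s]))
  invisible(x)
}

#' Plot per-group observed survival within each risk stratum
#'
#' @param x A [audit()] result.
#' @param ... Unused.
#' @export
plot.stratification_result <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$km)))
  on.exit(graphics::par(old))
  for (s in names(x$km)) {
    curves <- Filter(Negate(is.null), x$km[[s]])
    cols <- grDevices::hcl.colors(length(curves), "Dark 3")
    graphics::plot(NULL, xlim = c(0, max(unlist(lapply(curves, `[[`, "time")))),
                   ylim = c(0, 1), xlab = "time", ylab = "KM survival",
                   main = paste(s, "risk"))
    for (i in seq_along(curves))
      graphics::lines(stats::stepfun(curves[[i]]$time, c(1, curves[[i]]$surv)),
                      col = cols[i], do.points = FALSE)
    graphics::legend("bottomleft", names(curves), col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
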