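# Breslow baseline hazard recovery and absolute survival curves.

#' Breslow baseline hazard estimator
#'
#' After the log-hazard scores are fitted, the nonparametric baseline
#' hazard is recovered post hoc: at each unique event time `t_j` the
#' discrete increment is `h0(t_j) = d_j / sum_{l in R(t_j)} exp f(x_l)`,
#' the number of events at `t_j` over the accumulated risk of everyone
#' still at risk, `R(t_j) = {l : o_l >= t_j}` (subjects censored exactly
#' at `t_j` remain in the risk set; tied events share one increment).
#' With all scores zero this reduces to the Nelson-Aalen estimator.
#'
#' @param scores Numeric log-hazard scores aligned with the cohort.
#' @param cohort A [survival_cohort()] with at least one event.
#' @return An object of class `breslow_hazard` with `event_times`
#'   (strictly increasing), `increments` and `cumulative`.
#' @export
breslow_fit <- function(scores, cohort) {
  stopifnot(length(scores) == length(cohort$time))
  if (any(!is.finite(scores))) stop("non-finite score")
  time <- cohort$time; event <- cohort$event
  if (sum(event) == 0L) stop("no events: baseline hazard undefined")
  ord <- order(time)
  ts <- time[ord]; es <- event[ord]
  M <- max(scores)
  w <- exp(scores[ord] - M)
  suffix <- rev(cumsum(rev(w)))               # sum of exp(f - M) over {o >= t}
  first_pos <- which(!duplicated(ts))         # block start per unique time
  ut <- ts[first_pos]
  d <- as.numeric(rowsum(es, match(ts, ut)))  # events per unique time
  keep <- d > 0
  denom <- suffix[first_pos][keep] * exp(M)
  stopifnot(all(denom > 0))
  inc <- d[keep] / denom
  structure(list(event_times = ut[keep], increments = inc,
                 cumulative = cumsum(inc)),
            class = "breslow_hazard")
}

#' @export
print.breslow_hazard <- function(x, ...) {
  cat("<breslow_hazard> ", length(x$event_times),
      " event times, H0 range [0, ",
      sprintf("%.4g", max(x$cumulative)), "]\n", sep = "")
  invisible(x)
}

# cumulative baseline hazard H0(t) at arbitrary times (right-continuous
# step function, 0 before the first event time)
cumulative_hazard_at <- function(hazard, times) {
  idx <- findInterval(times, hazard$event_times)
  c(0, hazard$cumulative)[idx + 1L]
}

#' Predicted survival curves from scores and a baseline hazard
#'
#' `S_i(t) = exp(-H0(t) * exp f(x_i))` with `H0(t)` the right-continuous
#' cumulative Breslow hazard. Step function between event times;
#' `S_i(0) = 1`.
#'
#' @param scores Numeric log-hazard scores.
#' @param hazard A [breslow_fit()] result.
#' @param times Nonnegative evaluation grid (defaults to the hazard's
#'   event times).
#' @return An object of class `survival_curve`: `times` and an
#'   `n x length(times)` matrix `surv`.
#' @export
predict_survival <- function(scores, hazard, times = NULL) {
  stopifnot(inherits(hazard, "breslow_hazard"))
  if (is.null(times)) times <- hazard$event_times
  if (any(times < 0)) stop("evaluation grid must be nonnegative")
  H0 <- cumulative_hazard_at(hazard, times)
  surv <- exp(-outer(exp(scores), H0))
  structure(list(times = times, surv = surv), class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> ", nrow(x$surv), " subjects x ",
      length(x$times), " times\n", sep = "")
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, subjects = NULL, col = NULL, ...) {
  idx <- subjects %||% seq_len(min(nrow(x$surv), 20L))
  graphics::matplot(x$times, t(x$surv[idx, , drop = FALSE]), type = "s",
                    lty = 1, col = col %||% grDevices::hcl.colors(length(idx)),
                    xlab = "time", ylab = "S(t)", ylim = c(0, 1), ...)
  invisible(x)
}
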