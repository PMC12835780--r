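# Discrimination and calibration metrics, overall and per group.

# One pass over all comparable pairs (o_i < o_j, delta_i = 1), counting
# pairs / concordant / score-ties in K x K matrices indexed by
# (group of the earlier event i, group of the later subject j). Every
# C-index variant is derived from these counts.
concordance_counts <- function(scores, time, event, group, K) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; rs <- scores[ord]; es <- event[ord]; gs <- group[ord]
  # last index of each tie block: comparable j's start after it
  block_end <- seq_len(n)
  if (n > 1L) {
    same_next <- c(ts[-1L] == ts[-n], FALSE)
    for (i in rev(which(same_next))) block_end[i] <- block_end[i + 1L]
  }
  # gcum[i, h] = count of positions >= i in group h
  ind <- matrix(0L, n, K)
  ind[cbind(seq_len(n), gs)] <- 1L
  gcum <- apply(ind, 2, function(v) rev(cumsum(rev(v))))
  gcum <- rbind(gcum, 0L)

  npairs <- nconc <- ntie <- matrix(0, K, K)
  for (q in which(es == 1)) {
    j0 <- block_end[q] + 1L
    if (j0 > n) next
    sfx <- j0:n
    npairs[gs[q], ] <- npairs[gs[q], ] + gcum[j0, ]
    rq <- rs[q]
    conc <- sfx[rs[sfx] < rq]
    tie <- sfx[rs[sfx] == rq]
    if (length(conc))
      nconc[gs[q], ] <- nconc[gs[q], ] + tabulate(gs[conc], K)
    if (length(tie))
      ntie[gs[q], ] <- ntie[gs[q], ] + tabulate(gs[tie], K)
  }
  list(npairs = npairs, nconc = nconc, ntie = ntie)
}

cindex_from_counts <- function(cnt, cells) {
  np <- sum(cnt$npairs[cells])
  if (np == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no comparable pairs"
    return(out)
  }
  (sum(cnt$nconc[cells]) + 0.5 * sum(cnt$ntie[cells])) / np
}

# logical cell masks for the variants
variant_cells <- function(K, variant, k = NULL) {
  m <- matrix(FALSE, K, K)
  switch(variant,
    all = { m[, ] <- TRUE },
    within = { m[k, k] <- TRUE },
    cross = { m[k, ] <- TRUE; m[, k] <- TRUE; m[k, k] <- FALSE })
  m
}

#' Concordance index (overall, within-group, cross-group)
#'
#' Over the comparable pairs `(i, j)` with `o_i < o_j` and `delta_i = 1`,
#' the fraction for which the earlier event has the higher predicted risk
#' (score ties count 1/2). `variant = "all"` is Harrell's C over every
#' comparable pair; `"within"` keeps pairs entirely inside group `k`;
#' `"cross"` keeps pairs in which exactly one member belongs to group
#' `k`, measuring how well the model ranks that group's subjects against
#' the rest of the cohort.
#'
#' @param scores Predicted risk scores (higher = higher risk).
#' @param cohort A [survival_cohort()].
#' @param variant `"all"`, `"within"` or `"cross"`.
#' @param k Group code (required for `"within"`/`"cross"`).
#' @return A value in `[0, 1]`, or `NA` with a `"reason"` attribute when
#'   the pair set is empty (e.g. a group with no events).
#' @export
concordance <- function(scores, cohort,
                        variant = c("all", "within", "cross"), k = NULL) {
  variant <- match.arg(variant)
  if (variant != "all" && is.null(k))
    stop("variant '", variant, "' needs a group code k")
  K <- length(cohort$group_names)
  cnt <- concordance_counts(scores, cohort$time, cohort$event,
                            cohort$group, K)
  cindex_from_counts(cnt, variant_cells(K, variant, k))
}

#' Enumerate comparable pairs explicitly
#'
#' Materialises the ordered comparable pairs `(i, j)` (`o_i < o_j`,
#' `delta_i = 1`) of a small cohort, optionally restricted to one group's
#' within- or cross-group pair set. Intended for audits and worked
#' examples; the metric computations never materialise pairs.
#'
#' @inheritParams concordance
#' @return Two-column integer matrix of (i, j) index pairs.
#' @export
comparable_pairs <- function(cohort,
                             variant = c("all", "within", "cross"),
                             k = NULL) {
  variant <- match.arg(variant)
  n <- length(cohort$time)
  if (n > 2000L) stop("pair enumeration is limited to n <= 2000")
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- cohort$time[ii] < cohort$time[jj] & cohort$event[ii] == 1
  gi <- cohort$group[ii]; gj <- cohort$group[jj]
  keep <- keep & switch(variant,
    all = TRUE,
    within = gi == k & gj == k,
    cross = (gi == k) != (gj == k))
  cbind(i = ii[keep], j = jj[keep])
}

# Kaplan-Meier estimate of the censoring distribution G(t) on the full
# cohort (censoring treated as the event). Returns right-continuous
# G(t) and the left limit G(t-) as vectorised evaluators.
censoring_km <- function(cohort) {
  fit <- survival::survfit(
    survival::Surv(cohort$time, 1 - cohort$event) ~ 1)
  tt <- fit$time[fit$n.event > 0]
  ss <- fit$surv[fit$n.event > 0]
  g_at <- function(t) c(1, ss)[findInterval(t, tt) + 1L]
  g_left <- function(t) c(1, ss)[findInterval(t, tt, left.open = TRUE) + 1L]
  list(at = g_at, left = g_left)
}

# evaluate a survival_curve at arbitrary times (right-continuous step,
# S = 1 before the first stored time)
curve_at <- function(curve, times) {
  idx <- findInterval(times, curve$times)
  cbind(1, curve$surv)[, idx + 1L, drop = FALSE]
}

default_tau <- function(cohort) unname(stats::quantile(cohort$time, 0.99))

#' IPCW integrated Brier score
#'
#' The Brier score at time `t` is the mean squared distance between the
#' predicted survival probability and the observed status `1(o_i > t)`,
#' reweighted for censoring by inverse-probability-of-censoring weights
#' `w_i(t) = delta_i 1(o_i <= t)/G(o_i-) + 1(o_i > t)/G(t)` with `G` the
#' Kaplan-Meier estimate of the censoring distribution on the full
#' cohort. The score is integrated over `(0, tau]` by the trapezoid rule
#' on the curve's time grid (with 0 and `tau` appended) and divided by
#' `tau`. Terms whose weight is undefined (`G = 0`) are dropped and
#' counted in the `"dropped"` attribute.
#'
#' @param curve A [predict_survival()] result covering `(0, tau]`.
#' @param cohort The evaluation [survival_cohort()] (also defines `G`).
#' @param group Optional group code restricting the averaged subjects
#'   (weights still use the full cohort's `G`).
#' @param tau Integration horizon; default the 99th percentile of
#'   follow-up.
#' @return Nonnegative scalar with attribute `"dropped"`.
#' @export
integrated_brier <- function(curve, cohort, group = NULL, tau = NULL) {
  tau <- tau %||% default_tau(cohort)
  if (tau > max(cohort$time)) stop("tau exceeds the maximum follow-up")
  G <- censoring_km(cohort)
  sel <- if (is.null(group)) seq_along(cohort$time)
         else which(cohort$group == group)
  if (!length(sel)) stop("group absent from the evaluation cohort")
  grid <- sort(unique(c(0, curve$times[curve$times <= tau], tau)))
  S <- curve_at(curve, grid)[sel, , drop = FALSE]
  o <- cohort$time[sel]; d <- cohort$event[sel]
  Go <- G$left(o)
  bs <- numeric(length(grid))
  dropped <- 0L
  for (g in seq_along(grid)) {
    t <- grid[g]
    Gt <- G$at(t)
    w <- ifelse(o > t, 1 / Gt, ifelse(d == 1, 1 / Go, 0))
    bad <- !is.finite(w)
    dropped <- dropped + sum(bad)
    w[bad] <- 0
    err <- (as.numeric(o > t) - S[, g])^2
    ok <- !bad
    bs[g] <- if (any(ok)) sum(w[ok] * err[ok]) / sum(ok) else 0
  }
  val <- trapz(grid, bs) / tau
  attr(val, "dropped") <- dropped
  val
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Integrated calibration index
#'
#' At each grid time `t` the predicted survival probabilities
#' `p_i = S_i(t)` of the group's subjects are compared with a calibrated
#' ("observed") probability obtained by a local-linear smoother of the
#' IPCW-weighted status indicators `1(o_i > t)` on `p_i` (loess, degree
#' 1, span `span`, clipped to `[0, 1]`). The mean absolute gap
#' `|p_i - calibrated(p_i)|` is then averaged over time by the trapezoid
#' rule on a grid of event-time deciles up to `tau` (with 0 and `tau`
#' appended) and divided by `tau`. When predictions at a time are
#' (nearly) degenerate the calibrated value falls back to the
#' IPCW-weighted empirical survival.
#'
#' @inheritParams integrated_brier
#' @param span Loess span (default 0.75).
#' @return Nonnegative scalar, or `NA` with a `"reason"` attribute when
#'   the group has fewer than 20 subjects (the smoother needs support).
#' @export
integrated_calibration_index <- function(curve, cohort, group = NULL,
                                         tau = NULL, span = 0.75) {
  tau <- tau %||% default_tau(cohort)
  G <- censoring_km(cohort)
  sel <- if (is.null(group)) seq_along(cohort$time)
         else which(cohort$group == group)
  if (length(sel) < 20L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 20 subjects in group"
    return(out)
  }
  ev_times <- cohort$time[cohort$event == 1]
  ev_times <- ev_times[ev_times <= tau]
  grid <- sort(unique(c(0, stats::quantile(ev_times, seq(0.1, 0.9, 0.1),
                                           names = FALSE), tau)))
  S <- curve_at(curve, grid)[sel, , drop = FALSE]
  o <- cohort$time[sel]; d <- cohort$event[sel]
  Go <- G$left(o)
  ici_t <- numeric(length(grid))
  for (g in seq_along(grid)) {
    t <- grid[g]
    Gt <- G$at(t)
    w <- ifelse(o > t, 1 / Gt, ifelse(d == 1, 1 / Go, 0))
    w[!is.finite(w)] <- 0
    p <- S[, g]
    status <- as.numeric(o > t)
    ici_t[g] <- mean(abs(p - calibrated_survival(p, status, w, span)))
  }
  trapz(grid, ici_t) / tau
}

# smoothed observed survival as a function of predicted survival
calibrated_survival <- function(p, status, w, span = 0.75) {
  if (stats::sd(p) < 1e-8 || sum(w > 0) < 10L) {
    cal <- if (sum(w) > 0) sum(w * status) / sum(w) else mean(status)
    return(rep(min(max(cal, 0), 1), length(p)))
  }
  fit <- try(suppressWarnings(
    stats::loess(status ~ p, weights = w, span = span, degree = 1,
                 family = "gaussian")),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    cal <- sum(w * status) / sum(w)
    return(rep(min(max(cal, 0), 1), length(p)))
  }
  cal <- stats::predict(fit, newdata = data.frame(p = p))
  cal[!is.finite(cal)] <- sum(w * status) / sum(w)
  pmin(pmax(cal, 0), 1)
}

#' Percentile bootstrap confidence intervals
#'
#' Resamples subjects with replacement and recomputes a statistic (which
#' may return a named vector of metrics, so one resampling pass serves a
#' whole report). Replicates returning `NA` for a component (e.g. a group
#' absent from the resample) are skipped for that component and counted;
#' a warning is attached when more than 10% are skipped.
#'
#' @param stat_fn Function of an index vector returning a numeric
#'   (optionally named) vector.
#' @param n Number of subjects to resample from.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf Confidence level (default 0.95).
#' @return A list with `lower`, `upper` (named vectors), `skipped`
#'   (NA counts per component) and `B`.
#' @export
bootstrap_ci <- function(stat_fn, n, B = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(B >= 100L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[[b]] <- stat_fn(idx)
  }
  mat <- do.call(rbind, reps)
  a <- (1 - conf) / 2
  lower <- apply(mat, 2, stats::quantile, probs = a, na.rm = TRUE)
  upper <- apply(mat, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  skipped <- colSums(is.na(mat))
  if (any(skipped > 0.1 * B))
    warning("more than 10% of bootstrap replicates skipped for: ",
            paste(colnames(mat)[skipped > 0.1 * B], collapse = ", "))
  list(lower = lower, upper = upper, skipped = skipped, B = B)
}

# all report metrics for one index vector (identity index = point
# estimates). scores/curve are fixed; G is refit on the resample.
report_stats <- function(idx, scores, cohort, K, tau, grid_size) {
  ch <- subset_cohort(cohort, idx)
  sc <- scores[idx]
  tau <- min(tau, max(ch$time))  # bootstrap resample may drop the max
  cnt <- concordance_counts(sc, ch$time, ch$event, ch$group, K)
  ev_times <- sort(unique(ch$time[ch$event == 1]))
  ev_times <- ev_times[ev_times <= tau]
  if (length(ev_times) > grid_size)
    ev_times <- unique(stats::quantile(ev_times,
                                       seq(0, 1, length.out = grid_size),
                                       names = FALSE, type = 1))
  bh <- breslow_fit(sc, ch)
  curve <- predict_survival(sc, bh, ev_times)
  out <- c(c_all = as.numeric(cindex_from_counts(cnt, variant_cells(K, "all"))),
           ibs_all = as.numeric(integrated_brier(curve, ch, tau = tau)),
           ici_all = as.numeric(integrated_calibration_index(curve, ch, tau = tau)))
  for (k in seq_len(K)) {
    has_k <- any(ch$group == k)
    out[paste0("c_within_", k)] <-
      as.numeric(cindex_from_counts(cnt, variant_cells(K, "within", k)))
    out[paste0("c_cross_", k)] <-
      as.numeric(cindex_from_counts(cnt, variant_cells(K, "cross", k)))
    out[paste0("ibs_", k)] <- if (has_k)
      as.numeric(integrated_brier(curve, ch, group = k, tau = tau)) else NA_real_
    out[paste0("ici_", k)] <- if (has_k)
      as.numeric(integrated_calibration_index(curve, ch, group = k, tau = tau))
      else NA_real_
  }
  out
}

#' Fairness evaluation report for a fitted model
#'
#' Computes, on an evaluation cohort, the overall Harrell's C, per-group
#' within-group and cross-group C-indices, the IPCW integrated Brier
#' score and the integrated calibration index (overall and per group),
#' optionally with percentile bootstrap confidence intervals. Survival
#' curves for the calibration metrics come from a Breslow baseline
#' hazard refit on the evaluation scores.
#'
#' @param fit A [dcph()] model.
#' @param cohort Evaluation cohort on the raw covariate scale; defaults
#'   to the model's internal validation split.
#' @param B Bootstrap replicates (0 = point estimates only).
#' @param seed Bootstrap seed.
#' @param tau Integration horizon for IBS/ICI (default: 99th percentile
#'   of follow-up).
#' @param grid_size Maximum number of grid times for the calibration
#'   metrics (event times are quantile-thinned beyond it).
#' @return A `fairness_report`: a data.frame with one row per group plus
#'   an overall row, and columns for each metric (and CI bounds when
#'   `B > 0`).
#' @export
evaluate <- function(fit, cohort = NULL, B = 0L, seed = 1L, tau = NULL,
                     grid_size = 200L) {
  stopifnot(inherits(fit, "dcph"))
  if (is.null(cohort)) {
    cohort <- fit$valid_cohort
    scores <- mlp_forward(fit$net, cohort$covariates)
  } else {
    scores <- predict.dcph(fit, cohort)
  }
  K <- length(cohort$group_names)
  tau <- tau %||% default_tau(cohort)
  pt <- report_stats(seq_along(scores), scores, cohort, K, tau, grid_size)
  ci <- NULL
  if (B > 0)
    ci <- bootstrap_ci(function(idx)
      report_stats(idx, scores, cohort, K, tau, grid_size),
      n = length(scores), B = B, seed = seed)

  rows <- c("overall", cohort$group_names)
  nk <- c(length(scores), tabulate(cohort$group, K))
  evk <- c(sum(cohort$event),
           vapply(seq_len(K), function(k) sum(cohort$event[cohort$group == k]),
                  numeric(1)))
  rep_df <- data.frame(
    group = rows, n = nk, events = evk,
    c_within = c(unname(pt["c_all"]),
                 unname(pt[paste0("c_within_", seq_len(K))])),
    c_cross = c(NA_real_, unname(pt[paste0("c_cross_", seq_len(K))])),
    ibs = c(unname(pt["ibs_all"]), unname(pt[paste0("ibs_", seq_len(K))])),
    ici = c(unname(pt["ici_all"]), unname(pt[paste0("ici_", seq_len(K))])))
  if (!is.null(ci)) {
    grab <- function(v, nms) unname(v[nms])
    nms_within <- c("c_all", paste0("c_within_", seq_len(K)))
    nms_cross <- c(NA, paste0("c_cross_", seq_len(K)))
    nms_ibs <- c("ibs_all", paste0("ibs_", seq_len(K)))
    nms_ici <- c("ici_all", paste0("ici_", seq_len(K)))
    add_ci <- function(df, col, nms) {
      lo <- ifelse(is.na(nms), NA_real_, grab(ci$lower, nms))
      hi <- ifelse(is.na(nms), NA_real_, grab(ci$upper, nms))
      df[[paste0(col, "_lo")]] <- lo
      df[[paste0(col, "_hi")]] <- hi
      df
    }
    rep_df <- add_ci(rep_df, "c_within", nms_within)
    rep_df <- add_ci(rep_df, "c_cross", nms_cross)
    rep_df <- add_ci(rep_df, "ibs", nms_ibs)
    rep_df <- add_ci(rep_df, "ici", nms_ici)
  }
  structure(rep_df, class = c("fairness_report", "data.frame"),
            tau = tau, B = B, objective = fit$objective)
}

#' @export
print.fairness_report <- function(x, digits = 3, ...) {
  cat("Fairness report (objective: ",
      attr(x, "objective") %||% "?", ", tau = ",
      sprintf("%.3g", attr(x, "tau")), ", bootstrap B = ",
      attr(x, "B"), ")\n\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cross-group concordance fairness gap
#'
#' The spread (max minus min) of the cross-group C-index across groups;
#' the headline scalar by which the objectives are compared.
#'
#' @param report A [evaluate()] report.
#' @return Nonnegative scalar (NA if any group's cross-group C is
#'   undefined).
#' @export
fairness_gap <- function(report) {
  cc <- report$c_cross[report$group != "overall"]
  if (anyNA(cc)) return(NA_real_)
  max(cc) - min(cc)
}
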