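# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (double loops, explicit risk sets) so they share no
# code path with the implementations they check.

# negative mean partial log-likelihood by explicit risk-set enumeration
oracle_npll <- function(scores, time, event, subset = NULL) {
  if (is.null(subset)) subset <- rep(TRUE, length(time))
  terms <- c()
  for (i in seq_along(time)) {
    if (event[i] == 1 && subset[i]) {
      R <- which(time >= time[i])
      terms <- c(terms, scores[i] - log(sum(exp(scores[R]))))
    }
  }
  -mean(terms)
}

# C-index by exhaustive O(n^2) pair enumeration
oracle_cindex <- function(scores, time, event, group, variant = "all",
                          k = NULL) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!(event[i] == 1 && time[i] < time[j])) next
    keep <- switch(variant,
      all = TRUE,
      within = group[i] == k && group[j] == k,
      cross = xor(group[i] == k, group[j] == k))
    if (!keep) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# Breslow increments by explicit per-time risk-set sums
oracle_breslow <- function(scores, time, event) {
  ut <- sort(unique(time[event == 1]))
  sapply(ut, function(t)
    sum(event[time == t]) / sum(exp(scores[time >= t])))
}

# Kaplan-Meier of the censoring distribution, left-continuous variant
# evaluated by explicit products
oracle_censor_km <- function(time, event, at, left = FALSE) {
  ct <- sort(unique(time[event == 0]))
  vapply(at, function(t) {
    use <- if (left) ct[ct < t] else ct[ct <= t]
    prod(vapply(use, function(s)
      1 - sum(time == s & event == 0) / sum(time >= s), numeric(1)))
  }, numeric(1))
}

# small random cohort with groups, ties and censoring
random_cohort <- function(n, K = 3, tie_times = TRUE, p_event = 0.6) {
  tm <- if (tie_times) sample(1:max(4, n %/% 2), n, replace = TRUE)
        else stats::rexp(n) + 0.01
  ch <- survival_cohort(tm, stats::rbinom(n, 1, p_event),
                        sample.int(K, n, replace = TRUE), NULL)
  ch$group_names <- as.character(seq_len(K))
  ch
}

# tiny two-covariate cohort for model fits
quick_sim <- function(n, seed, beta = c(0.8, -0.5), censor_rate = 0.2) {
  simulate_cohort(simulation_config(
    n = n, group_probs = c(0.6, 0.4), baseline_shape = 1,
    baseline_scale = 10, beta = beta, group_log_hr = c(0, 0.3),
    censor_rate = censor_rate, seed = seed))
}
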