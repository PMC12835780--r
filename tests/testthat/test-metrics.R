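test_that("concordance handles perfect ranking and total ties", {
  n <- 12
  tm <- sort(rexp(n)) + 0.01
  ch <- survival_cohort(tm, rep(1, n), rep(1, n), NULL)
  expect_equal(concordance(-tm, ch), 1)       # inverse to event times
  expect_equal(concordance(rep(0.4, n), ch), 0.5)  # all ties

  # empty pair set is defined-missing, not NaN
  che <- survival_cohort(c(1, 2), c(0, 0), c(1, 1), NULL)
  expect_true(is.na(concordance(c(1, 2), che)))
  expect_match(attr(concordance(c(1, 2), che), "reason"), "no comparable")
})

test_that("all C-index variants equal exhaustive pair enumeration", {
  set.seed(31)
  for (r in 1:60) {
    K <- sample(2:4, 1)
    ch <- random_cohort(sample(5:50, 1), K = K)
    ch$group_names <- as.character(seq_len(K))
    sc <- round(rnorm(n_subjects(ch)), 1)  # force score ties
    expect_identical(as.numeric(concordance(sc, ch)),
                     oracle_cindex(sc, ch$time, ch$event, ch$group))
    for (k in seq_len(K)) {
      expect_identical(as.numeric(concordance(sc, ch, "within", k)),
                       oracle_cindex(sc, ch$time, ch$event, ch$group,
                                     "within", k))
      expect_identical(as.numeric(concordance(sc, ch, "cross", k)),
                       oracle_cindex(sc, ch$time, ch$event, ch$group,
                                     "cross", k))
    }
  }
})

test_that("pair sets partition: |all| = sum|within| + half sum|cross|", {
  set.seed(32)
  for (r in 1:40) {
    K <- sample(2:5, 1)
    ch <- random_cohort(sample(6:60, 1), K = K)
    n_all <- nrow(comparable_pairs(ch, "all"))
    n_w <- sum(vapply(seq_len(K), function(k)
      nrow(comparable_pairs(ch, "within", k)), numeric(1)))
    n_c <- sum(vapply(seq_len(K), function(k)
      nrow(comparable_pairs(ch, "cross", k)), numeric(1)))
    expect_identical(n_all, as.integer(n_w + n_c / 2))
  }
})

test_that("negating tie-free scores maps C to 1 - C", {
  set.seed(33)
  ch <- random_cohort(40, tie_times = FALSE)
  sc <- rnorm(40)
  expect_equal(as.numeric(concordance(-sc, ch)),
               1 - as.numeric(concordance(sc, ch)), tolerance = 1e-12)
})

test_that("IPCW Brier score matches closed forms and a hand oracle", {
  # perfect oracle predictions, no censoring -> IBS = 0
  n <- 15
  tm <- seq_len(n)
  ch <- survival_cohort(tm, rep(1, n), rep(1, n), NULL)
  grid <- sort(unique(tm))
  oracle_surv <- outer(tm, grid, function(o, t) as.numeric(o > t))
  curve <- structure(list(times = grid, surv = oracle_surv),
                     class = "survival_curve")
  expect_equal(as.numeric(integrated_brier(curve, ch, tau = max(tm))), 0)

  # constant S = 0.5 at every time including 0, no censoring:
  # Brier 0.25 at every t, IBS 0.25
  flat <- structure(list(times = c(0, grid),
                         surv = matrix(0.5, n, length(grid) + 1L)),
                    class = "survival_curve")
  expect_equal(as.numeric(integrated_brier(flat, ch, tau = max(tm))),
               0.25, tolerance = 1e-12)

  # 6 subjects, 2 censored: explicit IPCW double sum with hand-built G
  tm6 <- c(1, 2, 3, 4, 5, 6); ev6 <- c(1, 0, 1, 1, 0, 1)
  ch6 <- survival_cohort(tm6, ev6, rep(1, 6), NULL)
  grid6 <- c(1, 3, 4, 6)
  set.seed(34)
  S6 <- matrix(runif(24, 0.2, 0.95), 6, 4)
  S6 <- t(apply(S6, 1, function(x) sort(x, decreasing = TRUE)))
  curve6 <- structure(list(times = grid6, surv = S6),
                      class = "survival_curve")
  tau <- 6
  full_grid <- c(0, grid6)  # implementation appends 0 and tau
  Sfull <- cbind(1, S6)
  bs <- vapply(seq_along(full_grid), function(gi) {
    t <- full_grid[gi]
    tot <- 0
    for (i in 1:6) {
      w <- if (tm6[i] > t) 1 / oracle_censor_km(tm6, ev6, t)
           else if (ev6[i] == 1) 1 / oracle_censor_km(tm6, ev6, tm6[i],
                                                      left = TRUE)
           else 0
      tot <- tot + w * (as.numeric(tm6[i] > t) - Sfull[i, gi])^2
    }
    tot / 6
  }, numeric(1))
  hand <- sum(diff(full_grid) * (head(bs, -1) + tail(bs, -1)) / 2) / tau
  expect_equal(as.numeric(integrated_brier(curve6, ch6, tau = tau)),
               hand, tolerance = 1e-12)
})

test_that("censoring Kaplan-Meier evaluator matches explicit products", {
  set.seed(35)
  ch <- random_cohort(30, tie_times = TRUE, p_event = 0.5)
  G <- fairsurv:::censoring_km(ch)
  at <- c(0.5, 2, 3.5, 7, 11)
  expect_equal(G$at(at), oracle_censor_km(ch$time, ch$event, at),
               tolerance = 1e-12)
  expect_equal(G$left(at),
               oracle_censor_km(ch$time, ch$event, at, left = TRUE),
               tolerance = 1e-12)
})

test_that("degenerate predictions calibrate to the IPCW empirical rate", {
  # all predictions equal -> calibrated value is the weighted status mean
  p <- rep(0.6, 30)
  status <- rep(c(1, 0), 15)
  w <- rep(1, 30)
  expect_equal(fairsurv:::calibrated_survival(p, status, w),
               rep(0.5, 30))
})

test_that("true generative probabilities give near-zero ICI at scale", {
  cfg <- simulation_config(20000, 1, baseline_shape = 1,
                           baseline_scale = 20, beta = c(0.6, -0.4),
                           censor_rate = 0.02, admin_time = 60, seed = 36)
  sim <- simulate_cohort(cfg)
  ch <- sim$cohort
  tau <- unname(quantile(ch$time, 0.9))
  grid <- unique(quantile(ch$time[ch$event == 1], seq(0.01, 1, 0.01),
                          names = FALSE))
  truth <- exp(-outer(exp(sim$eta), grid / 20))
  curve <- structure(list(times = grid, surv = truth),
                     class = "survival_curve")
  ici <- integrated_calibration_index(curve, ch, tau = tau)
  expect_lt(as.numeric(ici), 0.02)

  # a constant -0.2 shift (no clipping in this range) raises ICI to ~0.2
  tau2 <- 5  # S(t) stays above ~0.45, shifted values stay interior
  shifted <- structure(list(times = grid, surv = pmax(truth - 0.2, 0)),
                       class = "survival_curve")
  ici2 <- as.numeric(integrated_calibration_index(shifted, ch, tau = tau2))
  expect_lt(abs(ici2 - 0.2), 0.05)

  # small groups are defined-missing
  chs <- survival_cohort(1:25, rep(1, 25), rep(c(1, 2), c(20, 5)), NULL)
  cs <- structure(list(times = 1:25, surv = matrix(0.5, 25, 25)),
                  class = "survival_curve")
  expect_true(is.na(integrated_calibration_index(cs, chs, group = 2)))
})

test_that("bootstrap intervals are deterministic and shrink with n", {
  # constant statistic -> degenerate interval
  ci <- bootstrap_ci(function(idx) c(m = 0.7), n = 50, B = 100, seed = 1)
  expect_equal(unname(ci$lower), 0.7)
  expect_equal(unname(ci$upper), 0.7)

  # same seed -> identical interval
  stat <- function(ch) function(idx) {
    chs <- subset_cohort(ch, idx)
    c(c = as.numeric(concordance(-chs$time + rnorm(length(idx), sd = 3),
                                 chs)))
  }
  set.seed(37)
  ch <- random_cohort(120, tie_times = FALSE)
  a <- bootstrap_ci(stat(ch), 120, B = 100, seed = 5)
  b <- bootstrap_ci(stat(ch), 120, B = 100, seed = 5)
  expect_identical(a, b)

  # width ~ 1/sqrt(n): strictly narrower as n grows 500 -> 2000 -> 8000
  width_at <- function(n) {
    sim <- quick_sim(n, seed = 38, censor_rate = 0.4)
    sc <- sim$eta + rnorm(n)
    f <- function(idx) {
      chs <- subset_cohort(sim$cohort, idx)
      c(c = as.numeric(concordance(sc[idx], chs)))
    }
    ci <- bootstrap_ci(f, n, B = 100, seed = 39)
    unname(ci$upper - ci$lower)
  }
  w <- vapply(c(500, 2000, 8000), width_at, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("evaluate produces a complete per-group report", {
  sim <- quick_sim(800, seed = 40)
  fit <- dcph(sim$cohort, "baseline",
              model = model_spec(hidden_layers = 1, hidden_width = 8),
              train = train_spec(max_epochs = 3, seed = 40))
  rep <- evaluate(fit)
  expect_s3_class(rep, "fairness_report")
  expect_identical(nrow(rep), 3L)  # overall + 2 groups
  expect_true(all(c("c_within", "c_cross", "ibs", "ici") %in% names(rep)))
  # overall row's C equals the all-pairs concordance
  va <- fit$valid_cohort
  sc <- fairsurv:::mlp_forward(fit$net, va$covariates)
  expect_equal(rep$c_within[1],
               as.numeric(concordance(sc, va)), tolerance = 1e-12)
  expect_true(all(rep$c_within >= 0 & rep$c_within <= 1, na.rm = TRUE))
  expect_true(all(rep$ibs >= 0, na.rm = TRUE))

  # bootstrap CIs bracket the point estimates
  repb <- evaluate(fit, B = 100, seed = 2)
  expect_true(all(repb$c_within_lo <= repb$c_within + 1e-12 &
                    repb$c_within <= repb$c_within_hi + 1e-12,
                  na.rm = TRUE))
})
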