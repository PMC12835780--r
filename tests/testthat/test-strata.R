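test_that("risk strata follow the quantile cutpoints", {
  sc8 <- c(0.1, 0.9, 0.4, 0.8, 0.2, 0.6, 0.3, 0.7)
  st <- stratify(sc8)
  expect_identical(as.integer(table(st)), c(2L, 4L, 2L))
  expect_identical(as.character(st[c(1, 5)]), c("low", "low"))
  expect_identical(as.character(st[c(2, 4)]), c("high", "high"))

  # sort-and-slice oracle on 10 stated scores
  sc10 <- c(2.5, -1.2, 0.3, 1.8, -0.7, 0.9, -2.1, 1.1, 0.0, -0.4)
  st10 <- stratify(sc10)
  ord <- order(sc10)
  expect_true(all(st10[ord[1:2]] == "low"))
  expect_true(all(st10[ord[3:8]] == "mid"))
  expect_true(all(st10[ord[9:10]] == "high"))

  # results-variant cutpoints: low = bottom 50%, mid = 25-50%
  stv <- stratify(sc8, c(0.5, 0.75))
  expect_identical(as.integer(table(stv)), c(4L, 2L, 2L))

  # degenerate ties
  expect_warning(stall <- stratify(rep(1, 6)), "identical")
  expect_true(all(stall == "mid"))
  expect_error(stratify(c(1, 2)), "fewer subjects")

  # sizes within 1 of n * (0.25, 0.5, 0.25) for distinct scores
  set.seed(61)
  for (n in c(17, 53, 101)) {
    tt <- table(stratify(rnorm(n)))
    expect_true(all(abs(as.integer(tt) - n * c(0.25, 0.5, 0.25)) <= 1))
  }
})

test_that("Kaplan-Meier matches the hand product-limit", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$surv, c(2/3, 0))

  # no censoring: complement of the ECDF
  tm <- c(2, 4, 6, 8)
  km2 <- kaplan_meier(tm, rep(1, 4))
  expect_equal(km2$surv, 1 - (1:4) / 4)

  # all censored: S = 1 everywhere (no event rows)
  expect_identical(nrow(kaplan_meier(c(1, 2, 3), c(0, 0, 0))), 0L)
})

test_that("-log KM tracks the Nelson-Aalen hazard at scale", {
  cfg <- simulation_config(10000, 1, baseline_shape = 1,
                           baseline_scale = 10, censor_rate = 0.05,
                           admin_time = 30, seed = 62)
  ch <- simulate_cohort(cfg)$cohort
  km <- kaplan_meier(ch$time, ch$event)
  na <- breslow_fit(rep(0, n_subjects(ch)), ch)  # Nelson-Aalen here
  mid <- km$surv > 0.2  # central region, away from sparse tails
  rel <- abs(-log(km$surv[mid]) - na$cumulative[mid]) /
    na$cumulative[mid]
  expect_lt(max(rel), 0.02)
})

test_that("log-rank test matches the O-E oracle and degenerate cases", {
  # identical samples interleaved: statistic exactly 0, p = 1
  tm <- c(1, 1, 2, 2, 3, 3)
  ev <- c(1, 1, 1, 1, 0, 0)
  gr <- c(1, 2, 1, 2, 1, 2)
  lt <- logrank_test(tm, ev, gr)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p_value, 1)

  # explicit 2x2-table-per-event-time O-E oracle on a small instance
  set.seed(63)
  tm <- sample(1:8, 24, replace = TRUE)
  ev <- rbinom(24, 1, 0.7)
  gr <- rep(1:2, each = 12)
  O <- E <- V <- 0
  for (t in sort(unique(tm[ev == 1]))) {
    n1 <- sum(tm >= t & gr == 1); n2 <- sum(tm >= t & gr == 2)
    d1 <- sum(tm == t & ev == 1 & gr == 1)
    d <- sum(tm == t & ev == 1); N <- n1 + n2
    O <- O + d1
    E <- E + d * n1 / N
    if (N > 1) V <- V + d * (n1 / N) * (n2 / N) * (N - d) / (N - 1)
  }
  lt2 <- logrank_test(tm, ev, gr)
  expect_equal(lt2$statistic, (O - E)^2 / V, tolerance = 1e-10)

  # no events at all: defined-missing
  lt3 <- logrank_test(c(1, 2), c(0, 0), c(1, 2))
  expect_true(is.na(lt3$statistic))

  # power under a 3-fold hazard ratio, n = 500 per arm
  rej <- 0
  set.seed(64)
  for (r in 1:20) {
    t1 <- rexp(500, 1); t2 <- rexp(500, 3)
    p <- logrank_test(c(t1, t2), rep(1, 1000), rep(1:2, each = 500))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej, 20 * 0.99)
})

test_that("audit flags a planted under-estimated group in the high stratum", {
  # group 2 carries a large extra hazard invisible to the scores
  set.seed(65)
  n <- 3000
  gr <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  x <- rnorm(n)
  eta_true <- 0.8 * x + 1.0 * (gr == 2)
  tm <- rexp(n, exp(eta_true)); cens <- rexp(n, 0.1)
  ch <- survival_cohort(pmin(tm, cens) + 1e-9, as.numeric(tm <= cens),
                        gr, NULL)
  blind_scores <- 0.8 * x  # risk model that ignores the group effect
  au <- audit(blind_scores, ch)
  expect_match(au$verdicts[["high"]], "significant pairwise difference")
  expect_identical(nrow(au$tests), 3L)  # 3 strata x C(2,2 groups) = 1 pair

  # structure: strata partition the cohort
  expect_length(au$strata, n)
  expect_false(anyNA(au$strata))
})

test_that("audit stays quiet when scores carry no group bias", {
  # 20 null simulations; significant fraction near the nominal level
  set.seed(66)
  n_sig <- 0; n_tests <- 0
  for (r in 1:20) {
    n <- 300
    gr <- sample(1:2, n, replace = TRUE)
    x <- rnorm(n)
    tm <- rexp(n, exp(0.8 * x)); cens <- rexp(n, 0.1)
    ch <- survival_cohort(pmin(tm, cens) + 1e-9, as.numeric(tm <= cens),
                          gr, NULL)
    au <- audit(0.8 * x, ch)
    n_sig <- n_sig + sum(au$tests$p_value < 0.05, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(au$tests$p_value))
  }
  expect_lt(n_sig / n_tests, 0.12)  # ~5% nominal, wide binomial slack
})
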