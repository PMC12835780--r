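test_that("zero-score loss on all-event distinct times is log(n!)/n", {
  for (n in 3:8) {
    ch <- survival_cohort(seq_len(n), rep(1, n), rep(1, n), NULL)
    expect_equal(neg_partial_log_likelihood(rep(0, n), ch),
                 log(factorial(n)) / n, tolerance = 1e-13)
  }
})

test_that("all objectives are invariant to a constant score shift", {
  set.seed(11)
  for (r in 1:20) {
    ch <- random_cohort(sample(8:40, 1))
    sc <- rnorm(n_subjects(ch))
    c0 <- 3.7
    expect_equal(neg_partial_log_likelihood(sc, ch),
                 neg_partial_log_likelihood(sc + c0, ch),
                 tolerance = 1e-10)
    expect_equal(fair_penalty(sc, ch$group),
                 fair_penalty(sc + c0, ch$group), tolerance = 1e-10)
    expect_equal(as.numeric(groupdro_objective(sc, ch)),
                 as.numeric(groupdro_objective(sc + c0, ch)),
                 tolerance = 1e-10)
  }
})

test_that("partial likelihood matches brute-force risk-set enumeration", {
  ch <- survival_cohort(c(1, 2, 3, 4), c(1, 1, 0, 1), c(1, 2, 1, 2), NULL)
  sc <- c(0.5, -0.2, 0.1, 0.0)
  expect_equal(neg_partial_log_likelihood(sc, ch),
               oracle_npll(sc, ch$time, ch$event), tolerance = 1e-12)

  # random cohorts with ties and subsets, risk sets over the full cohort
  set.seed(12)
  for (r in 1:30) {
    ch <- random_cohort(sample(6:30, 1))
    sc <- rnorm(n_subjects(ch))
    expect_equal(neg_partial_log_likelihood(sc, ch),
                 oracle_npll(sc, ch$time, ch$event), tolerance = 1e-10)
    sub <- ch$group == 1
    if (sum(ch$event[sub]) > 0)
      expect_equal(neg_partial_log_likelihood(sc, ch, subset = sub),
                   oracle_npll(sc, ch$time, ch$event, sub),
                   tolerance = 1e-10)
  }

  expect_error(neg_partial_log_likelihood(
    c(0, 0), survival_cohort(1:2, c(0, 0), c(1, 1), NULL)), "no events")
  expect_error(neg_partial_log_likelihood(
    c(NaN, 0), survival_cohort(1:2, c(1, 1), c(1, 1), NULL)), "non-finite")
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(13)
  n <- 40
  tm <- sample(1:15, n, replace = TRUE)
  ev <- rbinom(n, 1, 0.6)
  sc <- rnorm(n)
  g <- fairsurv:::npll_terms(sc, tm, ev, gradient = TRUE)$grad
  fd <- vapply(seq_len(n), function(i) {
    e <- rep(0, n); e[i] <- 1e-6
    (fairsurv:::npll_terms(sc + e, tm, ev) -
       fairsurv:::npll_terms(sc - e, tm, ev)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
})

test_that("fair penalty matches its defining arithmetic", {
  expect_identical(fair_penalty(c(2, 2, 5, 5), c(1, 1, 2, 2)),
                   fair_penalty(c(5, 5, 2, 2), c(1, 1, 2, 2)))
  expect_equal(fair_penalty(c(1, 3), c(1, 2)), 2)  # means +-1 around 0
  expect_equal(fair_penalty(c(1, 1, -1, -1), c(1, 1, 2, 2)), 2)
  expect_equal(fair_penalty(rep(0.3, 7), c(1, 1, 2, 2, 3, 3, 3)), 0)

  # three groups of sizes 2, 3, 5: brute-force means
  sc <- c(1.2, 0.8, -0.5, 0.0, 0.5, 2.0, 1.0, -1.0, 0.3, 0.7)
  gr <- rep(1:3, c(2, 3, 5))
  m <- mean(sc)
  exp_val <- (mean(sc[1:2]) - m)^2 + (mean(sc[3:5]) - m)^2 +
    (mean(sc[6:10]) - m)^2
  expect_equal(fair_penalty(sc, gr), exp_val, tolerance = 1e-12)
  expect_error(fair_penalty(numeric(0), integer(0)), "empty")

  # gradient against finite differences
  fd <- vapply(seq_along(sc), function(i) {
    e <- rep(0, length(sc)); e[i] <- 1e-6
    (fair_penalty(sc + e, gr) - fair_penalty(sc - e, gr)) / 2e-6
  }, numeric(1))
  expect_equal(unname(fairsurv:::fair_penalty_grad(sc, gr)), fd,
               tolerance = 1e-6)
})

test_that("groupdro objective is the max over group-restricted losses", {
  # single group: coincides with the baseline loss
  ch1 <- survival_cohort(c(2, 5, 7), c(1, 1, 0), rep(1, 3), NULL)
  sc1 <- c(0.4, -0.1, 0.2)
  expect_equal(as.numeric(groupdro_objective(sc1, ch1)),
               neg_partial_log_likelihood(sc1, ch1), tolerance = 1e-12)

  # 6 subjects in 2 groups: equals max of three brute-force terms
  ch <- survival_cohort(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 1, 1, 0),
                        c(1, 2, 1, 2, 1, 2), NULL)
  sc <- c(0.3, -0.4, 0.6, 0.1, -0.2, 0.5)
  t_full <- oracle_npll(sc, ch$time, ch$event)
  t_g1 <- oracle_npll(sc, ch$time, ch$event, ch$group == 1)
  t_g2 <- oracle_npll(sc, ch$time, ch$event, ch$group == 2)
  expect_equal(as.numeric(groupdro_objective(sc, ch)),
               max(t_full, t_g1, t_g2), tolerance = 1e-12)

  # dominance: max includes the full-cohort term k = 0
  set.seed(14)
  for (r in 1:30) {
    chr <- random_cohort(sample(6:40, 1))
    scr <- rnorm(n_subjects(chr))
    expect_gte(as.numeric(groupdro_objective(scr, chr)),
               neg_partial_log_likelihood(scr, chr) - 1e-12)
  }

  # a group with zero events is skipped and reported
  chz <- survival_cohort(c(1, 2, 3, 4), c(1, 1, 1, 0), c(1, 1, 1, 2), NULL)
  gd <- groupdro_objective(c(0.1, 0.2, 0.3, 0.4), chz)
  expect_identical(attr(gd, "skipped"), 2L)
})

test_that("the argmax group flags a systematically mis-ranked group", {
  # group 2's scores are mirrored within its own range (anti-ranked),
  # group 1's are perfectly ranked; both share the same score scale
  set.seed(15)
  n <- 60
  tm <- rexp(n) + 0.1
  gr <- rep(1:2, each = n / 2)
  sc <- -tm
  g2 <- gr == 2
  sc[g2] <- -(min(tm[g2]) + max(tm[g2]) - tm[g2])  # mirror: anti-ranked
  ch <- survival_cohort(tm, rep(1, n), gr, NULL)
  expect_identical(attr(groupdro_objective(sc, ch), "worst_group"), 2L)
})
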