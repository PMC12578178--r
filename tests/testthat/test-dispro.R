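test_that("contingency tables match hand counts on a small cohort", {
  drugs <- data.frame(primaryid = c(1, 2, 3, 4, 4, 5, 6, 7),
                      drug = c("X", "X", "X", "X", "Y", "Y", "Y", "Y"))
  cohort <- make_cohort(primaryid = 1:10,
                        is_dimd_case = c(TRUE, TRUE, FALSE, FALSE, TRUE,
                                         FALSE, FALSE, TRUE, TRUE, FALSE),
                        drugs = drugs)
  # hand count: X on reports 1-4 (cases 1,2); 5 cases total among 10 reports
  expect_equal(contingency_table(cohort, "X"),
               c(a = 2, b = 2, c = 3, d = 3))
  expect_equal(contingency_table(cohort, "Y"),
               c(a = 1, b = 3, c = 4, d = 2))
  # absent drug: a = b = 0, margins intact
  expect_equal(contingency_table(cohort, "ZZZ"),
               c(a = 0, b = 0, c = 5, d = 5))
  # drug on every report: c = d = 0
  all_dr <- make_cohort(primaryid = 1:4, is_dimd_case = c(TRUE, TRUE, FALSE, FALSE),
                        drugs = data.frame(primaryid = 1:4, drug = "Z"))
  expect_equal(contingency_table(all_dr, "Z"), c(a = 2, b = 2, c = 0, d = 0))
})

test_that("ROR, PRR and chi-squared equal hand arithmetic", {
  expect_equal(ror_stat(10, 10, 10, 10)$ror, 1)
  r <- ror_stat(20, 10, 10, 20)
  expect_equal(r$ror, 4)
  expect_equal(r$ror_lo, exp(log(4) - qnorm(0.975) * sqrt(0.3)))
  expect_equal(r$ror_hi, exp(log(4) + qnorm(0.975) * sqrt(0.3)))
  expect_equal(r$ror_lo, 1.367, tolerance = 1e-3)
  expect_equal(r$ror_hi, 11.699, tolerance = 1e-3)
  # Haldane on a zero cell, flagged
  h <- ror_stat(0, 10, 10, 10)
  expect_true(h$ror_corrected)
  expect_equal(h$ror, (0.5 * 10.5) / (10.5 * 10.5))
  expect_false(ror_stat(1, 10, 10, 10)$ror_corrected)

  expect_equal(prr_stat(10, 90, 10, 890)$prr, 9)
  expect_equal(prr_stat(5, 15, 20, 60)$prr, 1)    # equal row proportions
  expect_equal(prr_stat(20, 10, 10, 20)$chi2, 20 / 3)
  # Yates correction shrinks the statistic
  expect_lt(prr_stat(20, 10, 10, 20, yates = TRUE)$chi2, 20 / 3)
})

test_that("ROR/PRR/chi2 match independent arithmetic on a fixed table grid", {
  tabs <- expand.grid(a = c(1, 3, 12, 40), b = c(2, 9, 30),
                      c = c(4, 25), d = c(7, 60))   # 48 tables, no zeros
  with(tabs, {
    s_ror <- ror_stat(a, b, c, d)
    s_prr <- prr_stat(a, b, c, d)
    expect_equal(s_ror$ror, (a * d) / (b * c), tolerance = 1e-12)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    expect_equal(log(s_ror$ror_hi) - log(s_ror$ror_lo), 2 * qnorm(0.975) * se,
                 tolerance = 1e-12)
    expect_equal(s_prr$prr, (a / (a + b)) / (c / (c + d)), tolerance = 1e-12)
    N <- a + b + c + d
    expect_equal(s_prr$chi2,
                 N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
                 tolerance = 1e-12)
  })
})

test_that("ROR and PRR increase strictly in a with other cells fixed", {
  a <- 1:30
  r <- ror_stat(a, 50, 40, 900)$ror
  p <- prr_stat(a, 50, 40, 900)$prr
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
})

test_that("ROR approximates PRR for rare events", {
  set.seed(77)
  a <- sample(5:50, 30, replace = TRUE)
  b <- a * sample(50:200, 30, replace = TRUE)       # a << b
  cc <- sample(20:100, 30, replace = TRUE)
  d <- cc * sample(50:200, 30, replace = TRUE)      # c << d
  ror <- ror_stat(a, b, cc, d)$ror
  prr <- prr_stat(a, b, cc, d)$prr
  expect_true(all(abs(ror - prr) / prr < 0.05))
  # full-database-scale integer counts must not overflow the chi-squared
  big <- prr_stat(2000L, 500000L, 130000L, 9000000L)
  expect_true(is.finite(big$chi2) && big$chi2 > 0)
})

test_that("BCPNN information component shrinks toward zero and brackets", {
  # independence limit
  expect_lt(abs(bcpnn_ic(1000, 1000, 1000, 1000)$ic), 0.01)
  # raw log2 ratio is 1; shrunk estimate pulled into (0.8, 1.0)
  s <- bcpnn_ic(25, 75, 100, 800)
  expect_gt(s$ic, 0.8)
  expect_lt(s$ic, 1.0)
  # credible bound strictly below the point estimate
  set.seed(3)
  a <- sample(0:40, 25, replace = TRUE)
  b <- sample(1:200, 25, replace = TRUE)
  cc <- sample(1:200, 25, replace = TRUE)
  d <- sample(10:2000, 25, replace = TRUE)
  s2 <- bcpnn_ic(a, b, cc, d)
  expect_true(all(s2$ic025 < s2$ic))
  expect_true(all(s2$ic_var > 0))
})

test_that("BCPNN closed-form moments match numeric integration", {
  tabs <- rbind(c(25, 75, 100, 800), c(3, 10, 40, 200), c(0, 12, 30, 150),
                c(8, 2, 5, 90), c(1, 1, 1, 1), c(15, 200, 60, 3000))
  for (i in seq_len(nrow(tabs))) {
    t_ <- tabs[i, ]
    got <- bcpnn_ic(t_[1], t_[2], t_[3], t_[4])
    want <- bcpnn_oracle(t_[1], t_[2], t_[3], t_[4])
    expect_equal(got$ic, unname(want["ic"]), tolerance = 1e-6)
    expect_equal(got$ic_var, unname(want["var"]), tolerance = 1e-6)
  }
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  expect_equal(fisher_exact(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(10, 0, 0, 10), 2 / choose(20, 10))
  # random tables against stats::fisher.test (independent route)
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b + cc + d == 0) next
    want <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact(a, b, cc, d), want, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 10), 0.1)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_equal(bonferroni_adjust(0, 1000), 0)
  p <- runif(20)
  expect_true(all(bonferroni_adjust(p, 7) >= p))
})

test_that("EBGM hyperparameter fit recovers a single-gamma prior", {
  set.seed(202)
  n <- 5000
  E <- runif(n, 0.5, 20)
  lambda <- rgamma(n, shape = 2, rate = 2)
  a <- rpois(n, lambda * E)
  fit <- ebgm_fit(a, E, mix_p = 1)
  expect_lt(abs(fit$alpha1 - 2) / 2, 0.15)
  expect_lt(abs(fit$beta1 - 2) / 2, 0.15)
  expect_error(ebgm_fit(5, 2), "at least 2")
})

test_that("EBGM prior mean is near 1 for null (lambda = 1) data", {
  set.seed(303)
  n <- 4000
  E <- runif(n, 50, 400)
  a <- rpois(n, E)
  fit <- ebgm_fit(a, E)
  prior_mean <- fit$mix_p * fit$alpha1 / fit$beta1 +
    (1 - fit$mix_p) * fit$alpha2 / fit$beta2
  expect_lt(abs(prior_mean - 1), 0.05)
})

test_that("EBGM posterior summaries match the closed-form gamma posterior", {
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
                          mix_p = 1, negll = NA, counts = NULL,
                          convergence = 0L), class = "ebgm_prior")
  s <- ebgm_score(0, 1, prior)
  expect_equal(s$ebgm, exp(digamma(1)) / 2, tolerance = 1e-8)
  # large-count limit: posterior concentrates at a/E
  s2 <- ebgm_score(1000, 100, prior)
  expect_equal(s2$ebgm, 10, tolerance = 0.01 * 10)
  # eb05 is the posterior 5th percentile: closed form for a pure gamma
  expect_equal(s$eb05, qgamma(0.05, 1, rate = 2), tolerance = 1e-8)
  expect_true(s$eb05 <= s$ebgm)
  # E = 0 undefined, flagged missing
  s3 <- ebgm_score(c(2, 3), c(0, 1), prior)
  expect_true(is.na(s3$ebgm[1]) && is.na(s3$eb05[1]))
})

test_that("EBGM shrinks relative-reporting ratios toward the prior mean", {
  set.seed(404)
  E <- runif(300, 2, 50)
  a <- rpois(300, E)  # null world
  prior <- ebgm_fit(a, E)
  grid_a <- c(1, 3, 10, 30, 100)
  grid_E <- c(0.5, 2, 8, 40)
  for (ai in grid_a) for (Ei in grid_E) {
    s <- ebgm_score(ai, Ei, prior)
    rr <- ai / Ei
    if (rr > 1.05) expect_lt(s$ebgm, rr)
    if (rr < 0.95) expect_gt(s$ebgm, rr)
    expect_true(s$eb05 <= s$ebgm)
  }
})

test_that("the combined signal rule is a strict conjunction with a >= 3", {
  base <- data.table::data.table(
    drug = "X", a = 5, ror_lo = 2, prr = 3, chi2 = 10, ic025 = 0.5,
    ebgm = 4, eb05 = 2.5)
  expect_true(classify_signals(base)$is_signal)
  low_a <- data.table::copy(base)[, a := 2]
  expect_false(classify_signals(low_a)$is_signal)
  weak_ror <- data.table::copy(base)[, ror_lo := 0.99]
  expect_false(classify_signals(weak_ror)$is_signal)
  weak_ebgm <- data.table::copy(base)[, ebgm := 1.9]
  expect_false(classify_signals(weak_ebgm)$is_signal)
  # eb05 metric option
  expect_true(classify_signals(base, ebgm_metric = "eb05")$is_signal)
})

test_that("volcano coordinates are simple logs with zero-p protection", {
  s <- data.table::data.table(drug = c("X", "Y", "Z"), a = c(10, 100, 3),
                              ror = c(10, 1, 2), p_adjust = c(0.001, 1, 0))
  v <- volcano_table(s)
  expect_equal(v$log_ror, c(1, 0, log10(2)))
  expect_equal(v$neg_log10_p_adjust[1:2], c(3, 0))
  expect_true(v$p_zero_replaced[3])
  expect_equal(v$neg_log10_p_adjust[3], -log10(.Machine$double.xmin))
  expect_equal(v$log10_case_count, log10(c(10, 100, 3)))
  expect_identical(attr(volcano_table(s, ror_axis = "y"), "ror_axis"), "y")
})
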