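test_that("Cliff's delta handles the canonical cases", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$estimate, 0)
  expect_equal(cliffs_delta(c(4, 5, 6), c(1, 2, 3))$estimate, 1)
  expect_equal(cliffs_delta(c(2, 4), c(1, 3))$estimate, 0.5)
  expect_equal(cliffs_delta(c(2, 4), c(1, 3))$magnitude_label, "large")
  expect_equal(cliffs_delta(c(1, 1), c(1, 1))$estimate, 0)
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
})

test_that("Cliff's delta equals brute-force enumeration on random samples", {
  set.seed(101)
  for (i in 1:1000) {
    m <- sample(1:8, 1); n <- sample(1:8, 1)
    x <- sample(-3:3, m, replace = TRUE) + round(runif(m), 1)
    y <- sample(-3:3, n, replace = TRUE) + round(runif(n), 1)
    expect_equal(cliffs_delta(x, y)$estimate, brute_cliffs(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Cliff's delta is antisymmetric and rank-invariant", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(sample(2:20, 1)); y <- rnorm(sample(2:20, 1))
    d <- cliffs_delta(x, y)$estimate
    expect_equal(cliffs_delta(y, x)$estimate, -d)
    expect_equal(cliffs_delta(exp(x), exp(y))$estimate, d)
    expect_true(d >= -1 && d <= 1)
  }
})

test_that("Cramer's V covers perfect association, independence and a hand case", {
  expect_equal(cramers_v(rbind(c(10, 0), c(0, 10)))$estimate, 1)
  expect_equal(cramers_v(rbind(c(5, 5), c(5, 5)))$estimate, 0)
  # chi-square = 20/3 for this table, V = sqrt((20/3)/60) = 1/3
  expect_equal(cramers_v(rbind(c(20, 10), c(10, 20)))$estimate, 1 / 3,
               tolerance = 1e-12)
  expect_error(cramers_v(rbind(c(1, 0), c(2, 0))), "empty row or column")
  expect_error(cramers_v(matrix(1, 1, 2)), "r,c >= 2")
})

test_that("Clopper-Pearson intervals match beta quantiles and boundaries", {
  ci <- exact_binomial_ci(13, 43)
  expect_equal(ci$lower, qbeta(0.025, 13, 31))
  expect_equal(ci$upper, qbeta(0.975, 14, 30))
  expect_equal(exact_binomial_ci(0, 10)$lower, 0)
  expect_equal(exact_binomial_ci(10, 10)$upper, 1)
  expect_error(exact_binomial_ci(5, 4), "successes")
  expect_error(exact_binomial_ci(1, 0), "successes")
  # agreement with the stats-package reference implementation
  bt <- binom.test(9, 43)$conf.int
  ci9 <- exact_binomial_ci(9, 43)
  expect_equal(c(ci9$lower, ci9$upper), as.numeric(bt), tolerance = 1e-9)
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(202)
  for (p in c(0.05, 0.2, 0.5)) {
    for (n in c(10, 43, 200)) {
      k <- rbinom(3000, n, p)
      lo <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
      hi <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
      cover <- mean(lo <= p & p <= hi)
      # Monte-Carlo error ~ 0.004; exact intervals are conservative
      expect_gte(cover, 0.95 - 3 * sqrt(0.05 * 0.95 / 3000))
    }
  }
})

test_that("BH step-up matches its definition and the trivial cases", {
  expect_true(all(bh_fdr(rep(0.001, 5), 0.05)))
  expect_false(any(bh_fdr(c(0.6, 0.7), 0.05)))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.6), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(303)
  for (i in 1:300) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(bh_fdr(p, q), brute_bh(p, q))
  }
})

test_that("two-proportion power: null, design point, and saturation", {
  expect_lt(abs(two_proportion_power(0.3, 0.3, 100, 100) - 0.05), 0.005)
  expect_gt(two_proportion_power(0.01, 0.9, 1000, 1000), 0.999)
  pw <- two_proportion_power(0.025, 0.101, 1110, 119)
  expect_gt(pw, 0.80)
  # Monte-Carlo cross-check of the pooled z-test rejection rate
  set.seed(404)
  reps <- 1e5
  x1 <- rbinom(reps, 1110, 0.025); x2 <- rbinom(reps, 119, 0.101)
  p1 <- x1 / 1110; p2 <- x2 / 119
  pb <- (x1 + x2) / (1110 + 119)
  z <- (p1 - p2) / sqrt(pb * (1 - pb) * (1 / 1110 + 1 / 119))
  mc <- mean(abs(z) > qnorm(0.975))
  expect_lt(abs(pw - mc), 0.02)
  expect_error(two_proportion_power(0, 0.5, 10, 10), "strictly")
})

test_that("change ANCOVA reproduces a closed-form least-squares fit", {
  # 6 points, 2 groups; solve the normal equations independently
  d <- data.frame(change = c(1.3, 2.1, 3.4, -0.8, 0.3, 1.1),
                  group = rep(c("A", "B"), each = 3),
                  baseline = c(10, 12, 14, 11, 13, 15),
                  interval = c(2, 2.7, 3, 2.2, 2.5, 3.1))
  an <- change_ancova(d$change, d$group, d$baseline, d$interval)
  X <- cbind(1, d$group == "B", d$baseline, d$interval)
  beta <- solve(t(X) %*% X, t(X) %*% d$change)
  adjA <- beta[1] + beta[3] * mean(d$baseline) + beta[4] * mean(d$interval)
  expect_equal(unname(an$adjusted_means["A"]), drop(adjA),
               tolerance = 1e-10)
  expect_equal(unname(an$adjusted_means["B"] - an$adjusted_means["A"]),
               drop(beta[2]), tolerance = 1e-10)
})

test_that("change ANCOVA is well calibrated under the null", {
  set.seed(505)
  n <- 300
  g <- sample(c("CU_S", "CU_D", "MCI"), n, replace = TRUE)
  base <- rnorm(n, 100, 10)
  iv <- runif(n, 2, 3)
  ch <- -0.3 * (base - 100) + rnorm(n, 0, 5)   # regression to the mean only
  an <- change_ancova(ch, g, base, iv)
  expect_true(all(abs(an$adjusted_means - mean(an$adjusted_means)) < 2.5))
  expect_gt(an$kruskal_p, 0.001)
})

test_that("change ANCOVA recovers an injected group effect", {
  set.seed(506)
  n <- 400
  g <- factor(sample(c("CU_S", "CU_D"), n, replace = TRUE, c(0.8, 0.2)))
  base <- rnorm(n, 100, 10)
  iv <- runif(n, 2, 3)
  ch <- ifelse(g == "CU_D", -10, 0) - 0.2 * (base - 100) + rnorm(n, 0, 6)
  an <- change_ancova(ch, g, base, iv)
  est <- an$contrasts$estimate[1]          # CU_D - CU_S
  se <- an$contrasts$se[1]
  sgn <- if (an$contrasts$group1[1] == "CU_D") 1 else -1
  expect_lt(abs(sgn * est - (-10)), 3 * se)
})

test_that("logistic progression reproduces the closed-form 2x2 odds ratio", {
  # printed progression counts: 16/119 CU-D, 32/1110 CU-S
  outcome <- c(rep(1, 16), rep(0, 103), rep(1, 32), rep(0, 1078))
  status0 <- c(rep(1, 119), rep(0, 1110))
  fit <- logistic_progression(outcome, status0)
  or_hand <- (16 * 1078) / (103 * 32)
  expect_equal(fit$or[fit$term == "status0"], or_hand, tolerance = 1e-6)
  expect_lt(fit$p[fit$term == "status0"], 1e-4)
})

test_that("logistic progression flags separation and covers the null", {
  expect_error(
    logistic_progression(c(rep(1, 20), rep(0, 20)),
                         c(rep(1, 20), rep(0, 20))),
    "converge|separation")
  set.seed(607)
  out <- rbinom(2000, 1, 0.05)
  st <- rbinom(2000, 1, 0.1)
  fit <- logistic_progression(out, st)
  r <- fit[fit$term == "status0", ]
  expect_true(r$ci_lower < 1 && r$ci_upper > 1)
})

test_that("logistic progression recovers an injected adjusted effect", {
  set.seed(608)
  n <- 4000
  st <- rbinom(n, 1, 0.15)
  age <- rnorm(n, 60, 6)
  lp <- -3.5 + 1.5 * st + 0.03 * (age - 60)
  out <- rbinom(n, 1, plogis(lp))
  fit <- logistic_progression(out, st,
                              covariates = data.frame(age = age))
  r <- fit[fit$term == "status0", ]
  expect_lt(abs(r$estimate - 1.5), 3 * r$se)
})

test_that("group comparisons gate pairwise follow-ups on the omnibus test", {
  set.seed(709)
  null_x <- rnorm(90)
  g <- rep(c("a", "b", "c"), 30)
  res <- group_compare(null_x, g, "anova")
  if (res$omnibus_p >= 0.05) expect_null(res$pairwise)
  # strong separation: follow-ups appear and all pairs with the shifted
  # group are significant
  x <- c(rnorm(50), rnorm(50), rnorm(50, 2))
  g3 <- rep(c("a", "b", "c"), each = 50)
  res3 <- group_compare(x, g3, "anova", fdr_q = 0.05)
  expect_lt(res3$omnibus_p, 0.001)
  expect_equal(nrow(res3$pairwise), 3)
  expect_true(all(res3$pairwise$reject_fdr[res3$pairwise$group2 == "c"]))
  res_kw <- group_compare(x, g3, "kruskal_wallis")
  expect_lt(res_kw$omnibus_p, 0.001)
})

test_that("the anova omnibus rejects at about its level under the null", {
  set.seed(710)
  rej <- mean(replicate(400, {
    x <- rnorm(60); g <- rep(c("a", "b", "c"), each = 20)
    group_compare(x, g, "anova")$omnibus_p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("Fisher family matches the hypergeometric enumeration", {
  tab <- rbind(c(1, 9), c(9, 1))
  res <- group_compare(tab, family = "fisher_exact")
  expect_equal(res$omnibus_p, fisher.test(tab)$p.value)
  # direct two-sided hypergeometric sum for this margin
  probs <- dhyper(0:10, 10, 10, 10)
  expect_equal(res$omnibus_p, sum(probs[probs <= dhyper(1, 10, 10, 10)]),
               tolerance = 1e-9)
  expect_error(group_compare(rnorm(10), rep(1:2, 5), "fisher_exact"),
               "contingency table|numeric")
  expect_error(group_compare(tab, group = 1:2, family = "fisher_exact"),
               "contingency")
})
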