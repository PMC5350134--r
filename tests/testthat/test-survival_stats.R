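test_that("product-limit estimate matches the hand computation on the all-event fixture", {
  km <- km_estimate(1:5, rep(TRUE, 5))
  expect_equal(km$event_times, 1:5)
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$at_risk, 5:1)
  expect_equal(km$median, 3)
})

test_that("degenerate KM inputs follow the conventions", {
  all_cens <- km_estimate(c(2, 5, 9), c(FALSE, FALSE, FALSE))
  expect_length(all_cens$event_times, 0L)
  expect_true(is.na(all_cens$median))          # "not reached"
  one <- km_estimate(7, TRUE)
  expect_equal(one$survival, 0)
  expect_equal(one$median, 7)
  expect_error(km_estimate(numeric(), logical()), "non-empty")
})

test_that("KM with zero censoring equals the empirical survival function", {
  set.seed(21)
  for (i in 1:10) {
    t <- sample(1:40, 25, replace = TRUE)
    km <- km_estimate(t, rep(TRUE, 25))
    emp <- vapply(km$event_times, function(u) mean(t > u), numeric(1))
    expect_equal(km$survival, emp, tolerance = 1e-12)
  }
})

test_that("KM agrees with the survival package on censored fixtures", {
  set.seed(31)
  for (i in 1:10) {
    fx <- random_survival_fixture(30)
    km <- km_estimate(fx$time, fx$event)
    sf <- survival::survfit(survival::Surv(fx$time, fx$event) ~ 1)
    sm <- summary(sf, times = km$event_times)
    expect_equal(km$survival, sm$surv, tolerance = 1e-12)
    med <- unname(summary(sf)$table["median"])
    # survfit medians use S(t) <= 0.5 at event times, same convention
    if (is.na(med)) expect_true(is.na(km$median)) else expect_equal(km$median, med)
  }
})

test_that("log-rank statistic is zero for identical groups and matches the hand fixture", {
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- rep(TRUE, 8)
  g <- rep(c(0, 1), each = 4)
  r <- logrank_test(t, e, g)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  # group A events at {1, 2}; group B events at {3, 4}
  t2 <- c(1, 2, 3, 4); e2 <- rep(TRUE, 4); g2 <- c(0, 0, 1, 1)
  r2 <- logrank_test(t2, e2, g2)
  expect_equal(r2$statistic, naive_logrank_stat(t2, e2, g2 == 1),
               tolerance = 1e-12)
  expect_equal(r2$observed, c(2, 2))
  # hand sums: E1 = 2/4 + 2/3 + 1 + 1 = 19/6; V = 1/4 + 2/9
  expect_equal(r2$expected[2], 19 / 6, tolerance = 1e-12)
  expect_equal(r2$statistic, (2 - 19 / 6)^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-12)
})

test_that("log-rank matches both the naive oracle and survdiff on random fixtures", {
  set.seed(101)
  n_done <- 0
  while (n_done < 25) {
    fx <- random_survival_fixture(sample(8:30, 1))
    if (length(unique(fx$group)) < 2 || sum(fx$event) == 0) next
    n_done <- n_done + 1
    r <- logrank_test(fx$time, fx$event, fx$group)
    expect_equal(r$statistic, naive_logrank_stat(fx$time, fx$event, fx$group),
                 tolerance = 1e-9)
    sd <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ fx$group)
    expect_equal(r$statistic, unname(sd$chisq), tolerance = 1e-9)
  }
})

test_that("log-rank is invariant to label swaps and monotone time transforms", {
  set.seed(13)
  for (i in 1:10) {
    fx <- random_survival_fixture(25)
    if (length(unique(fx$group)) < 2) next
    a <- logrank_test(fx$time, fx$event, fx$group)$statistic
    b <- logrank_test(fx$time, fx$event, !fx$group)$statistic
    expect_equal(a, b, tolerance = 1e-12)
    d <- logrank_test(exp(fx$time / 10), fx$event, fx$group)$statistic
    expect_equal(a, d, tolerance = 1e-12)
  }
})

test_that("log-rank edge cases: one group, no events", {
  expect_error(logrank_test(1:4, rep(TRUE, 4), rep(1, 4)), "2 groups")
  expect_warning(r <- logrank_test(1:4, rep(FALSE, 4), c(0, 0, 1, 1)),
                 "no events")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("Cox coefficient matches golden-section partial-likelihood maximization", {
  set.seed(55)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    t <- round(rexp(n), 6)            # continuous, no ties
    e <- runif(n) < 0.8
    x <- rbinom(n, 1, 0.5)
    if (sum(e) == 0 || length(unique(x)) < 2) next
    fit <- try(suppressWarnings(cox_fit(t, e, x)), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) next
    expect_equal(unname(fit$coefficients[1]), grid_cox_beta(t, e, x),
                 tolerance = 1e-4)
    # log partial likelihood at the optimum comes from the same surface
    expect_equal(fit$loglik,
                 cox_partial_loglik(unname(fit$coefficients[1]), t, e, x),
                 tolerance = 1e-6)
    expect_equal(fit$loglik_null, cox_partial_loglik(0, t, e, x),
                 tolerance = 1e-6)
  }
})

test_that("Cox Wald intervals achieve roughly nominal null coverage", {
  set.seed(77)
  cover <- logical(200)
  for (i in 1:200) {
    n <- 100
    t <- rexp(n)
    e <- runif(n) < 0.8
    x <- rbinom(n, 1, 0.5)            # independent of survival
    fit <- cox_fit(t, e, x)
    cover[i] <- fit$ci95_low[1] < 1 && 1 < fit$ci95_high[1]
  }
  expect_gte(mean(cover), 0.90)
})

test_that("Cox estimates recover a known log-hazard ratio at large n", {
  set.seed(88)
  beta_hat <- vapply(1:10, function(i) {
    n <- 2000
    x <- rbinom(n, 1, 0.3)
    t <- rexp(n, rate = 0.01 * 2.2^x)
    cens <- runif(n, 0, 150)
    unname(cox_fit(pmin(t, cens), t <= cens, x)$coefficients[1])
  }, numeric(1))
  expect_lt(abs(mean(beta_hat) - log(2.2)), 0.15)
})

test_that("Cox input validation names the offending covariate", {
  expect_error(cox_fit(1:5, rep(TRUE, 5), data.frame(good = c(1, 0, 1, 0, 1),
                                                     flat = rep(2, 5))),
               "flat")
  expect_error(cox_fit(1:5, rep(FALSE, 5), rbinom(5, 1, 0.5)), "no events")
})

test_that("nested ANOVA applies the likelihood-ratio formula and preconditions", {
  mk <- function(ll, df, covs) structure(
    list(covariates = covs, loglik = ll, loglik_null = -12, df = df,
         n = 50L, n_events = 20L), class = "cox_fit")
  r <- nested_anova(mk(-10, 1, "a"), mk(-7, 3, c("a", "b", "c")))
  expect_equal(r$chi_square, 6)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, pchisq(6, 2, lower.tail = FALSE))
  expect_error(nested_anova(mk(-10, 1, "a"), mk(-10, 1, "a")), "at least one")
  expect_error(nested_anova(mk(-10, 1, "z"), mk(-9, 2, c("a", "b"))),
               "not nested")
})

test_that("nested ANOVA agrees with the survival package's anova on real fits", {
  set.seed(123)
  n <- 150
  x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
  t <- rexp(n, 0.1 * exp(0.5 * x1))
  e <- runif(n) < 0.8
  red <- cox_fit(t, e, data.frame(x1 = x1))
  full <- cox_fit(t, e, data.frame(x1 = x1, x2 = x2))
  mine <- nested_anova(red, full)
  a <- survival::coxph(survival::Surv(t, e) ~ x1)
  b <- survival::coxph(survival::Surv(t, e) ~ x1 + x2)
  ref <- stats::anova(a, b)
  expect_equal(mine$chi_square, ref$Chisq[2], tolerance = 1e-8)
  expect_equal(mine$p_value, ref[2, "Pr(>|Chi|)"], tolerance = 1e-8)
})

test_that("null-model likelihood-ratio chi-square tracks the log-rank statistic", {
  set.seed(321)
  n <- 2000
  x <- rbinom(n, 1, 0.3)
  t <- rexp(n, 0.02 * 1.8^x)
  cens <- runif(n, 0, 100)
  time <- pmin(t, cens); ev <- t <= cens
  fit <- cox_fit(time, ev, x)
  lrt <- nested_anova(NULL, fit)
  lr <- logrank_test(time, ev, x)
  expect_lt(abs(lrt$chi_square - lr$statistic) / lr$statistic, 0.15)
})

test_that("the likelihood-ratio statistic is chi-square(1) under a pure-noise addition", {
  set.seed(99)
  chis <- vapply(1:500, function(i) {
    n <- 60
    x1 <- rnorm(n); x2 <- rnorm(n)   # x2 is pure noise
    t <- rexp(n, 0.1 * exp(0.4 * x1))
    e <- runif(n) < 0.85
    red <- cox_fit(t, e, data.frame(x1 = x1))
    full <- cox_fit(t, e, data.frame(x1 = x1, x2 = x2))
    nested_anova(red, full)$chi_square
  }, numeric(1))
  ks <- stats::ks.test(chis, "pchisq", df = 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("Welch t from summary statistics behaves at the fixtures and limits", {
  eq <- welch_t_from_summary(5, 1, 30, 5, 2, 40)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)
  big <- welch_t_from_summary(10, 2, 1e6, 12, 2, 1e6)
  expect_lt(big$p_value, 1e-12)
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 10), "n >= 2")
  expect_error(welch_t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("clinical table reading standardizes and validates columns", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tDFS_MONTHS\tSTATUS\tage",
               "p1\t12.5\t1\t61", "p2\t40\t0\t58"), tf)
  clin <- read_clinical(tf, col_map = c(patient_id = "id",
                                        dfs_months = "DFS_MONTHS",
                                        event = "STATUS"))
  expect_equal(clin$dfs_months, c(12.5, 40))
  expect_equal(clin$event, c(1L, 0L))
  expect_error(read_clinical(tf), "dfs_months")
  writeLines(c("dfs_months\tevent", "-3\t1"), tf)
  expect_error(read_clinical(tf), "non-negative")
})
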