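test_that("median dichotomization follows the >= median rule", {
  expect_equal(median_dichotomize(c(1, 2, 3, 4)),
               c("low", "low", "high", "high"))
  # odd n: the subject at the median is high
  expect_equal(median_dichotomize(c(1, 2, 3)), c("low", "high", "high"))
  expect_error(median_dichotomize(rep(2, 5)), "degenerate")
  # median-tied subjects all land in "high", so group sizes differ by at
  # most twice the tie count (1 when untied); checked over small vectors
  set.seed(14)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    v <- sample(1:4, n, replace = TRUE)
    if (length(unique(v)) == 1) next
    g <- median_dichotomize(v)
    n_tied <- sum(v == median(v))
    expect_lte(abs(sum(g == "high") - sum(g == "low")),
               max(2 * n_tied, 1))
  }
})

test_that("Kaplan-Meier matches hand product-limit values", {
  # three subjects, all events at t = 1, 2, 3
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  # interleaved censoring: times 1, 2+, 3, 4+, 5, 6 (+ = censored)
  tab6 <- data.frame(time = 1:6, event = c(1, 0, 1, 0, 1, 1))
  km6 <- km_estimate(tab6)
  expect_equal(km6$time, c(1, 3, 5, 6))
  expect_equal(km6$survival[km6$time == 3], (5 / 6) * (3 / 4))
  expect_equal(km6$survival, c(5 / 6, (5 / 6) * (3 / 4),
                               (5 / 6) * (3 / 4) * (1 / 2), 0))

  # all censored: survival identically 1 (no event rows)
  km0 <- km_estimate(data.frame(time = c(2, 4), event = c(0, 0)))
  expect_equal(nrow(km0), 0)

  expect_error(km_estimate(data.frame(time = c(1, -1), event = c(1, 1))),
               ">= 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(23)
  times <- round(rexp(40, 0.1), 2)
  km <- km_estimate(data.frame(time = times, event = 1))
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(times > km$time[i]))
})

test_that("KM curve and Greenwood SE agree with the survival package", {
  set.seed(31)
  tab <- data.frame(time = round(rexp(60, 0.08), 1),
                    event = rbinom(60, 1, 0.7))
  km <- km_estimate(tab)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = tab)
  i <- sf$n.event > 0
  expect_equal(km$survival, sf$surv[i], tolerance = 1e-12)
  ok <- km$survival > 0
  expect_equal(km$greenwood_se[ok], (sf$std.err * sf$surv)[i][ok],
               tolerance = 1e-12)
})

test_that("log-rank: identical groups, hand-built tables, survdiff agreement", {
  tab <- data.frame(time = c(1, 3, 5, 7), event = c(1, 1, 0, 1))
  same <- logrank_test(tab, tab)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # group A all events at t=1, group B all events at t=10 (n = 5 each):
  # at t=1 observed A events = 5, expected = 5 * 5/10 = 2.5, variance
  # = 5 * (1/2)(1/2)(5/9); at t=10 A has left the risk set entirely
  a <- data.frame(time = rep(1, 5), event = 1)
  b <- data.frame(time = rep(10, 5), event = 1)
  lr <- logrank_test(a, b)
  V <- 5 * 0.25 * 5 / 9
  expect_equal(lr$chi2, (5 - 2.5)^2 / V)
  expect_equal(lr$observed, 5)
  expect_equal(lr$expected, 2.5)

  # symmetry: swapping groups leaves chi2 unchanged
  set.seed(40)
  g1 <- data.frame(time = rexp(30, 0.1), event = rbinom(30, 1, 0.8))
  g2 <- data.frame(time = rexp(25, 0.2), event = rbinom(25, 1, 0.8))
  expect_equal(logrank_test(g1, g2)$chi2, logrank_test(g2, g1)$chi2)

  # survdiff cross-check
  pooled <- rbind(cbind(g1, grp = 1), cbind(g2, grp = 2))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp,
                               data = pooled)
  expect_equal(logrank_test(g1, g2)$chi2, sd_fit$chisq, tolerance = 1e-10)

  expect_error(logrank_test(data.frame(time = 1, event = 0),
                            data.frame(time = 2, event = 0)), "no events")
})

test_that("Cox fit agrees with coxph (Breslow) on beta, SE and loglik", {
  set.seed(51)
  n <- 150
  tab <- data.frame(
    time = round(rexp(n, 0.1), 1),  # rounding forces ties
    event = rbinom(n, 1, 0.75),
    x = rnorm(n), z = rbinom(n, 1, 0.5))
  fit <- cox_fit(tab, c("x", "z"))
  ref <- survival::coxph(survival::Surv(time, event) ~ x + z, data = tab,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-8)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-8)
  # HR/CI columns are exp-transforms of beta +/- 1.96 se
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$beta))
  expect_true(all(fit$coefficients$ci_low < fit$coefficients$hr &
                    fit$coefficients$hr < fit$coefficients$ci_high))
})

test_that("score test at beta = 0 equals the log-rank statistic (tie-free)", {
  set.seed(62)
  n <- 80
  grp <- rbinom(n, 1, 0.5)
  tab <- data.frame(time = rexp(n, 0.1 * exp(0.5 * grp)),  # continuous: no ties
                    event = 1, grp = grp)
  fit <- cox_fit(tab, "grp")
  lr <- logrank_test(tab[tab$grp == 1, ], tab[tab$grp == 0, ])
  expect_equal(fit$score_chi2, lr$chi2, tolerance = 1e-6)
})

test_that("Cox estimates are invariant to time rescaling and covariate shifts", {
  set.seed(71)
  tab <- data.frame(time = rexp(100, 0.1), event = rbinom(100, 1, 0.8),
                    x = rnorm(100))
  f0 <- cox_fit(tab, "x")
  tab_days <- transform(tab, time = time * 30.44)
  expect_equal(coef(cox_fit(tab_days, "x")), coef(f0), tolerance = 1e-8)
  tab_shift <- transform(tab, x = x + 1000)
  expect_equal(coef(cox_fit(tab_shift, "x")), coef(f0), tolerance = 1e-6)
})

test_that("Cox edge cases: null model, degenerate covariate, separation flag", {
  tab <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 1, 1),
                    x = c(0, 0, 0, 1, 1, 1), const = 2)
  nul <- cox_fit(tab, character(0))
  expect_equal(nrow(nul$coefficients), 0)
  expect_equal(nul$loglik, nul$loglik_null)
  expect_error(cox_fit(tab, "const"), "degenerate")
  expect_error(cox_fit(data.frame(time = 1:3, event = 0, x = 1:3), "x"),
               ">= 1 event")
  # perfect separation: all early events in one group -> flagged
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12, 13),
                    event = c(1, 1, 1, 0, 0, 0, 0),
                    x = c(1, 1, 1, 0, 0, 0, 0))
  expect_warning(fsep <- cox_fit(sep, "x"), "separation")
  expect_true(fsep$flagged)
})

test_that("univariate screen keeps prognostic covariates and drops noise", {
  set.seed(83)
  n <- 300
  covs <- data.frame(strong = rnorm(n), noise = rnorm(n))
  tab <- simulate_survival_cohort(
    survival_sim_spec(n, beta = c(log(3), 0), baseline_rate = 0.05,
                      censor_rate = 0.02, seed = 19),
    covs)
  scr <- univariate_screen(tab, c("strong", "noise"))
  expect_true("strong" %in% scr$selected)
  expect_equal(nrow(scr$table), 2)
  expect_lt(scr$table$wald_p[scr$table$covariate == "strong"], 1e-6)
  expect_identical(univariate_screen(tab, character(0))$selected,
                   character(0))
})

test_that("stepwise selection: true covariate, collinear guard, null model", {
  set.seed(91)
  n <- 500
  covs <- data.frame(true_cov = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                     n3 = rnorm(n))
  tab <- simulate_survival_cohort(
    survival_sim_spec(n, beta = c(log(2.5), 0, 0, 0), baseline_rate = 0.05,
                      censor_rate = 0.02, seed = 7),
    covs)
  fit <- stepwise_cox(tab, names(covs))
  expect_true("true_cov" %in% fit$coefficients$covariate)

  # duplicated copies of one covariate: exactly one enters (tie by name)
  tab$dup_a <- tab$true_cov
  tab$dup_b <- tab$true_cov
  fit2 <- stepwise_cox(tab, c("dup_a", "dup_b"))
  expect_identical(fit2$coefficients$covariate, "dup_a")

  # no candidate below p_enter: the null model comes back
  fit3 <- stepwise_cox(tab, c("n1", "n2", "n3"), p_enter = 1e-12)
  expect_equal(nrow(fit3$coefficients), 0)
})
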