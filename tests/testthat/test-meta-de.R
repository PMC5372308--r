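test_that("moderated t matches hand arithmetic and its Student-t limit", {
  # case=(3,5), control=(1,3), s0=0.5: diff = 2, sp = sqrt(2),
  # se = sqrt(2)*sqrt(1/2+1/2) = sqrt(2), t = 2/(sqrt(2)+0.5)
  r <- moderated_t(c(3, 5), c(1, 3), s0 = 0.5)
  expect_equal(r$mean_diff, 2)
  expect_equal(r$t_mod, 2 / (sqrt(2) + 0.5))

  # identical group means: t = 0 regardless of s0
  expect_equal(moderated_t(c(1, 3), c(0, 4), s0 = 2)$t_mod, 0)

  # s0 = 0 reduces exactly to the pooled-variance Student t
  set.seed(4)
  a <- rnorm(7); b <- rnorm(9)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(moderated_t(a, b, 0)$t_mod, unname(tt$statistic),
               tolerance = 1e-12)

  expect_error(moderated_t(c(1, 1), c(1, 1), s0 = 0), "zero denominator")
})

test_that("fudge constant is the requested quantile of the SE terms", {
  s <- toy_study(J = 100, n1 = 6, n2 = 6, seed = 12)
  ci <- which(s$classes == "T")
  se <- apply(s$values, 1, function(v) {
    sp <- sqrt(((6 - 1) * var(v[ci]) + (6 - 1) * var(v[-ci])) / 10)
    sp * sqrt(1 / 6 + 1 / 6)
  })
  expect_equal(estimate_fudge(s, 0.5),
               unname(quantile(sort(se), 0.5)))
  expect_equal(estimate_fudge(s, 0), min(se))

  # all features with identical spread: s0 equals that common SE
  vals <- matrix(rep(c(0, 1, 2, 3), each = 5), 5, 4,
                 dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  s2 <- study_matrix(vals, c("T", "T", "N", "N"), case_class = "T")
  common_se <- sqrt(((1) * var(c(0, 1)) + (1) * var(c(2, 3))) / 2) * sqrt(1)
  expect_equal(estimate_fudge(s2, 0.5), common_se)
})

test_that("Fisher combination: closed form, symmetry, monotonicity", {
  expect_equal(fisher_combine(c(1, 1, 1)), 0)
  expect_equal(fisher_combine(c(0.1, 0.1)), -2 * (log(0.1) + log(0.1)))
  expect_equal(fisher_combine(c(0.1, 0.1)), 9.21034, tolerance = 1e-6)
  p <- c(0.3, 0.05, 0.8)
  expect_equal(fisher_combine(p), fisher_combine(rev(p)))
  # strictly increasing as any p decreases
  expect_gt(fisher_combine(c(0.2, 0.5)), fisher_combine(c(0.3, 0.5)))
  expect_error(fisher_combine(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("exact enumeration equals the brute-force permutation oracle", {
  for (seed in 1:3) {
    s <- toy_study(J = 8, n1 = 2, n2 = 2, seed = seed, delta = 1)
    meta <- meta_dataset(list(s, toy_study(J = 8, n1 = 3, n2 = 3,
                                           seed = seed + 50,
                                           study_id = "toy2")))
    s0 <- vapply(meta$studies, estimate_fudge, 0)
    w <- capture_warnings(
      null <- permutation_null(meta, B = 50, s0 = s0, seed = 1))
    expect_true(length(w) >= 1 && all(grepl("exact enumeration", w)))
    for (k in 1:2) {
      oracle <- perm_p_bruteforce(meta$studies[[k]], s0[k])
      got <- null$studies[[k]]
      expect_equal(got$method, "exact")
      expect_equal(got$p_two, unname(oracle$p_two), tolerance = 1e-12)
      expect_equal(got$p_up, unname(oracle$p_up), tolerance = 1e-12)
      expect_equal(got$p_down, unname(oracle$p_down), tolerance = 1e-12)
      # n1 = n2 = 2 has 6 assignments: p on the grid {1/6, ..., 1}
      if (k == 1) expect_true(all(got$p_two * 6 == round(got$p_two * 6)))
    }
  }
})

test_that("sampled permutation p-values: estimator bounds and constant features", {
  s1 <- toy_study(J = 5, n1 = 6, n2 = 6, seed = 2, study_id = "a")
  s2 <- toy_study(J = 5, n1 = 6, n2 = 6, seed = 3, study_id = "b")
  # plant a constant feature in both studies
  s1$values["f03", ] <- 7; s2$values["f03", ] <- 7
  meta <- meta_dataset(list(s1, s2))
  B <- 40
  null <- permutation_null(meta, B = B, seed = 9)
  for (k in 1:2) {
    p <- null$studies[[k]]$p_two
    expect_true(all(p >= 1 / (B + 1) & p <= 1))
    expect_equal(p[3], 1)  # constant feature: t = 0 everywhere
    # both one-sided tails count the observed point
    expect_true(all(null$studies[[k]]$p_up + null$studies[[k]]$p_down >= 1))
  }
})

test_that("Hedges g matches hand arithmetic, antisymmetry and metafor", {
  # case=(2,4), control=(0,2): d = 2/2 = 1..., n = 4, J = 1 - 3/7
  r <- hedges_g(c(2, 4), c(0, 2))
  sp <- sqrt((var(c(2, 4)) + var(c(0, 2))) / 2)
  d <- 2 / sp
  J <- 1 - 3 / (4 * 4 - 9)
  expect_equal(r$g, J * d)
  expect_equal(r$v, 4 / 4 + (J * d)^2 / 8)

  # equal means: g = 0, v = (n1+n2)/(n1 n2)
  r0 <- hedges_g(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r0$g, 0)
  expect_equal(r0$v, 6 / 9)

  # swapping groups flips the sign exactly
  set.seed(5)
  a <- rnorm(10, 1); b <- rnorm(12)
  expect_equal(hedges_g(a, b)$g, -hedges_g(b, a)$g)

  # agrees with metafor's standardized-mean-difference computation
  es <- metafor::escalc(measure = "SMD",
                        m1i = mean(a), m2i = mean(b),
                        sd1i = sd(a), sd2i = sd(b),
                        n1i = length(a), n2i = length(b))
  expect_equal(hedges_g(a, b)$g, es$yi[1], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(hedges_g(a, b)$v, es$vi[1], tolerance = 1e-3)

  expect_error(hedges_g(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("effect pooling: closed forms, DL heterogeneity, metafor agreement", {
  # single study: both pooled estimates equal the input
  r1 <- combine_effects(0.8, 0.1)
  expect_equal(r1$mu_fixed, 0.8)
  expect_equal(r1$mu_random, 0.8)
  expect_equal(r1$tau2, 0)

  # two identical studies: mu = g, se = sqrt(v/2), Q = 0, I2 = 0
  r2 <- combine_effects(c(0.5, 0.5), c(0.08, 0.08))
  expect_equal(r2$mu_fixed, 0.5)
  expect_equal(r2$se_fixed, sqrt(0.08 / 2))
  expect_equal(r2$Q, 0)
  expect_equal(r2$I2, 0)
  expect_equal(r2$mu_random, r2$mu_fixed)

  # three heterogeneous studies: hand-evaluated Q = 18 >> df = 2
  g <- c(0.2, 0.8, 1.4); v <- rep(0.04, 3)
  r3 <- combine_effects(g, v)
  expect_equal(r3$Q, sum((g - 0.8)^2) / 0.04)
  expect_equal(r3$Q, 18)
  expect_gt(r3$tau2, 0)
  expect_gt(r3$se_random, r3$se_fixed)
  expect_equal(r3$ci95_low, r3$mu_random - 1.96 * r3$se_random)

  # independent oracle: metafor DerSimonian-Laird
  mf <- metafor::rma(yi = g, vi = v, method = "DL")
  expect_equal(r3$mu_random, unname(mf$beta[1, 1]), tolerance = 1e-10)
  expect_equal(r3$se_random, mf$se, tolerance = 1e-10)
  expect_equal(r3$tau2, mf$tau2, tolerance = 1e-10)
  fe <- metafor::rma(yi = g, vi = v, method = "FE")
  expect_equal(r3$mu_fixed, unname(fe$beta[1, 1]), tolerance = 1e-10)

  expect_error(combine_effects(c(0.1, 0.2), c(0.1, 0)), "> 0")
})

test_that("integrated fit classifies planted directions and flags conflicts", {
  # strong up-feature across 5 studies of 15+15: direction must be "up"
  sim <- simulate_meta_dataset(simulation_spec(
    n_studies = 5, n_features = 60, n_case = 15, n_control = 15,
    n_de = 6, effect_g = 2, frac_up = 1, tau = 0.1, seed = 41))
  fit <- meta_de(sim$dataset, B = 100, seed = 7)
  planted <- fit$table[fit$table$feature_id %in% sim$truth$feature_id, ]
  expect_true(all(planted$direction == "up"))
  expect_true(all(planted$mu_fixed > 0))
  expect_true(all(fit$table$q_bh >= fit$table$p_perm))

  # a feature up in half the studies and down in the rest, equal magnitude
  studies <- lapply(1:4, function(k) {
    s <- toy_study(J = 30, n1 = 15, n2 = 15, seed = 60 + k,
                   study_id = paste0("s", k))
    shift <- if (k <= 2) 2 else -2
    s$values["f01", s$classes == "T"] <-
      s$values["f01", s$classes == "T"] + shift
    s
  })
  fit2 <- meta_de(meta_dataset(studies), B = 150, seed = 8)
  expect_equal(fit2$table$direction[fit2$table$feature_id == "f01"],
               "inconsistent")
})

test_that("meta_de output contract: invariants of the result table", {
  sim <- simulate_meta_dataset(simulation_spec(
    n_studies = 3, n_features = 40, n_case = 8, n_control = 8,
    n_de = 4, seed = 77))
  fit <- meta_de(sim$dataset, B = 60, seed = 2)
  tab <- fit$table
  expect_equal(nrow(tab), 40)
  expect_true(all(tab$tau2 >= 0))
  expect_true(all(tab$I2 >= 0 & tab$I2 <= 100))
  expect_true(all(tab$se_random[tab$tau2 > 0] >=
                    tab$se_fixed[tab$tau2 > 0]))
  expect_true(all(tab$q_bh >= tab$p_perm))
  expect_true(all(tab$mu_fixed[tab$direction == "up"] > 0))
  expect_true(all(tab$mu_fixed[tab$direction == "down"] < 0))
  # coef() exposes the pooled random-effects estimates
  expect_equal(unname(coef(fit)), tab$mu_random)
  # determinism given the seed
  fitb <- meta_de(sim$dataset, B = 60, seed = 2)
  expect_identical(fit$table, fitb$table)
  # forest table: per-study rows plus the two pooled rows
  ft <- forest_table(fit, tab$feature_id[1])
  expect_equal(nrow(ft), 5)
  expect_equal(sum(ft$weight[1:3]), 100)
})
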