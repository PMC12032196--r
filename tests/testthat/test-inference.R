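test_that("Cochran's Q matches hand arithmetic and the equal-variance closed form", {
  expect_equal(cochran_q(c(1, 1), c(1, 1)), list(Q = 0, df = 1L))
  expect_equal(cochran_q(c(0, 2), c(1, 1)), list(Q = 2, df = 1L))
  expect_error(cochran_q(1, 1), "at least 2")

  set.seed(21)
  y <- rnorm(15)
  v <- 0.3
  q <- cochran_q(y, rep(v, 15))
  expect_equal(q$Q, (15 - 1) * var(y) / v, tolerance = 1e-12)
})

test_that("DerSimonian-Laird tau2 equals its closed form on random small instances", {
  expect_equal(estimate_tau2(c(0, 2), c(1, 1), "DL")$tau2, 1.0)
  expect_equal(estimate_tau2(rep(0.4, 5), runif(5, 0.1, 1), "DL")$tau2, 0)

  set.seed(99)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    y <- rnorm(k, 0.2, 0.5)
    v <- runif(k, 0.05, 1)
    # independent brute-force evaluation of the estimator
    w <- 1 / v
    mu <- sum(w * y) / sum(w)
    Q <- sum(w * (y - mu)^2)
    tau2_oracle <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    expect_equal(estimate_tau2(y, v, "DL")$tau2, tau2_oracle,
                 tolerance = 1e-10)
  }
})

test_that("DL and REML agree with an established reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(31)
  for (i in 1:5) {
    k <- 25
    v <- runif(k, 0.01, 0.2)
    y <- rnorm(k, 0.3, sqrt(v + 0.05))
    for (m in c("DL", "REML")) {
      ours <- estimate_tau2(y, v, m)
      ref <- metafor::rma(yi = y, vi = v, method = m)
      expect_lt(abs(ours$tau2 - ref$tau2), 1e-4)
      expect_lt(abs(ours$estimate - as.numeric(ref$beta)), 1e-4)
    }
  }
})

test_that("REML is unbiased at moderate heterogeneity and clean at the boundary", {
  set.seed(77)
  est <- replicate(500, {
    y <- rnorm(200, 0.2, sqrt(0.04 + 0.01))
    estimate_tau2(y, rep(0.01, 200), "REML")$tau2
  })
  expect_lt(abs(mean(est) - 0.04), 0.015)

  # true tau2 = 0: estimates are never negative and mostly exactly zero
  set.seed(78)
  est0 <- replicate(50, {
    v <- runif(20, 0.05, 0.2)
    estimate_tau2(rnorm(20, 0, sqrt(v)), v, "REML")$tau2
  })
  expect_true(all(est0 >= 0))
  expect_gt(mean(est0 == 0), 0.5)

  # identical effects have zero heterogeneity under both estimators
  expect_equal(estimate_tau2(rep(1.2, 8), runif(8, 0.1, 1), "REML")$tau2, 0)
})

test_that("tau2 estimates are invariant to observation order", {
  set.seed(13)
  y <- rnorm(12, 0.5, 0.4); v <- runif(12, 0.02, 0.3)
  perm <- sample(12)
  for (m in c("DL", "REML")) {
    expect_equal(estimate_tau2(y, v, m)$tau2,
                 estimate_tau2(y[perm], v[perm], m)$tau2, tolerance = 1e-10)
  }
})

test_that("vanishing sampling variances drive the pooled estimate to the unweighted mean", {
  set.seed(14)
  y <- rnorm(10, 0.3, 0.5)
  fit <- estimate_tau2(y, rep(1e-10, 10), "DL")
  expect_equal(fit$estimate, mean(y), tolerance = 1e-6)
})

test_that("significance follows the CI-excludes-zero rule", {
  expect_true(significance_by_ci(list(ci_low = 0.1, ci_high = 0.5)))
  expect_false(significance_by_ci(list(ci_low = -0.1, ci_high = 0.5)))
  expect_true(significance_by_ci(list(ci_low = -0.5, ci_high = -0.1)))
})

test_that("subgroup contrasts use a two-sided z-test with conventional stars", {
  f <- list(estimate = 0.4, se = 0.1)
  ct <- contrast_subgroups(f, f)
  expect_equal(ct$diff, 0)
  expect_equal(ct$p, 1)
  expect_equal(ct$stars, "ns")

  ct2 <- contrast_subgroups(list(estimate = 1, se = 0.1),
                            list(estimate = 0, se = 0.1))
  expect_equal(ct2$z, 1 / sqrt(0.02), tolerance = 1e-10) # ~7.07
  expect_lt(ct2$p, 0.001)
  expect_equal(ct2$stars, "***")
})

test_that("the contrast z-test holds its nominal type-I error", {
  set.seed(55)
  k <- 30
  rej <- replicate(1000, {
    v <- runif(2 * k, 0.02, 0.2)
    ya <- rnorm(k, 0.3, sqrt(v[1:k]))
    yb <- rnorm(k, 0.3, sqrt(v[(k + 1):(2 * k)]))
    ct <- contrast_subgroups(estimate_tau2(ya, v[1:k], "DL"),
                             estimate_tau2(yb, v[(k + 1):(2 * k)], "DL"))
    ct$p < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("the recovery-type summary mirrors the forest-plot structure", {
  sim <- generate_meta_dataset(quick_sim_config(seed = 9, n_studies = 40L))
  tab <- assign_subgroups(suppressWarnings(
    prepare_observations(sim$table, strict = FALSE)))
  eff <- compute_effects(tab)
  sm <- recovery_type_summary(eff)
  expect_true(all(c("variable", "recovery_type", "k", "lnrr_bar",
                    "ci_low", "ci_high", "pct_change", "contrast_p",
                    "stars") %in% names(sm)))
  # contrasts are symmetric within a variable pair
  for (v in unique(sm$variable)) {
    ps <- sm$contrast_p[sm$variable == v]
    expect_true(length(unique(round(ps, 12))) <= 1 || all(is.na(ps)))
  }
  # small cells are descriptive
  expect_true(all(sm$descriptive == (sm$k < 2)))
  # an ecosystem slice adds the slicing column
  sm2 <- recovery_type_summary(eff, slice = "ecosystem")
  expect_true(all(sm2$ecosystem %in% c("forest", "grassland")))
})
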