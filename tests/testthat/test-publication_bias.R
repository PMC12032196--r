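test_that("Egger intercept is exactly zero on a mirror-symmetric funnel", {
  # symmetric in both effect and precision: regression slope and intercept
  # are forced to zero
  y <- c(-2, -1, 1, 2)
  v <- c(4, 1, 1, 4)
  eg <- egger_test(y, v)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_error(egger_test(c(1, 2), c(1, 1)), "at least 3")
  expect_error(egger_test(c(1, 2, 3), c(1, 1, 1)), "degenerate")
})

test_that("Egger regression equals a hand-computed normal-equations solution", {
  y <- c(1, 2, 3)
  v <- c(1, 4, 9)
  eg <- suppressWarnings(egger_test(y, v))  # exactly collinear fixture
  # oracle: OLS of z on x via explicit 2x2 normal equations
  se <- sqrt(v); z <- y / se; x <- 1 / se
  n <- 3
  det <- n * sum(x^2) - sum(x)^2
  b0 <- (sum(x^2) * sum(z) - sum(x) * sum(x * z)) / det
  b1 <- (n * sum(x * z) - sum(x) * sum(z)) / det
  expect_equal(eg$intercept, b0, tolerance = 1e-12)
  expect_equal(eg$slope, b1, tolerance = 1e-12)
})

test_that("Egger p-value is invariant to a common variance rescaling", {
  set.seed(17)
  y <- rnorm(20, 0.4, 0.5)
  v <- runif(20, 0.02, 0.4)
  e1 <- egger_test(y, v)
  e2 <- egger_test(y, 7.3 * v)
  expect_equal(e1$p, e2$p, tolerance = 1e-10)
  expect_equal(e1$t, e2$t, tolerance = 1e-10)
})

test_that("Egger test holds its nominal size under no suppression", {
  set.seed(23)
  rej <- replicate(1000, {
    v <- runif(30, 0.01, 0.25)
    y <- rnorm(30, 0.2, sqrt(v))
    egger_test(y, v)$p < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("trim-and-fill leaves symmetric data untouched", {
  y <- 0.5 + c(-4, -3, -2, -1, 0, 1, 2, 3, 4) / 10
  v <- rep(0.04, 9)
  tf <- trim_and_fill(y, v, side = "left")
  expect_equal(tf$k0, 0L)
  expect_equal(nrow(tf$filled), 0)
  expect_equal(tf$adjusted$estimate, tf$original$estimate)
})

test_that("trim-and-fill recovers points deleted from one funnel side", {
  # mirror-symmetric funnel: a precise core and noisy extremes; deleting the
  # two most negative extremes leaves an observed excess on the right that
  # the rank algorithm detects and mirrors back
  mu <- 0.5
  off <- c(-4.2, -3.1, -2.05, -1.1, 0, 1.1, 2.05, 3.1, 4.2) / 10
  y_full <- mu + off
  v <- c(0.3, 0.3, 0.02, 0.02, 0.02, 0.02, 0.02, 0.3, 0.3)
  keep <- order(y_full)[-(1:2)]          # delete the 2 most negative
  y_obs <- y_full[keep]; v_obs <- v[keep]

  # rank-formula oracle at the converged trimmed centre (the symmetric core
  # pools exactly to mu): T = ranks of positive deviations = 3+5+6+7 = 21,
  # n = 7, L0 = (4*21 - 56) / 13 = 2.15 -> k0 = 2
  d <- y_obs - mu
  r <- rank(abs(d), ties.method = "first")
  t_pos <- sum(r[d > 0])
  n <- length(d)
  expect_equal(max(0, round((4 * t_pos - n * (n + 1)) / (2 * n - 1))), 2)

  tf <- trim_and_fill(y_obs, v_obs, side = "left", estimator = "L0")
  expect_equal(tf$k0, 2L)
  # the filled pseudo-studies sit exactly at the deleted points' positions
  expect_equal(sort(tf$filled$lnrr), sort(y_full[order(y_full)[1:2]]),
               tolerance = 1e-10)
  expect_equal(tf$filled$v, c(0.3, 0.3))
  # mirror symmetry of fill around the trimmed centre
  expect_equal(sort(mu - tf$filled$lnrr),
               sort(sort(y_obs, decreasing = TRUE)[1:2] - mu),
               tolerance = 1e-10)
  # adjustment moves the estimate back toward the pre-deletion value
  pre <- estimate_tau2(y_full, v)$estimate
  expect_lt(abs(tf$adjusted$estimate - pre),
            abs(tf$original$estimate - pre))
  expect_lt(tf$adjusted$estimate, tf$original$estimate)
})

test_that("trim-and-fill agrees with an established reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(41)
  for (i in 1:5) {
    v <- runif(25, 0.01, 0.2)
    y <- rnorm(25, 0.3, sqrt(v + 0.02))
    drop <- order(y)[1:3]                 # crude one-sided deletion
    y <- y[-drop]; v <- v[-drop]
    ref <- suppressWarnings(
      metafor::trimfill(metafor::rma(yi = y, vi = v, method = "DL"),
                        side = "left", estimator = "L0"))
    tf <- trim_and_fill(y, v, side = "left", estimator = "L0")
    expect_lte(abs(tf$k0 - ref$k0), 1)
  }
})

test_that("estimated k0 tracks the number of suppressed studies", {
  # funnel with precisions spanning a realistic order-of-magnitude range
  set.seed(61)
  for (m in c(2L, 5L)) {
    k0s <- replicate(100, {
      v <- exp(runif(30 + m, log(0.005), log(1)))
      y <- rnorm(30 + m, 0.3, sqrt(v))
      drop <- order(y)[seq_len(m)]       # suppress the m most negative
      tf <- suppressWarnings(trim_and_fill(y[-drop], v[-drop], side = "left"))
      tf$k0
    })
    expect_lte(abs(median(k0s) - m), 1)
  }
})

test_that("the bias verdict compares the original estimate to the imputed CI", {
  expect_equal(bias_verdict(list(estimate = 0.20),
                            list(ci_low = 0.10, ci_high = 0.30)),
               "no_material_bias")
  expect_equal(bias_verdict(list(estimate = 0.50),
                            list(ci_low = 0.10, ci_high = 0.30)),
               "possible_bias")
  # k0 = 0: adjusted equals original, verdict can only be clean
  y <- 0.3 + seq(-0.4, 0.4, length.out = 9)
  v <- rep(0.05, 9)
  tf <- trim_and_fill(y, v, side = "left")
  expect_equal(bias_verdict(tf$original, tf$adjusted), "no_material_bias")
})

test_that("the screening report applies trim-and-fill only below the Egger threshold", {
  sim <- generate_meta_dataset(quick_sim_config(seed = 19, n_studies = 40L))
  tab <- assign_subgroups(prepare_observations(sim$table))
  eff <- compute_effects(tab)
  rep_all <- bias_report(eff, alpha = 0.05)
  expect_true(all(rep_all$k0[rep_all$screened %in% FALSE & rep_all$k >= 3] == 0))
  # alpha = 1 screens everything estimable
  rep_full <- bias_report(eff, alpha = 1)
  expect_true(all(rep_full$screened[rep_full$k >= 3]))
  expect_true(all(rep_full$verdict[rep_full$k >= 3] %in%
                    c("no_material_bias", "possible_bias")))
})

test_that("funnel export provides points and pseudo-confidence contours", {
  set.seed(3)
  v <- runif(12, 0.01, 0.2)
  y <- rnorm(12, 0.2, sqrt(v))
  fd <- funnel_data(y, v)
  expect_equal(nrow(fd$points), 12)
  expect_equal(fd$contour$upper - fd$contour$center[1],
               1.96 * fd$contour$se, tolerance = 1e-12)
})
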