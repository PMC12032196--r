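# generating design used for recovery checks: moderate climate effects,
# stronger plant->microbe links, modest mediator->phosphorus paths
demo_path_design <- function() {
  spec <- default_path_spec()
  list(spec = spec,
       coefs = data.frame(from = spec$edges$from, to = spec$edges$to,
                          value = c(rep(0.3, 10), 0.35, 0.35, rep(0.22, 10))),
       covs = c("mat~~map" = 0.3, "STP~~SAP" = 0.15))
}

test_that("path specifications validate endpoints and reject cycles", {
  expect_error(path_spec(c("a", "b"), data.frame(from = "a", to = "c")),
               "not declared")
  expect_error(path_spec(c("a", "b", "c"),
                         data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "a"))),
               "cycle")
  sp <- path_spec(c("a", "b", "c"),
                  data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(sp$order, c("a", "b", "c"))
})

test_that("a saturated model reproduces the sample covariance with zero chi-square", {
  set.seed(2)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("x", "m", "y")))
  sat <- path_spec(c("x", "m", "y"),
                   data.frame(from = c("x", "x", "m"),
                              to = c("m", "y", "y")))
  fit <- fit_path_model(data = X, spec = sat, restarts = 2)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi2, 1e-4)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$implied, fit$S, tolerance = 1e-6)
})

test_that("a single-edge standardized coefficient equals the sample correlation", {
  set.seed(4)
  n <- 1e5
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, 0, 0.8)
  X <- cbind(x = x, y = y)
  sp <- path_spec(c("x", "y"), data.frame(from = "x", to = "y"))
  fit <- fit_path_model(data = X, spec = sp, restarts = 2)
  expect_equal(fit$coefficients$std, cor(x, y), tolerance = 1e-6)
})

test_that("chain path coefficients multiply to the implied end-to-end correlation", {
  sp <- path_spec(c("x", "m", "y"),
                  data.frame(from = c("x", "m"), to = c("m", "y")))
  sim <- generate_path_data(sp, c("x->m" = 0.5, "m->y" = 0.5), n = 1e5,
                            seed = 6)
  X <- sim$data
  fit <- fit_path_model(data = X, spec = sp, restarts = 2)
  prod_std <- prod(fit$coefficients$std)
  expect_lt(abs(prod_std - cor(X[, "x"], X[, "y"])), 1e-2)
  expect_lt(abs(prod_std - 0.25), 2e-2)
})

test_that("the full recovery model is estimated without bias", {
  d <- demo_path_design()
  errs <- replicate(8, NA_real_)
  sum_err <- 0
  for (r in 1:8) {
    sim <- generate_path_data(d$spec, d$coefs, n = 2000,
                              covariance_values = d$covs, seed = 100 + r)
    fit <- fit_path_model(data = sim$data, spec = d$spec, restarts = 1)
    err <- fit$coefficients$std - sim$truth$coefficients$std
    errs[r] <- mean(abs(err))
    sum_err <- sum_err + err
  }
  # per-replicate absolute error is small, and the average bias smaller still
  expect_lt(mean(errs), 0.03)
  expect_lt(max(abs(sum_err / 8)), 0.02)
})

test_that("chi-square never increases when edges are added to a nested model", {
  set.seed(10)
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  X[, "d"] <- 0.4 * X[, "a"] + 0.3 * X[, "b"] + rnorm(200, 0, 0.8)
  small <- path_spec(colnames(X), data.frame(from = "a", to = "d"))
  big <- path_spec(colnames(X),
                   data.frame(from = c("a", "b", "c"), to = c("d", "d", "d")))
  f_small <- fit_path_model(data = X, spec = small, restarts = 2)
  f_big <- fit_path_model(data = X, spec = big, restarts = 2)
  expect_lte(f_big$chi2, f_small$chi2 + 1e-6)
})

test_that("degenerate inputs are rejected with clear errors", {
  sp <- path_spec(c("x", "y"), data.frame(from = "x", to = "y"))
  S_bad <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(fit_path_model(spec = sp, S = S_bad, n = 50),
               "positive definite")
  S_ok <- matrix(c(1, 0.3, 0.3, 1), 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(fit_path_model(spec = sp, S = S_ok, n = 2), "exceed")
})

test_that("fit indices match their closed forms", {
  idx <- fit_indices(50, 10, 100, 15, 101)
  expect_equal(idx$rmsea, sqrt(40 / 1000)) # 0.2
  expect_equal(idx$cmin_df, 5)
  expect_equal(idx$nfi, 0.5)

  expect_equal(fit_indices(10, 10, 100, 15, 50)$rmsea, 0)
  perfect <- fit_indices(0, 5, 100, 10, 50)
  expect_equal(perfect$nfi, 1)
  expect_equal(perfect$cfi, 1)
  expect_error(fit_indices(5, 2, 0, 10, 50), "degenerate baseline")
})

test_that("the acceptance rule applies all three criteria", {
  ok <- list(rmsea = 0.03, cmin_df = 1.2, nfi = 0.5, cfi = 0.95, ifi = 0.5)
  expect_true(evaluate_acceptance(ok)$accepted)

  bad_rmsea <- list(rmsea = 0.12, cmin_df = 1.2, nfi = 0.95, cfi = 0.95,
                    ifi = 0.95)
  res <- evaluate_acceptance(bad_rmsea)
  expect_false(res$accepted)
  expect_false(res$checks[["rmsea"]])
  expect_match(res$note, "poor")

  bad_cmin <- list(rmsea = 0.04, cmin_df = 3.0, nfi = 0.95, cfi = 0.95,
                   ifi = 0.95)
  res2 <- evaluate_acceptance(bad_cmin)
  expect_false(res2$accepted)
  expect_false(res2$checks[["cmin_df"]])

  # truth table over the comparative-index disjunction
  for (trip in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))) {
    f <- list(rmsea = 0.02, cmin_df = 1,
              nfi = ifelse(trip[1], 0.95, 0.5),
              cfi = ifelse(trip[2], 0.95, 0.5),
              ifi = ifelse(trip[3], 0.95, 0.5))
    expect_equal(evaluate_acceptance(f)$accepted, sum(trip) > 0)
  }
})

test_that("the study matrix builder assembles composites and climate per study", {
  eff <- data.frame(
    study_id = c("s1", "s1", "s1", "s2", "s2"),
    variable = c("plant_shannon", "plant_richness", "STP", "AGB", "SAP"),
    recovery_type = "restoration",
    lnrr = c(0.2, 0.4, 0.1, 0.5, 0.3),
    mat = c(10, 10, 10, 5, 5), map = c(600, 600, 600, 400, 400),
    stringsAsFactors = FALSE)
  M <- build_rr_matrix(eff)
  expect_equal(M["s1", "plant_diversity"], 0.3)
  expect_equal(M["s1", "STP"], 0.1)
  expect_true(is.na(M["s1", "AGB"]))
  expect_equal(M["s2", "mat"], 5)

  # pairwise covariance input needs overlap
  expect_error(sem_input(M, use = "pairwise"), "fewer than 2")
  inp <- sem_input(M[, c("mat", "map")], use = "listwise")
  expect_equal(inp$n, 2)
})
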