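test_that("generation is deterministic under a fixed seed, byte for byte", {
  cfg <- quick_sim_config(seed = 123)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_meta_dataset(generate_meta_dataset(cfg), f1)
  write_meta_dataset(generate_meta_dataset(cfg), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the data
  write_meta_dataset(generate_meta_dataset(quick_sim_config(seed = 124)), f2)
  expect_false(tools::md5sum(f1) == tools::md5sum(f2))
  unlink(c(f1, f2))
})

test_that("the noise-free limit reproduces the configured effect", {
  cfg <- meta_sim_config(
    n_studies = 15L, tau2 = 0, cv = 1e-5,
    se_reported_fraction = 0, sd_missing_fraction = 0,
    true_effects = c(AGB = log(2)),
    variable_groups = list(
      biomass = list(p = 1, metrics = c(AGB = 1), force = "AGB")),
    seed = 2)
  sim <- generate_meta_dataset(cfg)
  lnrr <- compute_lnrr(sim$table$mean_t, sim$table$mean_c)
  expect_true(all(abs(lnrr - log(2)) < 1e-3))
})

test_that("generated composition fractions converge to the configured mix", {
  sim <- generate_meta_dataset(meta_sim_config(n_studies = 2000L, seed = 31))
  tab <- sim$table
  per_study <- unique(tab[, c("study_id", "recovery_type", "ecosystem_raw",
                              "duration_years")])
  expect_lt(abs(mean(per_study$recovery_type == "restoration") - 0.7127),
            0.03)
  expect_lt(abs(mean(per_study$ecosystem_raw == "grassland") - 0.6349), 0.03)
  expect_lt(abs(mean(per_study$ecosystem_raw == "shrubland") - 0.0457), 0.03)
  expect_lt(abs(mean(per_study$duration_years < 20) - 0.6566), 0.03)
})

test_that("the default configuration emulates the compiled dataset's shape", {
  sim <- generate_meta_dataset(meta_sim_config(seed = 8))
  expect_equal(length(unique(sim$table$study_id)), 72)
  expect_gt(nrow(sim$table), 350)
  expect_lt(nrow(sim$table), 650)
  # multiple observations per study-variable occur
  g <- table(paste(sim$table$study_id, sim$table$variable))
  expect_gt(max(g), 1)
})

test_that("preparation recovers exactly the generated conversion and imputation counts", {
  for (seed in c(4, 5)) {
    sim <- generate_meta_dataset(quick_sim_config(seed = seed))
    tab <- prepare_observations(sim$table)
    expect_equal(tab$prep_log$counts[["n_se_converted"]],
                 sim$truth$n_se_converted_cells)
    expect_equal(tab$prep_log$counts[["n_sd_imputed"]],
                 sim$truth$n_sd_imputed_cells)
  }
})

test_that("one-sided suppression removes observations and skews the funnel", {
  cfg <- meta_sim_config(
    n_studies = 60L, seed = 15,
    suppression = list(side = "left", z_threshold = 1.0, prob = 0.8))
  sim <- generate_meta_dataset(cfg)
  expect_gt(sim$truth$n_suppressed, 0)
  cfg0 <- meta_sim_config(n_studies = 60L, seed = 15)
  sim0 <- generate_meta_dataset(cfg0)
  expect_equal(nrow(sim0$table), nrow(sim$table) + sim$truth$n_suppressed)
})

test_that("truth records round-trip through JSON serialization", {
  sim <- generate_meta_dataset(quick_sim_config(seed = 44))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(sim$truth, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$tau2, sim$truth$tau2)
  expect_equal(back$n_se_converted_cells, sim$truth$n_se_converted_cells)
  expect_equal(unlist(back$true_effects), unlist(sim$truth$true_effects))
  unlink(f)
})

test_that("path-model simulation honours zero and chained coefficients deterministically", {
  sp <- path_spec(c("x", "m", "y"),
                  data.frame(from = c("x", "m"), to = c("m", "y")))
  # zero coefficients: empirical correlations are null
  sim0 <- generate_path_data(sp, c("x->m" = 0, "m->y" = 0), n = 5000,
                             seed = 9)
  C <- cor(sim0$data)
  expect_lt(max(abs(C[upper.tri(C)])), 3 / sqrt(5000))

  # chain of 0.5s: end-to-end correlation ~ 0.25
  sim <- generate_path_data(sp, c("x->m" = 0.5, "m->y" = 0.5), n = 1e5,
                            seed = 10)
  expect_lt(abs(cor(sim$data[, "x"], sim$data[, "y"]) - 0.25), 0.01)
  expect_equal(sim$truth$coefficients$std, c(0.5, 0.5))

  # determinism
  sim2 <- generate_path_data(sp, c("x->m" = 0.5, "m->y" = 0.5), n = 1e5,
                             seed = 10)
  expect_identical(sim$data, sim2$data)

  # cycles are rejected at spec construction
  expect_error(path_spec(c("x", "y"),
                         data.frame(from = c("x", "y"), to = c("y", "x"))),
               "cycle")
})
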