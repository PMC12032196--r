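#' Default true effects for the meta-analysis simulator
#'
#' Per-variable true log response ratios used by [meta_sim_config()]: strong
#' positive responses for biomass and coverage, moderate ones for plant
#' diversity and microbial biomass phosphorus, small ones for soil phosphorus
#' pools and microbial alpha-diversity.
#'
#' @return named numeric vector of lnRR values.
#' @export
default_true_effects <- function() {
  c(AGB = 0.50, BGB = 0.45, LB = 0.30, coverage = 0.45,
    plant_richness = 0.25, plant_shannon = 0.20, plant_simpson = 0.15,
    STP = 0.15, SAP = 0.12, MBP = 0.20,
    bacteria_shannon = 0.10, bacteria_richness = 0.10, bacteria_chao1 = 0.10,
    fungi_shannon = 0.05, fungi_richness = 0.05, fungi_chao1 = 0.05)
}

# which variables a study measures: group-presence then within-group metrics,
# forcing one metric per present group so presence is never vacuous
default_variable_groups <- function() {
  list(
    soil = list(p = 0.90, metrics = c(STP = 0.65, SAP = 0.55),
                force = "STP"),
    biomass = list(p = 0.40, metrics = c(AGB = 0.70, BGB = 0.50, LB = 0.20),
                   force = "AGB"),
    plant = list(p = 0.45,
                 metrics = c(coverage = 0.45, plant_richness = 0.60,
                             plant_shannon = 0.55, plant_simpson = 0.30),
                 force = "plant_richness"),
    bacteria = list(p = 0.28,
                    metrics = c(bacteria_shannon = 0.80,
                                bacteria_richness = 0.50,
                                bacteria_chao1 = 0.50),
                    force = "bacteria_shannon"),
    fungi = list(p = 0.22,
                 metrics = c(fungi_shannon = 0.80, fungi_richness = 0.50,
                             fungi_chao1 = 0.50),
                 force = "fungi_shannon"),
    mbp = list(p = 0.10, metrics = c(MBP = 1.0), force = "MBP")
  )
}

#' Configuration for the meta-analysis data simulator
#'
#' Defaults emulate the composition of the compiled restoration dataset:
#' 72 studies with roughly 460-520 observations, a 71.27% share of passive
#' restoration experiments, ecosystems split 63.49% grassland / 31.94%
#' forest / 4.57% shrubland, 65.66% of durations under 20 years (split
#' evenly between the 0-10 and 10-20 bins), one to three observations per
#' study-variable, a fraction of rows reporting SE instead of SD and a
#' fraction missing dispersion entirely.
#'
#' @param n_studies number of studies (>= 2).
#' @param obs_range integer range (min, max) of observations per
#'   study-variable, drawn uniformly.
#' @param true_effects named vector of true lnRR per variable.
#' @param tau2 between-study variance of true effects (lnRR^2 scale).
#' @param cv within-group coefficient of variation used to generate SDs
#'   (SD = cv * mean); at the default 0.1 the mean/10 imputation rule is
#'   exact in expectation.
#' @param se_reported_fraction fraction of rows reporting SE instead of SD.
#' @param sd_missing_fraction fraction of rows reporting neither SD nor SE.
#' @param restoration_fraction probability a study is passive restoration.
#' @param ecosystem_probs named probabilities for grassland/forest/shrubland.
#' @param duration_probs named probabilities for the three duration bins.
#' @param variable_groups study-level variable inclusion design; see
#'   `default_variable_groups()` source for the structure.
#' @param n_range integer range of per-group sample sizes.
#' @param control_mean_meanlog,control_mean_sdlog lognormal parameters of
#'   the control means.
#' @param suppression optional list `(side, z_threshold, prob)` dropping
#'   observations one-sidedly by their z = lnRR/sqrt(v) to create funnel
#'   asymmetry; `NULL` disables it.
#' @param seed integer RNG seed.
#' @return list of class `meta_sim_config`.
#' @export
meta_sim_config <- function(n_studies = 72L,
                            obs_range = c(1L, 3L),
                            true_effects = default_true_effects(),
                            tau2 = 0.05,
                            cv = 0.1,
                            se_reported_fraction = 0.3,
                            sd_missing_fraction = 0.1,
                            restoration_fraction = 0.7127,
                            ecosystem_probs = c(grassland = 0.6349,
                                                forest = 0.3194,
                                                shrubland = 0.0457),
                            duration_probs = c(d0_10 = 0.3283,
                                               d10_20 = 0.3283,
                                               d20_plus = 0.3434),
                            variable_groups = default_variable_groups(),
                            n_range = c(3L, 10L),
                            control_mean_meanlog = 3,
                            control_mean_sdlog = 0.5,
                            suppression = NULL,
                            seed = 1L) {
  stopifnot(n_studies >= 2, tau2 >= 0, cv >= 0,
            se_reported_fraction >= 0, sd_missing_fraction >= 0,
            se_reported_fraction + sd_missing_fraction <= 1,
            restoration_fraction >= 0, restoration_fraction <= 1,
            abs(sum(ecosystem_probs) - 1) < 1e-6,
            abs(sum(duration_probs) - 1) < 1e-6)
  structure(
    list(n_studies = as.integer(n_studies), obs_range = as.integer(obs_range),
         true_effects = true_effects, tau2 = tau2, cv = cv,
         se_reported_fraction = se_reported_fraction,
         sd_missing_fraction = sd_missing_fraction,
         restoration_fraction = restoration_fraction,
         ecosystem_probs = ecosystem_probs,
         duration_probs = duration_probs,
         variable_groups = variable_groups, n_range = as.integer(n_range),
         control_mean_meanlog = control_mean_meanlog,
         control_mean_sdlog = control_mean_sdlog,
         suppression = suppression, seed = as.integer(seed)),
    class = "meta_sim_config")
}

study_variables <- function(groups) {
  vars <- character()
  for (g in groups) {
    if (stats::runif(1) < g$p) {
      inc <- names(g$metrics)[stats::runif(length(g$metrics)) < g$metrics]
      if (!length(inc)) inc <- g$force
      vars <- c(vars, inc)
    }
  }
  # every included study reports something; fall back to the first group's
  # forced metric (the soil-phosphorus requirement of the inclusion criteria)
  if (!length(vars)) vars <- groups[[1]]$force
  vars
}

#' Generate a synthetic meta-analysis dataset with known ground truth
#'
#' Simulates the long observation table consumed by
#' [prepare_observations()]: per study, a recovery type, ecosystem, duration
#' and climate; per study-variable, a true effect `theta = mu_v + N(0, tau2)`;
#' per observation, a lognormal control mean, a treatment mean
#' `control * exp(theta) * exp(sampling noise)` with noise variance
#' `cv^2/n_t + cv^2/n_c`, and SDs equal to `cv * mean`. A configured fraction
#' of rows reports SE instead of SD and another fraction reports neither.
#' Optional one-sided suppression drops observations by their z-score to
#' create funnel asymmetry. Fully deterministic under the config seed.
#'
#' @param config a [meta_sim_config()].
#' @return list of class `meta_sim`: `table` (raw data.frame in the CSV
#'   schema) and `truth` (true effects, tau2, per-column counts of SE
#'   conversions and SD imputations the preparation step must perform,
#'   suppression count, seed).
#' @export
generate_meta_dataset <- function(config = meta_sim_config()) {
  stopifnot(inherits(config, "meta_sim_config"))
  set.seed(config$seed)
  rows <- list()
  for (s in seq_len(config$n_studies)) {
    sid <- sprintf("S%03d", s)
    recovery <- if (stats::runif(1) < config$restoration_fraction)
      "restoration" else "rehabilitation"
    eco <- sample(names(config$ecosystem_probs), 1,
                  prob = config$ecosystem_probs)
    bin <- sample(names(config$duration_probs), 1,
                  prob = config$duration_probs)
    duration <- switch(bin,
                       d0_10 = stats::runif(1, 0.5, 9.5),
                       d10_20 = stats::runif(1, 10, 20),
                       d20_plus = stats::runif(1, 20.5, 40))
    lat <- stats::runif(1, 20, 50)
    lon <- stats::runif(1, 80, 125)
    mat <- stats::rnorm(1, 8, 6)
    map <- max(50, stats::rnorm(1, 600, 250))
    vars <- study_variables(config$variable_groups)
    for (v in vars) {
      mu <- config$true_effects[[v]]
      if (is.null(mu)) {
        stop("generate_meta_dataset: no true effect configured for ", v,
             call. = FALSE)
      }
      theta <- mu + stats::rnorm(1, 0, sqrt(config$tau2))
      n_obs <- sample(seq(config$obs_range[1], config$obs_range[2]), 1)
      for (o in seq_len(n_obs)) {
        n_t <- sample(seq(config$n_range[1], config$n_range[2]), 1)
        n_c <- sample(seq(config$n_range[1], config$n_range[2]), 1)
        mean_c <- stats::rlnorm(1, config$control_mean_meanlog,
                                config$control_mean_sdlog)
        noise_sd <- sqrt(config$cv^2 / n_t + config$cv^2 / n_c)
        mean_t <- mean_c * exp(theta + stats::rnorm(1, 0, noise_sd))
        sd_t <- config$cv * mean_t
        sd_c <- config$cv * mean_c
        u <- stats::runif(1)
        report <- if (u < config$sd_missing_fraction) "missing"
                  else if (u < config$sd_missing_fraction +
                             config$se_reported_fraction) "se" else "sd"
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sid, variable = v,
          mean_t = mean_t, mean_c = mean_c,
          sd_t = if (report == "sd") sd_t else NA_real_,
          sd_c = if (report == "sd") sd_c else NA_real_,
          se_t = if (report == "se") sd_t / sqrt(n_t) else NA_real_,
          se_c = if (report == "se") sd_c / sqrt(n_c) else NA_real_,
          n_t = n_t, n_c = n_c,
          recovery_type = recovery, ecosystem_raw = eco,
          duration_years = duration, latitude = lat, longitude = lon,
          mat = mat, map = map,
          .report = report, .sd_t_true = sd_t, .sd_c_true = sd_c,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)

  n_suppressed <- 0L
  if (!is.null(config$suppression)) {
    sup <- config$suppression
    sd_t_eff <- ifelse(is.na(tab$sd_t), tab$.sd_t_true, tab$sd_t)
    sd_c_eff <- ifelse(is.na(tab$sd_c), tab$.sd_c_true, tab$sd_c)
    lnrr <- log(tab$mean_t / tab$mean_c)
    v <- sd_t_eff^2 / (tab$n_t * tab$mean_t^2) +
      sd_c_eff^2 / (tab$n_c * tab$mean_c^2)
    z <- lnrr / sqrt(v)
    at_risk <- if (sup$side == "left") z < sup$z_threshold
               else z > sup$z_threshold
    drop <- at_risk & stats::runif(nrow(tab)) < sup$prob
    n_suppressed <- sum(drop)
    if (n_suppressed >= nrow(tab)) {
      stop("generate_meta_dataset: suppression removed every observation",
           call. = FALSE)
    }
    tab <- tab[!drop, , drop = FALSE]
  }

  truth <- list(
    true_effects = as.list(config$true_effects),
    tau2 = config$tau2,
    n_rows = nrow(tab),
    n_se_converted_cells = 2L * sum(tab$.report == "se"),
    n_sd_imputed_cells = 2L * sum(tab$.report == "missing"),
    n_suppressed = n_suppressed,
    seed = config$seed
  )
  tab <- tab[, obs_schema_columns(), drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, truth = truth, config = config),
            class = "meta_sim")
}

#' @export
print.meta_sim <- function(x, ...) {
  cat("<meta_sim> ", nrow(x$table), " observations, ",
      length(unique(x$table$study_id)), " studies (seed ",
      x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset and its truth sidecar
#'
#' @param sim a `meta_sim` from [generate_meta_dataset()].
#' @param csv_path output CSV (same schema [read_observations()] consumes).
#' @param truth_path optional JSON sidecar with the ground truth.
#' @return `sim`, invisibly.
#' @export
write_meta_dataset <- function(sim, csv_path, truth_path = NULL) {
  stopifnot(inherits(sim, "meta_sim"))
  utils::write.csv(sim$table, csv_path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(sim)
}

#' Simulate observations from a linear-Gaussian path model
#'
#' Draws `n` rows in topological order: residuals (including any specified
#' covariance pairs) are jointly normal, and each variable is the linear
#' combination of its parents plus its residual. By default residual
#' variances are chosen so every variable has unit total variance, which
#' makes the supplied coefficients standardized generating coefficients.
#'
#' @param spec a [path_spec()].
#' @param coefficients data.frame (`from`, `to`, `value`) or a named vector
#'   `"from->to" = value` of path coefficients; unlisted edges get 0.
#' @param n number of observations.
#' @param residual_variances optional named vector; `NULL` targets unit total
#'   variance per variable.
#' @param covariance_values optional named vector `"a~~b" = value` for the
#'   spec's covariance pairs (default 0).
#' @param seed RNG seed.
#' @return list of class `path_sim`: `data` (n x p matrix), `truth`
#'   (generating coefficients with their standardized values, implied
#'   covariance matrix, seed).
#' @export
generate_path_data <- function(spec, coefficients, n,
                               residual_variances = NULL,
                               covariance_values = NULL, seed = 1L) {
  stopifnot(inherits(spec, "path_spec"), n >= 2)
  vars <- spec$variables
  p <- length(vars)
  ne <- nrow(spec$edges)

  beta <- numeric(ne)
  if (is.data.frame(coefficients)) {
    key_spec <- paste(spec$edges$from, spec$edges$to, sep = "->")
    key_in <- paste(coefficients$from, coefficients$to, sep = "->")
    m <- match(key_spec, key_in)
    beta[!is.na(m)] <- coefficients$value[m[!is.na(m)]]
  } else {
    key_spec <- paste(spec$edges$from, spec$edges$to, sep = "->")
    m <- match(key_spec, names(coefficients))
    beta[!is.na(m)] <- coefficients[m[!is.na(m)]]
  }

  covs <- numeric(nrow(spec$covariances))
  if (!is.null(covariance_values) && length(covs)) {
    key_spec <- paste(spec$covariances$a, spec$covariances$b, sep = "~~")
    key_rev <- paste(spec$covariances$b, spec$covariances$a, sep = "~~")
    m <- match(key_spec, names(covariance_values))
    m2 <- match(key_rev, names(covariance_values))
    m[is.na(m)] <- m2[is.na(m)]
    covs[!is.na(m)] <- covariance_values[m[!is.na(m)]]
  }

  # residual variances: supplied, or solved for unit total variance in
  # topological order
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  for (i in seq_len(ne)) B[spec$edges$to[i], spec$edges$from[i]] <- beta[i]
  resid <- stats::setNames(rep(NA_real_, p), vars)
  if (!is.null(residual_variances)) {
    resid[names(residual_variances)] <- residual_variances
    if (anyNA(resid)) stop("generate_path_data: residual_variances must ",
                           "cover every variable", call. = FALSE)
    if (any(resid <= 0)) stop("generate_path_data: residual variances must ",
                              "be positive", call. = FALSE)
  } else {
    Gamma <- matrix(0, p, p, dimnames = list(vars, vars))
    for (v in spec$order) {
      parents <- spec$edges$from[spec$edges$to == v]
      if (!length(parents)) {
        resid[v] <- 1
        Gamma[v, v] <- 1
      } else {
        b <- B[v, parents]
        var_expl <- drop(t(b) %*% Gamma[parents, parents] %*% b)
        if (var_expl >= 1) {
          stop("generate_path_data: coefficients imply explained variance ",
               ">= 1 for ", v, "; supply residual_variances", call. = FALSE)
        }
        resid[v] <- 1 - var_expl
        Gamma[v, ] <- Gamma[, v] <- drop(Gamma[, parents, drop = FALSE] %*% b)
        Gamma[v, v] <- 1
      }
    }
  }

  theta <- c(beta, log(resid), covs)
  implied <- sem_implied(theta, spec)

  Psi <- implied$Psi
  if (any(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("generate_path_data: residual covariance matrix is not positive ",
         "definite", call. = FALSE)
  }
  set.seed(seed)
  E <- matrix(stats::rnorm(n * p), n, p) %*% chol(Psi)
  colnames(E) <- vars
  X <- matrix(0, n, p, dimnames = list(NULL, vars))
  for (v in spec$order) {
    parents <- spec$edges$from[spec$edges$to == v]
    X[, v] <- E[, v]
    if (length(parents)) {
      X[, v] <- X[, v] + X[, parents, drop = FALSE] %*% B[v, parents]
    }
  }

  sds <- sqrt(diag(implied$Sigma))
  truth_coef <- spec$edges
  truth_coef$value <- beta
  truth_coef$std <- beta * sds[truth_coef$from] / sds[truth_coef$to]
  structure(
    list(data = X,
         truth = list(coefficients = truth_coef,
                      residual_variances = resid,
                      covariances = covs,
                      Sigma = implied$Sigma, seed = seed)),
    class = "path_sim")
}
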