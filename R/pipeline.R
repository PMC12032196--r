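#' Configuration for a full analysis run
#'
#' @param input path to an observation CSV, or `NULL` to simulate.
#' @param simulate logical; defaults to `TRUE` exactly when `input` is
#'   `NULL`. Exactly one of input / simulate must be active.
#' @param sim_config a [meta_sim_config()] used in simulate mode; its seed is
#'   overridden by `seed`.
#' @param slices subgroup slices to compute in addition to the overall
#'   recovery-type comparison: any of `"ecosystem"`, `"duration"`.
#' @param alpha Egger screening threshold for trim-and-fill.
#' @param tf_estimator,tf_side trim-and-fill settings (see
#'   [trim_and_fill()]).
#' @param tau2_method heterogeneity estimator for pooling (`"DL"`/`"REML"`).
#' @param sem logical; fit the path model per recovery type.
#' @param sem_use `"pairwise"` or `"listwise"` covariance handling.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed governing all randomness in the run.
#' @param strict passed to [prepare_observations()] (default lenient).
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = is.null(input),
                       sim_config = meta_sim_config(),
                       slices = c("ecosystem", "duration"),
                       alpha = 0.05, tf_estimator = "L0", tf_side = "auto",
                       tau2_method = "DL", sem = TRUE,
                       sem_use = "pairwise",
                       out_dir = tempfile("restoremeta_run_"),
                       seed = 1L, strict = FALSE) {
  if (simulate == !is.null(input)) {
    stop("run_config: exactly one of `input` and `simulate` must be set",
         call. = FALSE)
  }
  sim_config$seed <- as.integer(seed)
  structure(
    list(input = input, simulate = simulate, sim_config = sim_config,
         slices = slices, alpha = alpha, tf_estimator = tf_estimator,
         tf_side = tf_side, tau2_method = tau2_method, sem = sem,
         sem_use = sem_use, out_dir = out_dir, seed = as.integer(seed),
         strict = strict),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments
#'   (nested `sim_config` keys mirror [meta_sim_config()]).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim_config
  y$sim_config <- if (is.null(sim_args)) meta_sim_config() else
    do.call(meta_sim_config, sim_args)
  do.call(run_config, y)
}

# panel letters for the soil-phosphorus relationship surface: eight x axes
# (biomass, plant diversity, bacterial diversity, fungal diversity; two
# metrics each) by two y axes
pipeline_panel_xvars <- function() {
  c("AGB", "BGB", "plant_richness", "plant_shannon",
    "bacteria_shannon", "bacteria_chao1", "fungi_shannon", "fungi_chao1")
}

# JSON drops names from named atomic vectors; store them as objects so the
# manifest round-trips losslessly
sim_config_for_manifest <- function(sc) {
  sc <- unclass(sc)
  for (f in c("true_effects", "ecosystem_probs", "duration_probs")) {
    sc[[f]] <- as.list(sc[[f]])
  }
  sc$variable_groups <- lapply(sc$variable_groups, function(g) {
    g$metrics <- as.list(g$metrics)
    g
  })
  sc
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline [", name, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full meta-analysis pipeline
#'
#' Orchestrates ingest (or simulation), effect-size computation,
#' subgroup pooling with recovery-type contrasts, publication-bias
#' diagnostics, soil-phosphorus relationship regressions, and path models,
#' writing a reproducible report bundle:
#' `effects.csv`, `pooled_summary.csv`, `bias_reports.csv`,
#' `relationships/` (per-panel pair CSVs plus `fits.csv`), `sem_fits.json`,
#' and `run_manifest.json`. Partial outputs are removed on failure.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`study_table`,
#'   `effects`, `pooled`, `bias`, `relationships`, `sem`, `manifest`,
#'   `paths`).
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  fresh <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  created <- character()
  on_fail <- function(e) {
    unlink(created)
    if (fresh) unlink(out, recursive = TRUE)
    stop(e)
  }
  withCallingHandlers({
    set.seed(config$seed)

    truth <- NULL
    if (config$simulate) {
      sim <- stage("simulate", generate_meta_dataset(config$sim_config))
      raw <- sim$table
      truth <- sim$truth
      src <- "simulated"
    } else {
      raw <- stage("ingest", read_observations(config$input))
      src <- config$input
    }
    tab <- stage("ingest", suppressWarnings(
      prepare_observations(raw, strict = config$strict)))
    tab <- stage("ingest", assign_subgroups(tab))
    effects <- stage("effects", compute_effects(tab))

    f_effects <- file.path(out, "effects.csv")
    utils::write.csv(effects, f_effects, row.names = FALSE)
    created <- c(created, f_effects)

    slice_cols <- c(overall = NA, ecosystem = "ecosystem",
                    duration = "duration_bin")
    wanted <- c("overall", intersect(config$slices,
                                     c("ecosystem", "duration")))
    pooled <- do.call(rbind, lapply(wanted, function(sl) {
      col <- slice_cols[[sl]]
      res <- stage("inference", recovery_type_summary(
        effects, slice = if (is.na(col)) NULL else col,
        tau2_method = config$tau2_method))
      res$slice <- sl
      res$slice_level <- if (is.na(col)) "all" else res[[col]]
      res[, setdiff(names(res), c("ecosystem", "duration_bin")),
          drop = FALSE]
    }))
    pooled$pct_change_rounded <- round(pooled$pct_change, 2)
    f_pooled <- file.path(out, "pooled_summary.csv")
    utils::write.csv(pooled, f_pooled, row.names = FALSE)
    created <- c(created, f_pooled)

    bias <- stage("publication_bias", bias_report(
      effects, by = "variable", alpha = config$alpha,
      side = config$tf_side, estimator = config$tf_estimator))
    f_bias <- file.path(out, "bias_reports.csv")
    utils::write.csv(bias, f_bias, row.names = FALSE)
    created <- c(created, f_bias)

    rel_dir <- file.path(out, "relationships")
    dir.create(rel_dir, showWarnings = FALSE)
    xvars <- intersect(pipeline_panel_xvars(), unique(effects$variable))
    rel <- stage("relationships", relationship_panels(
      effects, x_variables = as.list(stats::setNames(xvars, xvars))))
    if (nrow(rel)) {
      rel$panel_letter <- LETTERS[
        match(interaction(rel$x_variable, rel$y_variable, drop = TRUE),
              unique(interaction(rel$x_variable, rel$y_variable,
                                 drop = TRUE)))]
      for (letter in unique(rel$panel_letter)) {
        sub <- rel[rel$panel_letter == letter, , drop = FALSE]
        pairs <- do.call(rbind, sub$pairs)
        f <- file.path(rel_dir, sprintf("panel_%s_%s_vs_%s.csv", letter,
                                        sub$x_variable[1], sub$y_variable[1]))
        utils::write.csv(pairs, f, row.names = FALSE)
        created <- c(created, f)
      }
    }
    fits <- rel[, setdiff(names(rel), c("pairs", "band")), drop = FALSE]
    f_fits <- file.path(rel_dir, "fits.csv")
    utils::write.csv(fits, f_fits, row.names = FALSE)
    created <- c(created, f_fits)

    sem_out <- list()
    if (isTRUE(config$sem)) {
      spec <- default_path_spec()
      for (rt in c("restoration", "rehabilitation")) {
        sem_out[[rt]] <- tryCatch({
          M <- build_rr_matrix(effects, recovery_type = rt)
          inp <- sem_input(M, variables = spec$variables,
                           use = config$sem_use)
          fit <- fit_path_model(spec = spec, S = inp$S, n = inp$n)
          list(status = "ok", n = fit$n, chi2 = fit$chi2, df = fit$df,
               cmin_df = fit$cmin_df, rmsea = fit$rmsea, nfi = fit$nfi,
               cfi = fit$cfi, ifi = fit$ifi, accepted = fit$accepted,
               coefficients = fit$coefficients)
        }, error = function(e) {
          list(status = "not_estimable", reason = conditionMessage(e))
        })
      }
    }
    f_sem <- file.path(out, "sem_fits.json")
    jsonlite::write_json(sem_out, f_sem, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    created <- c(created, f_sem)

    manifest <- list(
      package_version = as.character(utils::packageVersion("restoremeta")),
      seed = config$seed,
      source = src,
      config = list(
        simulate = config$simulate, input = config$input,
        slices = config$slices, alpha = config$alpha,
        tf_estimator = config$tf_estimator, tf_side = config$tf_side,
        tau2_method = config$tau2_method, sem = config$sem,
        sem_use = config$sem_use, strict = config$strict,
        sim_config = if (config$simulate)
          sim_config_for_manifest(config$sim_config) else NULL),
      prep_log = as.list(tab$prep_log$counts),
      effects_md5 = unname(tools::md5sum(f_effects)),
      truth = truth
    )
    f_manifest <- file.path(out, "run_manifest.json")
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    created <- c(created, f_manifest)

    invisible(list(study_table = tab, effects = effects, pooled = pooled,
                   bias = bias, relationships = rel, sem = sem_out,
                   manifest = manifest,
                   paths = list(out_dir = out, effects = f_effects,
                                pooled = f_pooled, bias = f_bias,
                                relationships = rel_dir, sem = f_sem,
                                manifest = f_manifest)))
  }, error = on_fail)
}

#' Re-run an analysis from its manifest
#'
#' Rebuilds the run configuration recorded in a `run_manifest.json` (simulate
#' mode carries the full simulator configuration) and re-executes the
#' pipeline, which reproduces the original outputs bit-for-bit.
#'
#' @param manifest_path path to a `run_manifest.json`.
#' @param out_dir output directory for the re-run.
#' @return the [run_full_analysis()] result, invisibly.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  if (length(cfg$input) == 0) cfg$input <- NULL
  sim_config <- meta_sim_config()
  if (isTRUE(cfg$simulate)) {
    sc <- cfg$sim_config
    if (length(sc$suppression) == 0) sc$suppression <- NULL
    groups <- lapply(sc$variable_groups, function(g) {
      list(p = g$p, metrics = unlist(g$metrics), force = g$force)
    })
    sim_config <- meta_sim_config(
      n_studies = sc$n_studies, obs_range = unlist(sc$obs_range),
      true_effects = unlist(sc$true_effects), tau2 = sc$tau2, cv = sc$cv,
      se_reported_fraction = sc$se_reported_fraction,
      sd_missing_fraction = sc$sd_missing_fraction,
      restoration_fraction = sc$restoration_fraction,
      ecosystem_probs = unlist(sc$ecosystem_probs),
      duration_probs = unlist(sc$duration_probs),
      variable_groups = groups, n_range = unlist(sc$n_range),
      control_mean_meanlog = sc$control_mean_meanlog,
      control_mean_sdlog = sc$control_mean_sdlog,
      suppression = sc$suppression, seed = man$seed)
  }
  config <- run_config(
    input = cfg$input, simulate = isTRUE(cfg$simulate),
    sim_config = sim_config, slices = unlist(cfg$slices),
    alpha = cfg$alpha, tf_estimator = cfg$tf_estimator,
    tf_side = cfg$tf_side, tau2_method = cfg$tau2_method,
    sem = isTRUE(cfg$sem), sem_use = cfg$sem_use, out_dir = out_dir,
    seed = man$seed, strict = isTRUE(cfg$strict))
  run_full_analysis(config)
}
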