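#' Log response ratio
#'
#' The effect size used throughout: the natural log of the ratio of the
#' treatment-group mean to the control-group mean,
#' `lnRR = ln(mean_t) - ln(mean_c)`.
#'
#' @param mean_t,mean_c strictly positive group means (vectorised).
#' @return lnRR, dimensionless.
#' @export
#' @examples
#' compute_lnrr(2, 1) # log(2)
compute_lnrr <- function(mean_t, mean_c) {
  if (any(!is.finite(mean_t) | mean_t <= 0) ||
      any(!is.finite(mean_c) | mean_c <= 0)) {
    stop("compute_lnrr: means must be strictly positive", call. = FALSE)
  }
  log(mean_t) - log(mean_c)
}

#' Sampling variance of the log response ratio
#'
#' `v = sd_t^2 / (n_t * mean_t^2) + sd_c^2 / (n_c * mean_c^2)`, the standard
#' large-sample variance of lnRR.
#'
#' @param sd_t,sd_c non-negative standard deviations.
#' @param n_t,n_c positive sample sizes.
#' @param mean_t,mean_c strictly positive means.
#' @param var_floor optional positive floor substituted (with a warning) when
#'   both SDs are zero; by default such degenerate observations are an error
#'   because the inverse-variance weight would be undefined.
#' @return the variance `v` (vectorised).
#' @export
#' @examples
#' compute_variance(1, 4, 2, 1, 4, 2) # 0.125
compute_variance <- function(sd_t, n_t, mean_t, sd_c, n_c, mean_c,
                             var_floor = NULL) {
  if (any(!is.finite(mean_t) | mean_t <= 0) ||
      any(!is.finite(mean_c) | mean_c <= 0)) {
    stop("compute_variance: means must be strictly positive", call. = FALSE)
  }
  if (any(n_t < 1) || any(n_c < 1)) {
    stop("compute_variance: sample sizes must be >= 1", call. = FALSE)
  }
  if (any(sd_t < 0) || any(sd_c < 0)) {
    stop("compute_variance: standard deviations must be non-negative",
         call. = FALSE)
  }
  v <- sd_t^2 / (n_t * mean_t^2) + sd_c^2 / (n_c * mean_c^2)
  zero <- v <= 0
  if (any(zero)) {
    if (is.null(var_floor)) {
      stop("compute_variance: both SDs zero for ", sum(zero),
           " observation(s); weight undefined (set `var_floor` to proceed)",
           call. = FALSE)
    }
    stopifnot(var_floor > 0)
    warning("compute_variance: substituted var_floor = ", var_floor,
            " for ", sum(zero), " zero-variance observation(s)",
            call. = FALSE)
    v[zero] <- var_floor
  }
  v
}

#' Down-weight multiple observations of one variable within one study
#'
#' When a single study contributes several observations of the same variable,
#' each observation's inverse-variance weight `w = 1/v` is divided by the
#' number of observations of that variable in that study, so a study's total
#' influence does not grow with how finely it sliced its measurements.
#' Singleton groups are unchanged.
#'
#' @param records data.frame with at least `study_id`, `variable`, `w`.
#' @return the data.frame with a `w_adj` column added.
#' @export
adjust_weights <- function(records) {
  stopifnot(all(c("study_id", "variable", "w") %in% names(records)))
  if (any(!is.finite(records$w) | records$w <= 0)) {
    stop("adjust_weights: every weight must be positive and finite",
         call. = FALSE)
  }
  grp <- interaction(records$study_id, records$variable, drop = TRUE)
  records$w_adj <- records$w / as.numeric(ave(records$w, grp, FUN = length))
  records
}

#' Weighted mean effect size
#'
#' Pools per-observation log response ratios with their adjusted weights:
#' `sum(lnrr * w_adj) / sum(w_adj)`.
#'
#' @param lnrr numeric effect sizes.
#' @param w_adj positive weights, same length.
#' @return scalar weighted mean.
#' @export
pool_effects <- function(lnrr, w_adj) {
  if (!length(lnrr)) stop("pool_effects: empty subgroup", call. = FALSE)
  stopifnot(length(lnrr) == length(w_adj))
  if (any(!is.finite(w_adj) | w_adj <= 0)) {
    stop("pool_effects: weights must be positive", call. = FALSE)
  }
  sum(lnrr * w_adj) / sum(w_adj)
}

#' Back-transform a pooled log response ratio to a percentage change
#'
#' @param lnrr_bar pooled mean lnRR.
#' @return `(exp(lnrr_bar) - 1) * 100`, in percent.
#' @export
#' @examples
#' percent_change(log(2)) # 100
percent_change <- function(lnrr_bar) {
  stopifnot(all(is.finite(lnrr_bar)))
  (exp(lnrr_bar) - 1) * 100
}

#' Per-observation effect table
#'
#' Computes, for every observation in a prepared table, the log response
#' ratio, its sampling variance, the inverse-variance weight and the
#' within-study adjusted weight, carrying all subgroup labels through.
#'
#' @param table a `study_table` (ideally after [assign_subgroups()]).
#' @param var_floor see [compute_variance()].
#' @return data.frame with one row per observation: identifiers, subgroup
#'   labels, `lnrr`, `v`, `w`, `w_adj`.
#' @export
compute_effects <- function(table, var_floor = NULL) {
  stopifnot(inherits(table, "study_table"))
  obs <- table$observations
  keep <- intersect(
    c("row", "study_id", "variable", "recovery_type", "ecosystem_raw",
      "ecosystem", "duration_years", "duration_bin", "latitude", "longitude",
      "mat", "map", "n_t", "n_c"),
    names(obs))
  eff <- obs[, keep, drop = FALSE]
  eff$lnrr <- compute_lnrr(obs$mean_t, obs$mean_c)
  eff$v <- compute_variance(obs$sd_t, obs$n_t, obs$mean_t,
                            obs$sd_c, obs$n_c, obs$mean_c,
                            var_floor = var_floor)
  eff$w <- 1 / eff$v
  eff <- adjust_weights(eff)
  rownames(eff) <- NULL
  eff
}

# Pool one cell of observations sharing a variable. Observations from the
# same study share that study's true effect, so the weighted mean's variance
# has a between-study component at the study level in addition to the
# per-observation sampling variances:
#   Var = (tau2 * sum_g W_g^2 + sum_i w_i^2 v_i) / (sum_i w_i)^2
# with W_g the summed weight of study g. tau2 is estimated from the
# inverse-variance-collapsed study-level effects.
collapse_to_study <- function(lnrr, v, study_id) {
  w0 <- 1 / v
  g <- factor(study_id)
  list(yg = as.numeric(tapply(w0 * lnrr, g, sum) / tapply(w0, g, sum)),
       vg = as.numeric(1 / tapply(w0, g, sum)))
}

pool_cell <- function(lnrr, v, study_id, method = "fixed",
                      tau2_method = "DL", tau2 = NULL) {
  w0 <- 1 / v
  g <- factor(study_id)
  n_g <- as.numeric(ave(w0, g, FUN = length))
  if (is.null(tau2)) {
    # study-level collapsed effects for heterogeneity estimation
    st <- collapse_to_study(lnrr, v, study_id)
    tau2 <- if (nlevels(g) >= 2) {
      estimate_tau2(st$yg, st$vg, method = tau2_method)$tau2
    } else NA_real_
  }
  t2 <- if (is.na(tau2)) 0 else tau2
  w <- if (method == "random") 1 / (v + t2) else w0
  w_adj <- w / n_g
  est <- sum(w_adj * lnrr) / sum(w_adj)
  Wg <- tapply(w_adj, g, sum)
  se <- sqrt((t2 * sum(Wg^2) + sum(w_adj^2 * v)) / sum(w_adj)^2)
  list(estimate = est, se = se, tau2 = tau2, k = length(lnrr),
       k_studies = nlevels(g))
}

#' Pool effects within subgroup slices
#'
#' Splits an effect table by variable (and optionally a subgroup slice and
#' recovery type) and pools each cell with the adjusted weights, reporting the
#' weighted mean lnRR, its standard error, the normal-theory 95% CI, the
#' DerSimonian-Laird between-study variance, the percentage change, and a
#' CI-excludes-zero significance flag.
#'
#' @param effects effect table from [compute_effects()].
#' @param by character vector of grouping columns in addition to `variable`
#'   (e.g. `"recovery_type"`, `c("recovery_type", "ecosystem")`).
#' @param method pooling route: `"fixed_w_adj"` (weighted mean with the
#'   adjusted inverse-variance weights; default) or `"random"`
#'   (weights `1/(v + tau2)` divided by the within-study group size).
#'   Either way the standard error carries the between-study variance at the
#'   study level, since observations within a study share its true effect.
#' @param tau2_method heterogeneity estimator (`"DL"` or `"REML"`), applied
#'   to the inverse-variance-collapsed study-level effects.
#' @param tau2_pooling where the between-study variance is estimated:
#'   `"variable"` (default) shares one tau^2 across all cells of a variable,
#'   the assumption a moderator-style multilevel fit makes and much more
#'   stable when single cells hold only a handful of studies; `"cell"`
#'   estimates tau^2 per cell; `"global"` shares one tau^2 across the whole
#'   table.
#' @return data.frame with one row per cell: `k`, `k_studies`, `lnrr_bar`,
#'   `se`, `ci_low`, `ci_high`, `tau2`, `pct_change`, `significant`, plus a
#'   `method` column recording which route produced the estimate.
#' @export
pool_by_subgroup <- function(effects, by = "recovery_type",
                             method = c("fixed_w_adj", "random"),
                             tau2_method = c("DL", "REML"),
                             tau2_pooling = c("variable", "cell", "global")) {
  method <- match.arg(method)
  tau2_method <- match.arg(tau2_method)
  tau2_pooling <- match.arg(tau2_pooling)
  stopifnot(all(c("variable", "study_id", "lnrr", "v") %in% names(effects)),
            all(by %in% names(effects)))
  cols <- c("variable", by)
  key <- effects[, cols, drop = FALSE]
  idx <- split(seq_len(nrow(effects)), key, drop = TRUE, sep = "\r")

  # study-level collapsed effects per cell, for shared-tau2 estimation
  tau2_for_cell <- function(cells_idx) {
    ys <- numeric(); vs <- numeric(); gs <- character()
    for (j in seq_along(cells_idx)) {
      cell <- effects[cells_idx[[j]], , drop = FALSE]
      st <- collapse_to_study(cell$lnrr, cell$v, cell$study_id)
      ys <- c(ys, st$yg); vs <- c(vs, st$vg)
      gs <- c(gs, rep(names(cells_idx)[j], length(st$yg)))
    }
    estimate_tau2_grouped(ys, vs, gs, method = tau2_method)
  }
  tau2_map <- NULL
  if (tau2_pooling == "global") {
    tau2_map <- tau2_for_cell(idx)
  } else if (tau2_pooling == "variable") {
    cell_var <- vapply(idx, function(i) effects$variable[i[1]], "")
    tau2_map <- vapply(split(idx, cell_var), tau2_for_cell, 0)
  }

  out <- lapply(idx, function(i) {
    cell <- effects[i, , drop = FALSE]
    labels <- cell[1, cols, drop = FALSE]
    tau2_fixed <- switch(tau2_pooling,
                         cell = NULL,
                         global = tau2_map,
                         variable = tau2_map[[cell$variable[1]]])
    pc <- pool_cell(cell$lnrr, cell$v, cell$study_id,
                    method = if (method == "random") "random" else "fixed",
                    tau2_method = tau2_method, tau2 = tau2_fixed)
    k <- pc$k
    se <- if (k < 2) sqrt(cell$v) else pc$se  # descriptive: single obs
    ci_low <- pc$estimate - 1.96 * se
    ci_high <- pc$estimate + 1.96 * se
    cbind(labels, data.frame(
      k = k, k_studies = pc$k_studies, lnrr_bar = pc$estimate, se = se,
      ci_low = ci_low, ci_high = ci_high, tau2 = pc$tau2,
      pct_change = percent_change(pc$estimate),
      significant = (k >= 2) & (ci_low > 0 | ci_high < 0),
      method = if (method == "random") paste0("random_", tau2_method)
               else "fixed_w_adj",
      stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$variable), , drop = FALSE]
}
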