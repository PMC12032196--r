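#' Pair response ratios of two variables within studies
#'
#' Matches the log response ratios of two variables study-by-study within a
#' recovery type (inner join on `study_id`). When a study contributes several
#' observations of one variable, the within-study mean lnRR is used and the
#' collapse is recorded in the `collapsed` attribute.
#'
#' @param effects effect table from [compute_effects()].
#' @param x_variable,y_variable variable tokens for the x and y axes.
#' @param recovery_type `"restoration"` or `"rehabilitation"`, or `NULL` to
#'   pair across both types (matching then also requires equal
#'   recovery_type).
#' @return data.frame of pairs: `study_id`, `recovery_type`, `x_rr`, `y_rr`;
#'   zero rows (with a warning) when no studies overlap.
#' @export
pair_rrs <- function(effects, x_variable, y_variable, recovery_type = NULL) {
  stopifnot(all(c("study_id", "variable", "recovery_type", "lnrr")
                %in% names(effects)))
  eff <- effects
  if (!is.null(recovery_type)) {
    eff <- eff[eff$recovery_type == recovery_type, , drop = FALSE]
  }
  collapse <- function(token) {
    sub <- eff[eff$variable == token, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(study_id = character(), recovery_type = character(),
                        rr = numeric(), n_obs = integer(),
                        stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(lnrr ~ study_id + recovery_type, data = sub,
                            FUN = mean)
    cnt <- stats::aggregate(lnrr ~ study_id + recovery_type, data = sub,
                            FUN = length)
    agg$n_obs <- cnt$lnrr
    names(agg)[names(agg) == "lnrr"] <- "rr"
    agg
  }
  xs <- collapse(x_variable)
  ys <- collapse(y_variable)
  pairs <- merge(xs, ys, by = c("study_id", "recovery_type"),
                 suffixes = c("_x", "_y"))
  if (!nrow(pairs)) {
    warning("pair_rrs: no overlapping studies for ", x_variable, " vs ",
            y_variable, call. = FALSE)
    out <- data.frame(study_id = character(), recovery_type = character(),
                      x_rr = numeric(), y_rr = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "collapsed") <- 0L
    return(out)
  }
  out <- data.frame(study_id = pairs$study_id,
                    recovery_type = pairs$recovery_type,
                    x_rr = pairs$rr_x, y_rr = pairs$rr_y,
                    stringsAsFactors = FALSE)
  attr(out, "collapsed") <- sum(pairs$n_obs_x > 1) + sum(pairs$n_obs_y > 1)
  out
}

#' Ordinary least-squares fit of paired response ratios
#'
#' Unweighted simple linear regression of `y_rr` on `x_rr` with a two-sided
#' t-test on the slope and a pointwise 95% confidence band for the mean
#' response.
#'
#' @param pairs data.frame from [pair_rrs()] (or any data.frame with `x_rr`
#'   and `y_rr`), n >= 3.
#' @param band_points number of x positions at which to evaluate the band.
#' @return list of class `rr_regression`: `slope`, `intercept`, `se_slope`,
#'   `r2`, `p_slope`, `n`, and `ci_band` (data.frame `x`, `fit`, `lower`,
#'   `upper`).
#' @export
fit_linear <- function(pairs, band_points = 50L) {
  stopifnot(all(c("x_rr", "y_rr") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3) stop("fit_linear: need at least 3 pairs", call. = FALSE)
  if (stats::var(pairs$x_rr) <= .Machine$double.eps *
        max(abs(pairs$x_rr), 1)^2) {
    stop("fit_linear: zero variance in x", call. = FALSE)
  }
  fit <- stats::lm(y_rr ~ x_rr, data = pairs)
  sm <- summary(fit)
  # constant response: R^2 is 0/0 in the summary; define it (and the slope
  # test) degenerately rather than reporting floating-point noise
  tss <- sum((pairs$y_rr - mean(pairs$y_rr))^2)
  r2 <- if (tss <= .Machine$double.eps * max(abs(pairs$y_rr), 1)^2 * n) 0
        else sm$r.squared
  grid <- data.frame(x_rr = seq(min(pairs$x_rr), max(pairs$x_rr),
                                length.out = band_points))
  band <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = 0.95)
  structure(
    list(slope = unname(stats::coef(fit)["x_rr"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         se_slope = sm$coefficients["x_rr", "Std. Error"],
         r2 = r2,
         p_slope = sm$coefficients["x_rr", "Pr(>|t|)"],
         n = n,
         ci_band = data.frame(x = grid$x_rr, fit = band[, "fit"],
                              lower = band[, "lwr"], upper = band[, "upr"])),
    class = "rr_regression")
}

#' @export
print.rr_regression <- function(x, ...) {
  cat(sprintf("<rr_regression> n = %d: y = %.4f + %.4f x, r2 = %.3f, p(slope) = %.4g\n",
              x$n, x$intercept, x$slope, x$r2, x$p_slope))
  invisible(x)
}

#' Soil-phosphorus relationship panels
#'
#' Enumerates the regression surface relating soil total and available
#' phosphorus response ratios (y axes) to plant-biomass, plant-diversity,
#' bacterial-diversity and fungal-diversity response ratios (x axes), per
#' recovery type. Regressions always run with the soil phosphorus RR as the
#' response; panels with fewer than `min_n` pairs are reported without a fit.
#'
#' @param effects effect table from [compute_effects()].
#' @param x_variables named list of x-axis variable groups; the default
#'   mirrors the standard panel layout (biomass, plant diversity, bacterial
#'   diversity, fungal diversity).
#' @param y_variables y-axis tokens (default STP and SAP).
#' @param recovery_types recovery types to split by.
#' @param min_n minimum pairs for fitting (default 3).
#' @return data.frame with one row per panel: grouping labels, `n`, fit
#'   coefficients (NA when not estimable), plus `pairs` and `band` stored as
#'   list-columns for export.
#' @export
relationship_panels <- function(effects,
                                x_variables = list(
                                  biomass = c("AGB", "BGB"),
                                  plant_diversity = c("plant_richness",
                                                      "plant_shannon",
                                                      "plant_simpson"),
                                  bacterial_diversity = c("bacteria_shannon",
                                                          "bacteria_richness",
                                                          "bacteria_chao1"),
                                  fungal_diversity = c("fungi_shannon",
                                                       "fungi_richness",
                                                       "fungi_chao1")),
                                y_variables = c("STP", "SAP"),
                                recovery_types = c("restoration",
                                                   "rehabilitation"),
                                min_n = 3L) {
  panels <- list()
  panel_id <- 0L
  for (grp in names(x_variables)) {
    for (xv in x_variables[[grp]]) {
      for (yv in y_variables) {
        for (rt in recovery_types) {
          panel_id <- panel_id + 1L
          pr <- suppressWarnings(pair_rrs(effects, xv, yv, rt))
          row <- data.frame(
            panel = panel_id, x_group = grp, x_variable = xv,
            y_variable = yv, recovery_type = rt, n = nrow(pr),
            slope = NA_real_, intercept = NA_real_, se_slope = NA_real_,
            r2 = NA_real_, p_slope = NA_real_, stringsAsFactors = FALSE)
          band <- NULL
          if (nrow(pr) >= min_n && stats::var(pr$x_rr) > 0) {
            ft <- fit_linear(pr)
            row$slope <- ft$slope; row$intercept <- ft$intercept
            row$se_slope <- ft$se_slope; row$r2 <- ft$r2
            row$p_slope <- ft$p_slope
            band <- ft$ci_band
          }
          row$pairs <- I(list(pr))
          row$band <- I(list(band))
          panels[[panel_id]] <- row
        }
      }
    }
  }
  if (!length(panels)) {
    return(data.frame(panel = integer(), x_group = character(),
                      x_variable = character(), y_variable = character(),
                      recovery_type = character(), n = integer(),
                      slope = numeric(), intercept = numeric(),
                      se_slope = numeric(), r2 = numeric(),
                      p_slope = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, panels)
  rownames(res) <- NULL
  res
}
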