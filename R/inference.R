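#' Cochran's Q heterogeneity statistic
#'
#' @param lnrr numeric effect sizes (k >= 2).
#' @param v positive sampling variances.
#' @return list with `Q` and `df = k - 1`.
#' @export
cochran_q <- function(lnrr, v) {
  k <- length(lnrr)
  if (k < 2) stop("cochran_q: need at least 2 observations", call. = FALSE)
  stopifnot(length(v) == k, all(v > 0))
  w <- 1 / v
  mu_fe <- sum(w * lnrr) / sum(w)
  list(Q = sum(w * (lnrr - mu_fe)^2), df = k - 1L)
}

# restricted log-likelihood of the random-effects model at tau2
reml_ll <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

# Fisher-scoring REML iteration for tau2; returns list(tau2, converged, iter)
reml_tau2 <- function(y, v, tol = 1e-8, max_iter = 100L) {
  q <- cochran_q(y, v)
  w0 <- 1 / v
  c0 <- sum(w0) - sum(w0^2) / sum(w0)
  tau2 <- max(0, (q$Q - q$df) / c0)  # DL start
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    sw <- sum(w); sw2 <- sum(w^2); sw3 <- sum(w^3)
    mu <- sum(w * y) / sw
    # score of the restricted likelihood wrt tau2
    score <- 0.5 * (sum(w^2 * (y - mu)^2) - sw + sw2 / sw)
    info <- 0.5 * (sw2 - 2 * sw3 / sw + sw2^2 / sw^2)
    if (info <= 0) break
    step <- score / info
    tau2_new <- max(0, tau2 + step)
    if (abs(tau2_new - tau2) <= tol * (abs(tau2) + tol)) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  # boundary case: a zero estimate with negative score at 0 is converged
  if (!converged && tau2 == 0) {
    w <- 1 / v
    mu <- sum(w * y) / sum(w)
    if (0.5 * (sum(w^2 * (y - mu)^2) - sum(w) + sum(w^2) / sum(w)) <= 0) {
      converged <- TRUE
    }
  }
  list(tau2 = tau2, converged = converged, iter = iter)
}

#' Random-effects meta-analytic fit with between-study variance
#'
#' Estimates the between-study variance tau^2 by DerSimonian-Laird (closed
#' form, `max(0, (Q - df) / c)` with `c = sum(w) - sum(w^2)/sum(w)`) or by
#' REML (Fisher scoring on the restricted likelihood, relative tolerance
#' 1e-8, at most 100 iterations; non-convergence falls back to DL with a
#' warning and is flagged). The pooled estimate uses weights
#' `1/(v + tau2)`; the 95% CI uses the normal critical value 1.96.
#'
#' @param lnrr numeric effect sizes (k >= 2).
#' @param v positive sampling variances.
#' @param method `"DL"` or `"REML"`.
#' @return object of class `het_fit`: `tau2`, `method`, `Q`, `df`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `k`, `converged`.
#' @export
estimate_tau2 <- function(lnrr, v, method = c("DL", "REML")) {
  method <- match.arg(method)
  k <- length(lnrr)
  if (k < 2) stop("estimate_tau2: need at least 2 observations", call. = FALSE)
  stopifnot(length(v) == k, all(v > 0))
  q <- cochran_q(lnrr, v)
  converged <- TRUE
  if (method == "DL") {
    w <- 1 / v
    c0 <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q$Q - q$df) / c0)
  } else {
    fit <- reml_tau2(lnrr, v)
    if (!fit$converged) {
      warning("estimate_tau2: REML did not converge in 100 iterations; ",
              "falling back to DL", call. = FALSE)
      w <- 1 / v
      c0 <- sum(w) - sum(w^2) / sum(w)
      tau2 <- max(0, (q$Q - q$df) / c0)
      method <- "DL_fallback"
      converged <- FALSE
    } else {
      tau2 <- fit$tau2
    }
  }
  w_re <- 1 / (v + tau2)
  estimate <- sum(w_re * lnrr) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  structure(
    list(tau2 = tau2, method = method, Q = q$Q, df = q$df,
         estimate = estimate, se = se,
         ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
         k = k, converged = converged),
    class = "het_fit")
}

#' @export
print.het_fit <- function(x, ...) {
  cat(sprintf(
    "<het_fit> k = %d, tau2 = %.4g (%s), estimate = %.4f [%.4f, %.4f]\n",
    x$k, x$tau2, x$method, x$estimate, x$ci_low, x$ci_high))
  invisible(x)
}

#' Common between-study variance across subgroup cells
#'
#' Estimates a single tau^2 shared by several groups of study-level effects
#' (each group keeps its own mean), the assumption a moderator-style
#' multilevel meta-analysis makes. For `"DL"` the within-group Q statistics,
#' degrees of freedom and scale constants are summed before the
#' DerSimonian-Laird moment inversion; for `"REML"` the group means are
#' profiled out of a joint restricted likelihood maximised by Fisher scoring.
#'
#' @param y study-level effects.
#' @param v their sampling variances.
#' @param groups factor assigning effects to cells (each keeps its own mean).
#' @param method `"DL"` or `"REML"`.
#' @return tau^2 (non-negative scalar; 0 when no group has 2+ effects).
#' @export
estimate_tau2_grouped <- function(y, v, groups, method = c("DL", "REML")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(v), length(y) == length(groups), all(v > 0))
  groups <- factor(groups)
  idx <- split(seq_along(y), groups, drop = TRUE)
  idx <- idx[vapply(idx, length, 1L) >= 2]
  if (!length(idx)) return(0)
  if (method == "DL") {
    Q <- 0; df <- 0; cc <- 0
    for (i in idx) {
      w <- 1 / v[i]
      mu <- sum(w * y[i]) / sum(w)
      Q <- Q + sum(w * (y[i] - mu)^2)
      df <- df + length(i) - 1
      cc <- cc + sum(w) - sum(w^2) / sum(w)
    }
    return(max(0, (Q - df) / cc))
  }
  # grouped REML: sum group-wise scores and informations
  tau2 <- estimate_tau2_grouped(y, v, groups, "DL")
  for (iter in 1:100) {
    score <- 0; info <- 0
    for (i in idx) {
      w <- 1 / (v[i] + tau2)
      sw <- sum(w); sw2 <- sum(w^2); sw3 <- sum(w^3)
      mu <- sum(w * y[i]) / sw
      score <- score + 0.5 * (sum(w^2 * (y[i] - mu)^2) - sw + sw2 / sw)
      info <- info + 0.5 * (sw2 - 2 * sw3 / sw + sw2^2 / sw^2)
    }
    if (info <= 0) break
    tau2_new <- max(0, tau2 + score / info)
    if (abs(tau2_new - tau2) <= 1e-8 * (abs(tau2) + 1e-8)) {
      return(tau2_new)
    }
    tau2 <- tau2_new
  }
  tau2
}

#' Significance by the 95% CI rule
#'
#' An effect is declared significant when its 95% confidence interval does
#' not overlap zero.
#'
#' @param fit a `het_fit`, or any list with `ci_low` and `ci_high`.
#' @return logical flag.
#' @export
significance_by_ci <- function(fit) {
  stopifnot(!is.null(fit$ci_low), !is.null(fit$ci_high))
  fit$ci_low > 0 || fit$ci_high < 0
}

p_to_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Contrast two subgroup fits
#'
#' Two-sided z-test on the difference of two independently estimated pooled
#' effects (e.g. restoration vs rehabilitation for one variable):
#' `z = (est_a - est_b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param fit_a,fit_b `het_fit` objects (or lists with `estimate` and `se`).
#' @param label_a,label_b optional group labels.
#' @return list of class `subgroup_contrast`: `diff`, `se_diff`, `z`, `p`,
#'   `stars`.
#' @export
contrast_subgroups <- function(fit_a, fit_b,
                               label_a = "a", label_b = "b") {
  if (is.null(fit_a$estimate) || is.null(fit_b$estimate)) {
    stop("contrast_subgroups: both groups need a valid fit", call. = FALSE)
  }
  se_diff <- sqrt(fit_a$se^2 + fit_b$se^2)
  diff <- fit_a$estimate - fit_b$estimate
  z <- diff / se_diff
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(group_a = label_a, group_b = label_b, diff = diff,
         se_diff = se_diff, z = z, p = p, stars = p_to_stars(p)),
    class = "subgroup_contrast")
}

#' @export
print.subgroup_contrast <- function(x, ...) {
  cat(sprintf("<subgroup_contrast> %s vs %s: diff = %.4f (se %.4f), z = %.2f, p = %.4g %s\n",
              x$group_a, x$group_b, x$diff, x$se_diff, x$z, x$p, x$stars))
  invisible(x)
}

#' Per-variable recovery-type summary with contrasts
#'
#' Builds the forest-plot-shaped summary: for each variable (within an
#' optional extra slice such as ecosystem or duration bin), a random-effects
#' fit per recovery type, the percentage change, and the z-contrast between
#' restoration and rehabilitation with significance stars. Cells with fewer
#' than two observations are reported descriptively (pooled mean only, no
#' contrast) and flagged.
#'
#' @param effects effect table from [compute_effects()].
#' @param slice optional extra grouping column (`"ecosystem"` or
#'   `"duration_bin"`), or `NULL` for the overall comparison.
#' @param tau2_method heterogeneity estimator, `"DL"` (default) or `"REML"`.
#' @param tau2_pooling see [pool_by_subgroup()]; default shares tau^2 across
#'   the cells of each variable.
#' @param adjust_p optional multiple-testing correction for the contrast
#'   p-values (`"none"`, default, or `"BH"`).
#' @return data.frame with one row per variable x slice-level x recovery type
#'   and contrast columns (`contrast_p`, `stars`) repeated within the pair.
#' @export
recovery_type_summary <- function(effects, slice = NULL,
                                  tau2_method = c("DL", "REML"),
                                  tau2_pooling = "variable",
                                  adjust_p = c("none", "BH")) {
  tau2_method <- match.arg(tau2_method)
  adjust_p <- match.arg(adjust_p)
  by <- c("recovery_type", slice)
  pooled <- pool_by_subgroup(effects, by = by, method = "random",
                             tau2_method = tau2_method,
                             tau2_pooling = tau2_pooling)
  slice_col <- if (is.null(slice)) NULL else slice
  key_cols <- c("variable", slice_col)
  keys <- unique(pooled[, key_cols, drop = FALSE])
  pooled$contrast_p <- NA_real_
  pooled$stars <- NA_character_
  pooled$descriptive <- pooled$k < 2
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(pooled))
    for (col in key_cols) sel <- sel & pooled[[col]] == keys[i, col]
    cell <- pooled[sel, , drop = FALSE]
    a <- cell[cell$recovery_type == "restoration" & cell$k >= 2, , drop = FALSE]
    b <- cell[cell$recovery_type == "rehabilitation" & cell$k >= 2, , drop = FALSE]
    if (nrow(a) == 1 && nrow(b) == 1) {
      ct <- contrast_subgroups(
        list(estimate = a$lnrr_bar, se = a$se),
        list(estimate = b$lnrr_bar, se = b$se),
        "restoration", "rehabilitation")
      pooled$contrast_p[sel] <- ct$p
    }
  }
  if (adjust_p == "BH") {
    # one correction across the distinct contrasts, not the duplicated rows
    key_id <- interaction(pooled[, key_cols, drop = FALSE], drop = TRUE)
    first <- !duplicated(key_id)
    adj <- stats::p.adjust(pooled$contrast_p[first], method = "BH")
    pooled$contrast_p <- adj[match(key_id, key_id[first])]
  }
  pooled$stars <- ifelse(is.na(pooled$contrast_p), NA_character_,
                         p_to_stars(pooled$contrast_p))
  pooled
}
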