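#' Specify an acyclic path model over observed variables
#'
#' A path specification is a directed acyclic graph over observed variables
#' plus an optional set of unordered variable pairs allowed to covary
#' (exogenous covariances or residual covariances between endogenous
#' variables).
#'
#' @param variables character vector of variable names (order fixes the
#'   covariance-matrix layout).
#' @param edges two-column data.frame or matrix of directed edges
#'   (`from`, `to`).
#' @param covariances optional two-column data.frame or matrix of unordered
#'   pairs allowed to covary.
#' @return object of class `path_spec`.
#' @export
path_spec <- function(variables, edges, covariances = NULL) {
  variables <- as.character(variables)
  stopifnot(!anyDuplicated(variables))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  bad <- setdiff(unique(c(edges$from, edges$to)), variables)
  if (length(bad)) {
    stop("path_spec: edge endpoint(s) not declared: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(covariances)) {
    covariances <- as.data.frame(covariances, stringsAsFactors = FALSE)
    names(covariances) <- c("a", "b")
    covariances$a <- as.character(covariances$a)
    covariances$b <- as.character(covariances$b)
    bad <- setdiff(unique(c(covariances$a, covariances$b)), variables)
    if (length(bad)) {
      stop("path_spec: covariance endpoint(s) not declared: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(covariances$a == covariances$b)) {
      stop("path_spec: a covariance pair must join two distinct variables",
           call. = FALSE)
    }
  } else {
    covariances <- data.frame(a = character(), b = character(),
                              stringsAsFactors = FALSE)
  }
  order <- topological_order(variables, edges)  # errors if cyclic
  structure(
    list(variables = variables, edges = edges, covariances = covariances,
         order = order),
    class = "path_spec")
}

# Kahn topological sort; stops on cycles
topological_order <- function(variables, edges) {
  indeg <- stats::setNames(integer(length(variables)), variables)
  for (to in edges$to) indeg[to] <- indeg[to] + 1L
  queue <- names(indeg)[indeg == 0L]
  out <- character()
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    out <- c(out, nd)
    kids <- edges$to[edges$from == nd]
    for (kid in kids) {
      indeg[kid] <- indeg[kid] - 1L
      if (indeg[kid] == 0L) queue <- c(queue, kid)
    }
  }
  if (length(out) != length(variables)) {
    stop("path_spec: the edge set contains a cycle", call. = FALSE)
  }
  out
}

#' @export
print.path_spec <- function(x, ...) {
  cat("<path_spec> ", length(x$variables), " variables, ",
      nrow(x$edges), " directed edges, ", nrow(x$covariances),
      " covariance pair(s)\n", sep = "")
  invisible(x)
}

#' Default recovery path model
#'
#' The standard model relating climate to soil phosphorus through vegetation
#' and microbial channels: mean annual temperature and precipitation predict
#' above- and belowground biomass and plant, bacterial and fungal diversity;
#' plant diversity additionally predicts the two microbial diversities; all
#' five mediators predict soil total and available phosphorus. MAT and MAP
#' covary; STP and SAP share a residual covariance.
#'
#' @return a `path_spec`.
#' @export
default_path_spec <- function() {
  mediators <- c("AGB", "BGB", "plant_diversity",
                 "bacteria_diversity", "fungi_diversity")
  edges <- rbind(
    expand.grid(from = c("mat", "map"), to = mediators,
                stringsAsFactors = FALSE),
    data.frame(from = "plant_diversity",
               to = c("bacteria_diversity", "fungi_diversity"),
               stringsAsFactors = FALSE),
    expand.grid(from = mediators, to = c("STP", "SAP"),
                stringsAsFactors = FALSE))
  path_spec(
    variables = c("mat", "map", mediators, "STP", "SAP"),
    edges = edges,
    covariances = data.frame(a = c("mat", "STP"), b = c("map", "SAP"),
                             stringsAsFactors = FALSE))
}

# parameter bookkeeping for the covariance-structure model
# theta = (beta per edge, log variance per variable, covariance per pair)
sem_implied <- function(theta, spec) {
  p <- length(spec$variables)
  ne <- nrow(spec$edges)
  nc <- nrow(spec$covariances)
  B <- matrix(0, p, p, dimnames = list(spec$variables, spec$variables))
  if (ne) {
    for (i in seq_len(ne)) {
      B[spec$edges$to[i], spec$edges$from[i]] <- theta[i]
    }
  }
  Psi <- diag(exp(theta[ne + seq_len(p)]), p)
  dimnames(Psi) <- dimnames(B)
  if (nc) {
    for (i in seq_len(nc)) {
      a <- spec$covariances$a[i]; b <- spec$covariances$b[i]
      Psi[a, b] <- Psi[b, a] <- theta[ne + p + i]
    }
  }
  IB <- diag(p) - B
  IBi <- solve(IB)
  Sigma <- IBi %*% Psi %*% t(IBi)
  list(Sigma = (Sigma + t(Sigma)) / 2, B = B, Psi = Psi)
}

sem_discrepancy <- function(theta, spec, S, logdet_S) {
  p <- nrow(S)
  Sigma <- tryCatch(sem_implied(theta, spec)$Sigma, error = function(e) NULL)
  if (is.null(Sigma)) return(1e10)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  f <- logdet + tr - logdet_S - p
  if (!is.finite(f)) 1e10 else f
}

# regression-based start values from S in topological order
sem_start <- function(spec, S) {
  vars <- spec$variables
  ne <- nrow(spec$edges)
  p <- length(vars)
  beta <- numeric(ne)
  resid <- diag(S)
  for (v in vars) {
    parents <- spec$edges$from[spec$edges$to == v]
    if (!length(parents)) next
    Sp <- S[parents, parents, drop = FALSE]
    b <- tryCatch(solve(Sp, S[parents, v]), error = function(e)
      rep(0, length(parents)))
    idx <- which(spec$edges$to == v)
    beta[idx] <- b[match(spec$edges$from[idx], parents)]
    rv <- S[v, v] - sum(S[v, parents] * b)
    resid[v] <- max(rv, 0.05 * S[v, v])
  }
  covs <- numeric(nrow(spec$covariances))
  if (length(covs)) {
    for (i in seq_along(covs)) {
      covs[i] <- 0.5 * S[spec$covariances$a[i], spec$covariances$b[i]]
    }
  }
  c(beta, log(resid), covs)
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the maximum-likelihood covariance-structure discrepancy
#' `F(theta) = ln|Sigma(theta)| + tr(S Sigma^-1) - ln|S| - p` over the free
#' parameters (path coefficients, variances, covariance pairs) by BFGS with
#' a regression-based start plus random restarts. The model chi-square is
#' `(n - 1) * F_min`; fit indices compare against the independence baseline
#' (all covariances zero, variances free).
#'
#' @param data numeric matrix/data.frame of observations (columns named as in
#'   the spec), or `NULL` when `S` and `n` are given directly.
#' @param spec a [path_spec()].
#' @param S covariance matrix (used when `data` is `NULL`).
#' @param n sample size (required with `S`); must exceed the number of
#'   variables.
#' @param restarts number of random restarts around the regression start
#'   (default 10).
#' @param tol convergence tolerance passed to the optimizer (default 1e-8).
#' @return object of class `path_model_fit`: `coefficients` (per-edge
#'   unstandardized and standardized estimates with SEs and p-values),
#'   `covariances`, `chi2`, `df`, `cmin_df`, `rmsea`, `nfi`, `cfi`, `ifi`,
#'   `n`, `accepted`, `acceptance`, `implied`, `converged`.
#' @export
fit_path_model <- function(data = NULL, spec, S = NULL, n = NULL,
                           restarts = 10L, tol = 1e-8) {
  stopifnot(inherits(spec, "path_spec"))
  vars <- spec$variables
  if (!is.null(data)) {
    data <- as.matrix(data[, vars, drop = FALSE])
    if (anyNA(data)) stop("fit_path_model: `data` contains missing values; ",
                          "build a covariance matrix explicitly", call. = FALSE)
    n <- nrow(data)
    S <- stats::cov(data)
  }
  if (is.null(S) || is.null(n)) {
    stop("fit_path_model: supply `data` or both `S` and `n`", call. = FALSE)
  }
  S <- as.matrix(S)[vars, vars]
  p <- length(vars)
  if (n <= p) stop("fit_path_model: n must exceed the number of variables",
                   call. = FALSE)
  ch_S <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch_S)) {
    stop("fit_path_model: covariance matrix is not positive definite",
         call. = FALSE)
  }
  logdet_S <- 2 * sum(log(diag(ch_S)))

  start <- sem_start(spec, S)
  npar <- length(start)
  df <- p * (p + 1) / 2 - npar
  if (df < 0) stop("fit_path_model: model has more parameters than moments",
                   call. = FALSE)

  obj <- function(th) sem_discrepancy(th, spec, S, logdet_S)
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    th0 <- if (r == 1) start else
      start + stats::rnorm(npar, sd = 0.2 * pmax(abs(start), 0.2))
    fit <- tryCatch(
      stats::optim(th0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = tol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("fit_path_model: optimizer failed across all restarts",
         call. = FALSE)
  }
  # polish + Hessian at the optimum
  final <- stats::optim(best$par, obj, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = tol))
  if (final$value > best$value) final <- c(best, list(hessian = NULL))
  theta <- final$par
  f_min <- max(final$value, 0)
  chi2 <- (n - 1) * f_min

  acov <- NULL
  if (!is.null(final$hessian)) {
    hinv <- tryCatch(solve(final$hessian), error = function(e) NULL)
    if (!is.null(hinv)) acov <- (2 / (n - 1)) * hinv
  }
  se_theta <- if (is.null(acov)) rep(NA_real_, npar) else
    sqrt(pmax(diag(acov), 0))

  implied <- sem_implied(theta, spec)
  sds <- sqrt(diag(implied$Sigma))
  names(sds) <- vars
  ne <- nrow(spec$edges)
  coefs <- spec$edges
  if (ne) {
    coefs$estimate <- theta[seq_len(ne)]
    coefs$se <- se_theta[seq_len(ne)]
    coefs$z <- coefs$estimate / coefs$se
    coefs$p <- 2 * stats::pnorm(-abs(coefs$z))
    coefs$std <- coefs$estimate * sds[coefs$from] / sds[coefs$to]
  } else {
    coefs$estimate <- coefs$se <- coefs$z <- coefs$p <- coefs$std <- numeric(0)
  }
  covs <- spec$covariances
  nc <- nrow(covs)
  if (nc) {
    covs$estimate <- theta[ne + p + seq_len(nc)]
    covs$se <- se_theta[ne + p + seq_len(nc)]
    covs$z <- covs$estimate / covs$se
    covs$p <- 2 * stats::pnorm(-abs(covs$z))
    covs$std <- implied$Psi[cbind(covs$a, covs$b)] /
      sqrt(implied$Psi[cbind(covs$a, covs$a)] *
             implied$Psi[cbind(covs$b, covs$b)])
  } else {
    covs$estimate <- covs$se <- covs$z <- covs$p <- covs$std <- numeric(0)
  }

  # independence baseline: diagonal Sigma with free variances
  f_base <- sum(log(diag(S))) - logdet_S
  chi2_base <- (n - 1) * f_base
  df_base <- p * (p - 1) / 2
  idx <- fit_indices(chi2, df, chi2_base, df_base, n)
  acc <- evaluate_acceptance(idx)

  structure(
    c(list(coefficients = coefs, covariances = covs,
           variances = stats::setNames(exp(theta[ne + seq_len(p)]), vars),
           chi2 = chi2, df = df, chi2_baseline = chi2_base,
           df_baseline = df_base, n = n, f_min = f_min,
           implied = implied$Sigma, S = S,
           accepted = acc$accepted, acceptance = acc,
           converged = final$convergence == 0),
      idx),
    class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("<path_model_fit> n = %d, chi2 = %.3f on %d df (chi2/df = %.2f)\n",
              x$n, x$chi2, x$df, x$cmin_df))
  cat(sprintf("  RMSEA = %.3f, NFI = %.3f, CFI = %.3f, IFI = %.3f -> %s\n",
              x$rmsea, x$nfi, x$cfi, x$ifi,
              if (x$accepted) "accepted" else "rejected"))
  print(x$coefficients[, c("from", "to", "estimate", "std", "p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Goodness-of-fit indices for a covariance-structure model
#'
#' @param chi2 model chi-square.
#' @param df model degrees of freedom.
#' @param chi2_baseline,df_baseline chi-square and df of the independence
#'   baseline model.
#' @param n sample size (>= 2).
#' @return list with `rmsea`, `cmin_df`, `nfi`, `cfi`, `ifi`.
#' @export
#' @examples
#' fit_indices(50, 10, 100, 15, 101) # rmsea = 0.2
fit_indices <- function(chi2, df, chi2_baseline, df_baseline, n) {
  stopifnot(n >= 2, df >= 0, df_baseline >= df, chi2 >= 0)
  if (chi2_baseline <= 0) {
    stop("fit_indices: degenerate baseline (chi2_baseline = 0)",
         call. = FALSE)
  }
  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  cmin_df <- if (df == 0) 0 else chi2 / df
  nfi <- (chi2_baseline - chi2) / chi2_baseline
  denom_cfi <- max(chi2_baseline - df_baseline, chi2 - df, 0)
  cfi <- if (denom_cfi <= 0) 1 else 1 - max(chi2 - df, 0) / denom_cfi
  denom_ifi <- chi2_baseline - df
  ifi <- if (denom_ifi <= 0) 1 else (chi2_baseline - chi2) / denom_ifi
  list(rmsea = rmsea, cmin_df = cmin_df, nfi = nfi, cfi = cfi, ifi = ifi)
}

#' Apply the model-acceptance rule
#'
#' A fit is accepted when RMSEA < 0.08, chi2/df lies in [0, 2], and at least
#' one of NFI, CFI, IFI exceeds 0.9. RMSEA above 0.1 is additionally noted as
#' indicating a poor fit, and RMSEA below 0.05 as excellent.
#'
#' @param fit a `path_model_fit` or any list with `rmsea`, `cmin_df`, `nfi`,
#'   `cfi`, `ifi`.
#' @return list with `accepted` (logical), `checks` (named logicals for the
#'   three criteria) and `note`.
#' @export
evaluate_acceptance <- function(fit) {
  checks <- c(
    rmsea = fit$rmsea < 0.08,
    cmin_df = fit$cmin_df >= 0 && fit$cmin_df <= 2,
    comparative = fit$nfi > 0.9 || fit$cfi > 0.9 || fit$ifi > 0.9
  )
  note <- if (fit$rmsea > 0.1) "rmsea above 0.1 indicates a poor model fit"
          else if (fit$rmsea < 0.05) "rmsea below 0.05 indicates an excellent fit"
          else ""
  list(accepted = all(checks), checks = checks, note = note)
}

#' Per-study response-ratio matrix for path modelling
#'
#' Collapses an effect table to one row per study within a recovery type:
#' mean lnRR per directly used variable (AGB, BGB, STP, SAP), observed
#' composites for plant, bacterial and fungal diversity (the mean of the
#' study's available diversity-metric lnRRs), and the study-level climate
#' covariates. Cells a study did not measure are `NA`.
#'
#' @param effects effect table from [compute_effects()] (needs `mat`, `map`
#'   columns carried through).
#' @param recovery_type `"restoration"`, `"rehabilitation"`, or `NULL` for
#'   all studies.
#' @param composites named list mapping composite names to the diversity
#'   tokens averaged into them.
#' @return numeric matrix, rows = studies, columns = the nine model
#'   variables, with an attribute `composite_log` counting contributing
#'   metrics per composite.
#' @export
build_rr_matrix <- function(effects, recovery_type = NULL,
                            composites = list(
                              plant_diversity = c("plant_richness",
                                                  "plant_shannon",
                                                  "plant_simpson"),
                              bacteria_diversity = c("bacteria_shannon",
                                                     "bacteria_richness",
                                                     "bacteria_chao1"),
                              fungi_diversity = c("fungi_shannon",
                                                  "fungi_richness",
                                                  "fungi_chao1"))) {
  eff <- effects
  if (!is.null(recovery_type)) {
    eff <- eff[eff$recovery_type == recovery_type, , drop = FALSE]
  }
  studies <- sort(unique(eff$study_id))
  direct <- c("AGB", "BGB", "STP", "SAP")
  out_vars <- c("mat", "map", direct[1:2], names(composites), direct[3:4])
  M <- matrix(NA_real_, length(studies), length(out_vars),
              dimnames = list(studies, out_vars))
  study_mean <- function(sub, var) {
    x <- sub$lnrr[sub$variable %in% var]
    if (length(x)) mean(x) else NA_real_
  }
  n_contrib <- stats::setNames(integer(length(composites)), names(composites))
  for (s in studies) {
    sub <- eff[eff$study_id == s, , drop = FALSE]
    M[s, "mat"] <- mean(sub$mat, na.rm = TRUE)
    M[s, "map"] <- mean(sub$map, na.rm = TRUE)
    for (dv in direct) M[s, dv] <- study_mean(sub, dv)
    for (cmp in names(composites)) {
      toks <- composites[[cmp]]
      M[s, cmp] <- study_mean(sub, toks)
      n_contrib[cmp] <- n_contrib[cmp] +
        length(unique(sub$variable[sub$variable %in% toks]))
    }
  }
  M[is.nan(M)] <- NA_real_
  attr(M, "composite_log") <- n_contrib
  M
}

#' Covariance input for the path model from an incomplete matrix
#'
#' Builds the covariance matrix and effective sample size from a per-study
#' matrix with missing cells, using pairwise-complete covariance with `n`
#' set to the minimum pairwise count (conservative) or listwise deletion.
#'
#' @param M matrix from [build_rr_matrix()].
#' @param variables columns to keep (default all).
#' @param use `"pairwise"` (default) or `"listwise"`.
#' @return list with `S`, `n`, and `pairwise_n` (matrix of pairwise counts).
#' @export
sem_input <- function(M, variables = colnames(M),
                      use = c("pairwise", "listwise")) {
  use <- match.arg(use)
  M <- M[, variables, drop = FALSE]
  if (use == "listwise") {
    M <- M[stats::complete.cases(M), , drop = FALSE]
    return(list(S = stats::cov(M), n = nrow(M), pairwise_n = NULL))
  }
  obs <- !is.na(M)
  pairwise_n <- crossprod(obs)
  if (any(pairwise_n < 2)) {
    stop("sem_input: some variable pairs share fewer than 2 studies; ",
         "insufficient data for a pairwise covariance", call. = FALSE)
  }
  S <- stats::cov(M, use = "pairwise.complete.obs")
  list(S = S, n = min(pairwise_n), pairwise_n = pairwise_n)
}
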