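#' Controlled vocabulary of response variables
#'
#' The registry of response-variable tokens recognised by the ingest layer:
#' plant biomass and diversity metrics, soil phosphorus pools, microbial
#' alpha-diversity metrics, and the relative abundances of twelve major
#' bacterial and fungal phyla. The registry is extensible: pass extra tokens
#' to admit additional variables without touching package code.
#'
#' @param extra character vector of additional variable tokens to admit.
#' @return Character vector of admissible `variable` tokens.
#' @export
#' @examples
#' variable_registry()
#' variable_registry(extra = "soil_organic_p")
variable_registry <- function(extra = character()) {
  core <- c(
    "AGB", "BGB", "LB", "coverage",
    "plant_richness", "plant_shannon", "plant_simpson",
    "STP", "SAP", "MBP",
    "bacteria_shannon", "bacteria_richness", "bacteria_chao1",
    "fungi_shannon", "fungi_richness", "fungi_chao1"
  )
  phyla <- c(
    "proteobacteria", "actinobacteria", "acidobacteria",
    "firmicutes", "bacteroidetes", "gemmatimonadetes",
    "ascomycota", "basidiomycota", "mortierellomycota",
    "glomeromycota", "rozellomycota", "chytridiomycota"
  )
  unique(c(core, phyla, as.character(extra)))
}

# canonical column order of the observation schema
obs_schema_columns <- function() {
  c("study_id", "variable", "mean_t", "mean_c", "sd_t", "sd_c",
    "se_t", "se_c", "n_t", "n_c", "recovery_type", "ecosystem_raw",
    "duration_years", "latitude", "longitude", "mat", "map")
}

#' Convert a standard error to a standard deviation
#'
#' @param se non-negative standard error.
#' @param n positive integer sample size.
#' @return `se * sqrt(n)`, vectorised.
#' @export
#' @examples
#' se_to_sd(2, 9) # 6
se_to_sd <- function(se, n) {
  if (any(!is.finite(n) | n < 1)) {
    stop("se_to_sd: sample size `n` must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(se) | se < 0)) {
    stop("se_to_sd: `se` must be non-negative", call. = FALSE)
  }
  se * sqrt(n)
}

#' Impute a missing standard deviation as one tenth of the mean
#'
#' Fallback used when a study reports neither SD nor SE for a group: the SD
#' is approximated as mean/10 (a 10% coefficient of variation).
#'
#' @param mean strictly positive group mean.
#' @return `mean / 10`, vectorised.
#' @export
#' @examples
#' impute_sd(50) # 5
impute_sd <- function(mean) {
  if (any(!is.finite(mean) | mean <= 0)) {
    stop("impute_sd: `mean` must be strictly positive", call. = FALSE)
  }
  mean / 10
}

#' Read a raw observation table from CSV
#'
#' Reads a UTF-8 CSV in the long observation format (one treatment/control
#' comparison per row). Missing values may be empty cells or "NA". A schema
#' mapping can rename non-canonical column headers.
#'
#' @param path path to the CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(mean_t = "treatment_mean")`.
#' @return A raw `data.frame`; validation happens in
#'   [prepare_observations()].
#' @export
read_observations <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("read_observations: schema maps `", canonical, "` to `", src,
             "` but that column is absent", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  attr(raw, "source_path") <- path
  raw
}

# coerce one column to numeric; cells that were non-empty but fail to parse
# are schema errors naming the offending rows
coerce_numeric_col <- function(x, col, rows) {
  if (is.numeric(x)) return(as.numeric(x))
  chr <- trimws(as.character(x))
  chr[chr %in% c("", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(chr))
  bad <- which(!is.na(chr) & is.na(out))
  if (length(bad)) {
    stop("prepare_observations: malformed numeric in column `", col,
         "`, row(s) ", paste(rows[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Validate and normalise a raw observation table
#'
#' Applies the data-preparation rules for response-ratio meta-analysis:
#' \itemize{
#'   \item if a group has an SD it is used as-is (a simultaneously reported
#'     SE is ignored and logged);
#'   \item an SD absent but SE present is converted via [se_to_sd()];
#'   \item an SD still missing afterwards is imputed via [impute_sd()]
#'     (mean/10);
#'   \item rows with non-positive or missing means, or missing/invalid sample
#'     sizes, are rejected (`strict = TRUE`) or dropped with a logged warning
#'     (`strict = FALSE`), since the log response ratio requires strictly
#'     positive means.
#' }
#' Every transformation is recorded in the returned `prep_log` with row
#' provenance. The operation is idempotent: re-preparing a prepared table
#' changes nothing.
#'
#' @param raw a raw `data.frame` from [read_observations()], a prepared
#'   `study_table` (returned unchanged up to logging), or any data.frame in
#'   the observation schema.
#' @param strict logical; `TRUE` stops on invalid rows, `FALSE` drops them
#'   with a warning.
#' @param variables admissible variable tokens; see [variable_registry()].
#' @return A `study_table`: list with `observations` (normalised
#'   data.frame), `provenance`, and `prep_log`.
#' @export
prepare_observations <- function(raw, strict = TRUE,
                                 variables = variable_registry()) {
  if (inherits(raw, "study_table")) raw <- raw$observations
  stopifnot(is.data.frame(raw))
  src <- attr(raw, "source_path")
  if (is.null(src)) src <- "<in-memory>"

  required <- c("study_id", "variable", "mean_t", "mean_c",
                "n_t", "n_c", "recovery_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("prepare_observations: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # optional columns default to NA so downstream code sees a fixed schema
  for (col in setdiff(obs_schema_columns(), names(raw))) raw[[col]] <- NA
  obs <- raw[, obs_schema_columns(), drop = FALSE]
  obs$row <- seq_len(nrow(obs))

  num_cols <- c("mean_t", "mean_c", "sd_t", "sd_c", "se_t", "se_c",
                "n_t", "n_c", "duration_years", "latitude", "longitude",
                "mat", "map")
  for (col in num_cols) obs[[col]] <- coerce_numeric_col(obs[[col]], col, obs$row)
  obs$study_id <- as.character(obs$study_id)
  obs$variable <- as.character(obs$variable)
  obs$recovery_type <- as.character(obs$recovery_type)

  bad_var <- which(!obs$variable %in% variables)
  if (length(bad_var)) {
    stop("prepare_observations: unknown variable token(s) ",
         paste(unique(obs$variable[bad_var]), collapse = ", "),
         " in column `variable`, row(s) ",
         paste(bad_var, collapse = ", "), call. = FALSE)
  }
  bad_rec <- which(!obs$recovery_type %in% c("restoration", "rehabilitation"))
  if (length(bad_rec)) {
    stop("prepare_observations: unknown recovery_type in row(s) ",
         paste(bad_rec, collapse = ", "),
         " (must be 'restoration' or 'rehabilitation')", call. = FALSE)
  }
  for (col in c("sd_t", "sd_c", "se_t", "se_c")) {
    neg <- which(!is.na(obs[[col]]) & obs[[col]] < 0)
    if (length(neg)) {
      stop("prepare_observations: negative dispersion in column `", col,
           "`, row(s) ", paste(neg, collapse = ", "), call. = FALSE)
    }
  }

  actions <- list()
  log_action <- function(row, column, action) {
    actions[[length(actions) + 1L]] <<- data.frame(
      row = row, column = column, action = action,
      stringsAsFactors = FALSE)
  }

  # invalid rows: non-positive/missing means or missing/invalid sample sizes
  invalid_mean <- is.na(obs$mean_t) | is.na(obs$mean_c) |
    obs$mean_t <= 0 | obs$mean_c <= 0
  invalid_n <- is.na(obs$n_t) | is.na(obs$n_c) | obs$n_t < 1 | obs$n_c < 1
  invalid <- invalid_mean | invalid_n
  dropped <- data.frame(row = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  if (any(invalid)) {
    reasons <- ifelse(invalid_mean[invalid],
                      "non-positive or missing mean",
                      "missing or invalid sample size")
    if (strict) {
      stop("prepare_observations: invalid row(s) ",
           paste(obs$row[invalid], collapse = ", "), " (",
           paste(unique(reasons), collapse = "; "),
           "); use strict = FALSE to drop them", call. = FALSE)
    }
    dropped <- data.frame(row = obs$row[invalid], reason = reasons,
                          stringsAsFactors = FALSE)
    warning("prepare_observations: dropped ", sum(invalid),
            " invalid row(s); see prep_log", call. = FALSE)
    obs <- obs[!invalid, , drop = FALSE]
  }

  # dispersion handling per group, SD taking precedence over SE
  for (grp in c("t", "c")) {
    sd_col <- paste0("sd_", grp)
    se_col <- paste0("se_", grp)
    n_col <- paste0("n_", grp)
    mean_col <- paste0("mean_", grp)
    has_sd <- !is.na(obs[[sd_col]])
    has_se <- !is.na(obs[[se_col]])
    both <- has_sd & has_se
    for (r in obs$row[both]) log_action(r, se_col, "se_ignored_sd_present")
    conv <- !has_sd & has_se
    if (any(conv)) {
      obs[[sd_col]][conv] <- se_to_sd(obs[[se_col]][conv], obs[[n_col]][conv])
      for (r in obs$row[conv]) log_action(r, sd_col, "se_converted")
    }
    imp <- is.na(obs[[sd_col]])
    if (any(imp)) {
      obs[[sd_col]][imp] <- impute_sd(obs[[mean_col]][imp])
      for (r in obs$row[imp]) log_action(r, sd_col, "sd_imputed")
    }
  }

  actions <- if (length(actions)) do.call(rbind, actions) else
    data.frame(row = integer(), column = character(), action = character(),
               stringsAsFactors = FALSE)
  counts <- c(
    n_input = nrow(raw),
    n_retained = nrow(obs),
    n_dropped = nrow(dropped),
    n_se_converted = sum(actions$action == "se_converted"),
    n_sd_imputed = sum(actions$action == "sd_imputed"),
    n_se_ignored = sum(actions$action == "se_ignored_sd_present")
  )

  structure(
    list(
      observations = obs,
      provenance = list(source = src, rows = obs$row),
      prep_log = list(actions = actions, dropped = dropped, counts = counts)
    ),
    class = "study_table"
  )
}

#' @export
print.study_table <- function(x, ...) {
  cnt <- x$prep_log$counts
  cat("<study_table> ", cnt[["n_retained"]], " observations from ",
      length(unique(x$observations$study_id)), " studies (source: ",
      x$provenance$source, ")\n", sep = "")
  cat("  prep: ", cnt[["n_se_converted"]], " SE->SD conversions, ",
      cnt[["n_sd_imputed"]], " SD imputations, ",
      cnt[["n_dropped"]], " rows dropped\n", sep = "")
  if ("ecosystem" %in% names(x$observations)) {
    cat("  subgroups assigned (ecosystem, duration_bin)\n")
  }
  invisible(x)
}

#' Attach subgroup labels to a prepared table
#'
#' Adds the two derived grouping columns used throughout the analysis:
#' \itemize{
#'   \item `ecosystem`: the raw ecosystem label with shrubland folded into
#'     forest (shrubland sites are treated as part of the forest ecosystem);
#'   \item `duration_bin`: restoration duration binned as `d0_10`
#'     (0 <= years < 10), `d10_20` (10 <= years <= 20) and `d20_plus`
#'     (> 20 years). Bin edges are configurable via `breaks`.
#' }
#'
#' @param table a `study_table` from [prepare_observations()].
#' @param breaks two increasing positive numbers, the bin edges (default
#'   `c(10, 20)`). A duration equal to the first edge falls in the middle
#'   bin; one equal to the second edge also falls in the middle bin.
#' @return The `study_table` with `ecosystem` and `duration_bin` columns.
#' @export
assign_subgroups <- function(table, breaks = c(10, 20)) {
  stopifnot(inherits(table, "study_table"),
            length(breaks) == 2, breaks[1] < breaks[2])
  obs <- table$observations
  if (any(!is.na(obs$duration_years) & obs$duration_years < 0)) {
    stop("assign_subgroups: negative duration_years", call. = FALSE)
  }
  eco <- obs$ecosystem_raw
  bad_eco <- which(!is.na(eco) & !eco %in% c("forest", "shrubland", "grassland"))
  if (length(bad_eco)) {
    stop("assign_subgroups: unknown ecosystem_raw in row(s) ",
         paste(obs$row[bad_eco], collapse = ", "), call. = FALSE)
  }
  obs$ecosystem <- ifelse(eco == "shrubland", "forest", eco)
  d <- obs$duration_years
  obs$duration_bin <- ifelse(is.na(d), NA_character_,
                      ifelse(d < breaks[1], "d0_10",
                      ifelse(d <= breaks[2], "d10_20", "d20_plus")))
  table$observations <- obs
  table
}

#' Write a normalised observation table and its preparation log
#'
#' @param table a `study_table`.
#' @param csv_path output CSV path for the observations (optional).
#' @param log_path output JSON path for the prep log (optional).
#' @return The input, invisibly.
#' @export
write_study_table <- function(table, csv_path = NULL, log_path = NULL) {
  stopifnot(inherits(table, "study_table"))
  if (!is.null(csv_path)) {
    utils::write.csv(table$observations, csv_path, row.names = FALSE)
  }
  if (!is.null(log_path)) {
    jsonlite::write_json(
      list(counts = as.list(table$prep_log$counts),
           actions = table$prep_log$actions,
           dropped = table$prep_log$dropped),
      log_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(table)
}
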