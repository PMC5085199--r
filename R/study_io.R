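## Study-level data model: reading, validation, median/range conversion.
##
## A study table is a plain data.frame with one row per case/control
## comparison.  Biomarker levels (e.g. serum TSH in mU/L) must be strictly
## positive: the ratio-of-means measure is undefined otherwise.

.rom_required <- c("study_id", "label", "ethnicity", "age_group", "design",
                   "quality_score", "n_case", "n_control")
.rom_meansd <- c("mean_case", "sd_case", "mean_control", "sd_control")
.rom_median <- c("median_case", "min_case", "max_case",
                 "median_control", "min_control", "max_control")
.rom_optional <- c("tumour_size_class", "tnm_stage", "node_metastasis",
                   "histology")

.cat_levels <- list(
  ethnicity         = c("Asian", "Caucasian", "Other"),
  age_group         = c("adult", "children"),
  design            = c("retrospective_cross_sectional", "other"),
  size_class        = c("small", "moderate", "large"),
  tumour_size_class = c("lt1cm", "ge1cm"),
  tnm_stage         = c("I_II", "III_IV"),
  node_metastasis   = c("yes", "no"),
  histology         = c("PTC", "FTC", "other"),
  cutoff_group      = c("lt0.5", "0.5to1.5", "1.5to2.5", "gt3.5")
)

#' Size class from the number of cases
#'
#' Studies are banded by case count: `small` (< 200 cases), `moderate`
#' (200--500) and `large` (> 500).  The class is always derived from
#' `n_case`; it is definitional, not free data.
#'
#' @param n_case integer vector of case counts.
#' @return character vector in `{small, moderate, large}`.
#' @export
size_class_from_n <- function(n_case) {
  if (any(!is_count(n_case) | n_case < 1))
    stopf("n_case must be positive integers")
  ifelse(n_case < 200, "small", ifelse(n_case <= 500, "moderate", "large"))
}

#' Convert a median/range summary to mean and SD
#'
#' Applies the standard median-range conversion for studies that report a
#' median with minimum and maximum instead of a mean and SD.  With
#' \eqn{a} = minimum, \eqn{m} = median, \eqn{b} = maximum:
#' \deqn{\hat\mu = (a + 2m + b)/4}
#' and the SD rule depends on sample size:
#' \deqn{n \le 15:\ \sqrt{\left(\tfrac{(a - 2m + b)^2}{4} + (b-a)^2\right)/12}}
#' \deqn{15 < n \le 70:\ (b-a)/4, \qquad n > 70:\ (b-a)/6.}
#' Band boundaries are closed on the left band (`n = 15` uses the small-n
#' formula, `n = 70` the middle one).
#'
#' @param median,minimum,maximum positive reals (same units as the
#'   biomarker); vectors recycle together.
#' @param n positive integer sample size(s).
#' @return data.frame with columns `mean` and `sd`.
#' @examples
#' hozo_convert(5, 1, 9, 100)  # mean 5, sd 8/6
#' @export
hozo_convert <- function(median, minimum, maximum, n) {
  len <- max(length(median), length(minimum), length(maximum), length(n))
  median <- rep_len(median, len); minimum <- rep_len(minimum, len)
  maximum <- rep_len(maximum, len); n <- rep_len(n, len)
  if (any(!is.finite(median) | !is.finite(minimum) | !is.finite(maximum)))
    stopf("median/minimum/maximum must be finite")
  if (any(!is_count(n) | n < 1)) stopf("n must be positive integers")
  bad <- minimum > median | median > maximum
  if (any(bad))
    stopf("ordering minimum <= median <= maximum violated at position(s) %s",
          paste(which(bad), collapse = ", "))
  if (any(maximum == minimum))
    stopf("degenerate range (maximum == minimum) at position(s) %s: SD is not estimable",
          paste(which(maximum == minimum), collapse = ", "))
  a <- minimum; m <- median; b <- maximum
  mean <- (a + 2 * m + b) / 4
  sd <- ifelse(n <= 15,
               sqrt(((a - 2 * m + b)^2 / 4 + (b - a)^2) / 12),
               ifelse(n <= 70, (b - a) / 4, (b - a) / 6))
  data.frame(mean = mean, sd = sd)
}

## normalize a categorical column case-insensitively against known levels;
## unknown/empty optional values become NA (explicit missing, never imputed)
.normalize_level <- function(x, field, required, rows) {
  levels <- .cat_levels[[field]]
  x <- trimws(as.character(x))
  x[x == "" | is.na(x) | tolower(x) %in% c("na", "missing", "unknown")] <- NA
  idx <- match(tolower(x), tolower(levels))
  out <- levels[idx]
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stopf("row(s) %s: invalid value(s) %s for '%s' (allowed: %s)",
          paste(rows[bad], collapse = ", "),
          paste(unique(sQuote(x[bad])), collapse = ", "),
          field, paste(levels, collapse = ", "))
  if (required && any(is.na(out)))
    stopf("row(s) %s: missing required categorical '%s'",
          paste(rows[is.na(out)], collapse = ", "), field)
  out
}

.check_numeric <- function(df, cols, rows) {
  for (col in cols) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(x) & !is.na(df[[col]]) & trimws(as.character(df[[col]])) != ""
    if (any(bad))
      stopf("row(s) %s: non-numeric value in '%s'", paste(rows[bad], collapse = ", "), col)
    df[[col]] <- x
  }
  df
}

.read_delim_guess <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#", quote = "\"", fileEncoding = "UTF-8",
                    check.names = TRUE)
}

#' Read and validate a study-level table
#'
#' Reads a UTF-8 delimited text file (comma default, tab accepted; header
#' required) and validates it against one of three schemas:
#' \describe{
#'   \item{`rom`}{case/control summary statistics for the ratio-of-means arm.
#'     Either `mean_*`/`sd_*` columns, or `median_*`/`min_*`/`max_*`
#'     columns together with `convert_median = TRUE`, in which case
#'     [hozo_convert()] supplies the mean and SD.}
#'   \item{`categories`}{long-form biomarker category counts
#'     (`study_id, bin_low, bin_high, case_count, control_count`).}
#'   \item{`diagnostic`}{2x2 counts at a named cut-off group
#'     (`study_id, cutoff_group, tp, fp, fn, tn`).}
#' }
#' Rows violating an invariant (non-positive mean or SD, zero sample size,
#' inconsistent bins, ...) abort the read with row-number diagnostics.
#' Categorical values are matched case-insensitively; unknown optional
#' subgroup values are stored as `NA`.
#'
#' @param path file path.
#' @param schema one of `"rom"`, `"categories"`, `"diagnostic"`.
#' @param convert_median logical; for the `rom` schema, derive mean/SD from
#'   median/min/max columns.
#' @return For `rom` and `diagnostic`, a validated data.frame (one row per
#'   study).  For `categories`, a list of category-count records, each with
#'   `study_id`, `bin_edges`, `case_counts`, `control_counts`.
#' @export
read_study_table <- function(path, schema = c("rom", "categories", "diagnostic"),
                             convert_median = FALSE) {
  schema <- match.arg(schema)
  df <- .read_delim_guess(path)
  switch(schema,
    rom        = validate_rom_table(df, convert_median = convert_median),
    categories = .validate_category_table(df),
    diagnostic = validate_diagnostic_table(df))
}

#' Validate an in-memory study table against the ratio-of-means schema
#'
#' @param df data.frame shaped like the `rom` CSV schema.
#' @param convert_median derive mean/SD columns from median/min/max via
#'   [hozo_convert()].
#' @return validated data.frame of study records.
#' @export
validate_rom_table <- function(df, convert_median = FALSE) {
  rows <- seq_len(nrow(df))
  missing_cols <- setdiff(.rom_required, names(df))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  value_cols <- if (convert_median) .rom_median else .rom_meansd
  missing_cols <- setdiff(value_cols, names(df))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))

  df$study_id <- trimws(as.character(df$study_id))
  if (anyDuplicated(df$study_id))
    stopf("duplicate study_id: %s",
          paste(unique(df$study_id[duplicated(df$study_id)]), collapse = ", "))
  df <- .check_numeric(df, c("n_case", "n_control", "quality_score", value_cols), rows)

  if (convert_median) {
    case <- hozo_convert(df$median_case, df$min_case, df$max_case, df$n_case)
    ctrl <- hozo_convert(df$median_control, df$min_control, df$max_control, df$n_control)
    df$mean_case <- case$mean;    df$sd_case <- case$sd
    df$mean_control <- ctrl$mean; df$sd_control <- ctrl$sd
  }

  bad <- !is_count(df$n_case) | df$n_case < 1 | !is_count(df$n_control) | df$n_control < 1
  if (any(bad))
    stopf("row(s) %s: sample sizes must be integers >= 1", paste(rows[bad], collapse = ", "))
  for (col in .rom_meansd) {
    bad <- !is.finite(df[[col]]) | df[[col]] <= 0
    if (any(bad))
      stopf("row(s) %s: '%s' must be strictly positive (biomarker levels and SDs are positive quantities)",
            paste(rows[bad], collapse = ", "), col)
  }
  bad <- !is_count(df$quality_score) | df$quality_score > 9
  if (any(bad))
    stopf("row(s) %s: quality_score must be an integer in 0..9", paste(rows[bad], collapse = ", "))

  for (field in c("ethnicity", "age_group", "design"))
    df[[field]] <- .normalize_level(df[[field]], field, required = TRUE, rows = rows)
  for (field in intersect(.rom_optional, names(df)))
    df[[field]] <- .normalize_level(df[[field]], field, required = FALSE, rows = rows)
  for (field in setdiff(.rom_optional, names(df))) df[[field]] <- NA_character_

  derived <- size_class_from_n(df$n_case)
  if ("size_class" %in% names(df)) {
    supplied <- .normalize_level(df$size_class, "size_class", required = FALSE, rows = rows)
    mismatch <- !is.na(supplied) & supplied != derived
    if (any(mismatch))
      warnf("row(s) %s: supplied size_class disagrees with the definitional bands; recomputed from n_case",
            paste(rows[mismatch], collapse = ", "))
  }
  df$size_class <- derived
  df[c(.rom_required[1:2], "ethnicity", "age_group", "design", "size_class",
       "quality_score", "n_case", "n_control", .rom_meansd, .rom_optional)]
}

#' Validate an in-memory diagnostic 2x2 table
#'
#' @param df data.frame with columns `study_id, cutoff_group, tp, fp, fn, tn`.
#' @return validated data.frame.
#' @export
validate_diagnostic_table <- function(df) {
  rows <- seq_len(nrow(df))
  need <- c("study_id", "cutoff_group", "tp", "fp", "fn", "tn")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  df$study_id <- trimws(as.character(df$study_id))
  if (anyDuplicated(df[c("study_id", "cutoff_group")]))
    stopf("duplicate study_id within a cutoff_group")
  df <- .check_numeric(df, c("tp", "fp", "fn", "tn"), rows)
  for (col in c("tp", "fp", "fn", "tn")) {
    bad <- !is_count(df[[col]])
    if (any(bad))
      stopf("row(s) %s: '%s' must be a non-negative integer", paste(rows[bad], collapse = ", "), col)
  }
  bad <- (df$tp + df$fn) < 1 | (df$fp + df$tn) < 1
  if (any(bad))
    stopf("row(s) %s: each study needs at least one diseased and one non-diseased subject",
          paste(rows[bad], collapse = ", "))
  df$cutoff_group <- .normalize_level(df$cutoff_group, "cutoff_group",
                                      required = TRUE, rows = rows)
  df[need]
}

## long-form category counts -> one record per study with contiguous bins
.validate_category_table <- function(df) {
  need <- c("study_id", "bin_low", "bin_high", "case_count", "control_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  df$bin_high[trimws(tolower(as.character(df$bin_high))) %in% c("inf", "+inf")] <- Inf
  df <- .check_numeric(df, c("bin_low", "bin_high", "case_count", "control_count"),
                       seq_len(nrow(df)))
  lapply(split(df, df$study_id), function(d) {
    d <- d[order(d$bin_low), ]
    if (any(d$bin_low >= d$bin_high))
      stopf("study %s: bin edges must be strictly increasing", d$study_id[1])
    if (nrow(d) > 1 && any(abs(d$bin_low[-1] - d$bin_high[-nrow(d)]) > 1e-9))
      stopf("study %s: bins are not contiguous", d$study_id[1])
    if (any(!is_count(d$case_count)) || any(!is_count(d$control_count)))
      stopf("study %s: counts must be non-negative integers", d$study_id[1])
    category_counts(d$study_id[1], c(d$bin_low, d$bin_high[nrow(d)]),
                    d$case_count, d$control_count)
  })
}

#' Construct a category-count record
#'
#' One study's distribution of cases and controls across biomarker ranges:
#' `bin_edges` has length one more than the count vectors and is strictly
#' increasing (the last edge may be `Inf`).
#'
#' @param study_id study identifier.
#' @param bin_edges numeric breaks, strictly increasing.
#' @param case_counts,control_counts non-negative integer counts per bin.
#' @return a `category_counts` object.
#' @export
category_counts <- function(study_id, bin_edges, case_counts, control_counts) {
  if (length(bin_edges) != length(case_counts) + 1 ||
      length(case_counts) != length(control_counts))
    stopf("study %s: need length(bin_edges) == length(counts) + 1", study_id)
  if (any(diff(bin_edges) <= 0))
    stopf("study %s: bin edges must be strictly increasing", study_id)
  if (any(!is_count(case_counts)) || any(!is_count(control_counts)))
    stopf("study %s: counts must be non-negative integers", study_id)
  structure(list(study_id = as.character(study_id), bin_edges = as.numeric(bin_edges),
                 case_counts = as.integer(case_counts),
                 control_counts = as.integer(control_counts)),
            class = "category_counts")
}

#' Write a study table back to delimited text
#'
#' Inverse of [read_study_table()] for the `rom` and `diagnostic` schemas;
#' re-reading the written file reproduces the validated table field by field.
#'
#' @param df validated study table.
#' @param path output path.
#' @param sep field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_study_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}
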