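## Effect measures on the analysis (log) scale.
##
## All pooling operates on `estimates` data.frames with columns
## study_id, y (log-scale effect), v (variance of y), measure.

new_estimates <- function(study_id, y, v, measure) {
  if (any(!is.finite(v) | v <= 0)) stopf("estimate variances must be strictly positive")
  if (any(!is.finite(y))) stopf("estimates must be finite")
  structure(data.frame(study_id = as.character(study_id), y = y, v = v,
                       measure = measure, stringsAsFactors = FALSE),
            class = c("estimates", "data.frame"))
}

#' Log ratio of means with delta-method variance
#'
#' The ratio of means (RoM) is the case-group mean divided by the
#' control-group mean; it is analysed on the log scale, where assay-scale
#' differences between studies cancel.  For one study,
#' \deqn{y = \ln(\bar x_{case}/\bar x_{control}), \quad
#'       v = \frac{s^2_{case}}{n_{case}\,\bar x_{case}^2} +
#'           \frac{s^2_{control}}{n_{control}\,\bar x_{control}^2}}
#' (first-order delta method).
#'
#' @param records validated study table (see [read_study_table()]), or any
#'   data.frame with `study_id`, `n_case`, `mean_case`, `sd_case`,
#'   `n_control`, `mean_control`, `sd_control`.
#' @return an `estimates` data.frame, measure `"log_rom"`.
#' @examples
#' rec <- data.frame(study_id = "s1", n_case = 100, mean_case = 2, sd_case = 1,
#'                   n_control = 100, mean_control = 1, sd_control = 1)
#' log_rom(rec)  # y = log 2, v = 0.0125
#' @export
log_rom <- function(records) {
  need <- c("study_id", "n_case", "mean_case", "sd_case",
            "n_control", "mean_control", "sd_control")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stopf("log_rom: missing column(s) %s", paste(missing_cols, collapse = ", "))
  with(records, {
    if (any(mean_case <= 0 | mean_control <= 0 | sd_case <= 0 | sd_control <= 0))
      stopf("log_rom: means and SDs must be strictly positive")
    y <- log(mean_case / mean_control)
    v <- sd_case^2 / (n_case * mean_case^2) +
         sd_control^2 / (n_control * mean_control^2)
    new_estimates(study_id, y, v, "log_rom")
  })
}

#' Log odds ratio from a 2x2 table
#'
#' Cell layout: `a` = cases exposed, `b` = controls exposed, `c` = cases
#' referent, `d` = controls referent; \eqn{y = \ln(ad/bc)},
#' \eqn{v = 1/a + 1/b + 1/c + 1/d}.  When any cell is zero, `correction`
#' (default 0.5) is added to every cell before computing; with no zero cell
#' the counts are used as given.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param correction continuity correction added to all cells when a zero
#'   cell is present.
#' @param study_id identifier carried into the estimate.
#' @return a one-row `estimates` data.frame, measure `"log_or"`.
#' @export
log_or <- function(a, b, c, d, correction = 0.5, study_id = "table") {
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(!is_count(cells))) stopf("log_or: cells must be non-negative integers")
  if (a + c < 1 || b + d < 1)
    stopf("log_or: each column of the 2x2 table needs at least one subject")
  if (any(cells == 0)) {
    if (correction <= 0)
      stopf("log_or: zero cell with no continuity correction; odds ratio undefined")
    cells <- cells + correction
  }
  y <- log(cells["a"] * cells["d"] / (cells["b"] * cells["c"]))
  v <- sum(1 / cells)
  new_estimates(study_id, unname(y), unname(v), "log_or")
}

#' Collapse category counts to a 2x2 exposure table
#'
#' Sums the bins of a category-count record that fall inside the half-open
#' exposed and referent ranges `[low, high)`.  Both range endpoints must
#' coincide with bin edges of the study (the record cannot be split below
#' its own resolution).
#'
#' @param row a [category_counts()] record.
#' @param exposed_range,referent_range numeric length-2 vectors `(low, high)`;
#'   `Inf` is allowed as an upper endpoint.
#' @return named integer vector `c(a, b, c, d)`: cases/controls exposed,
#'   cases/controls referent.
#' @export
categories_to_or <- function(row, exposed_range, referent_range) {
  stopifnot(inherits(row, "category_counts"))
  pick <- function(range, what) {
    lo <- range[1]; hi <- range[2]
    edges <- row$bin_edges
    i <- which(abs(edges - lo) < 1e-9 | (is.infinite(lo) & is.infinite(edges) & sign(edges) == sign(lo)))
    j <- which(abs(edges - hi) < 1e-9 | (is.infinite(hi) & is.infinite(edges) & sign(edges) == sign(hi)))
    if (!length(i))
      stopf("study %s: %s range edge %s does not align with the study's bins",
            row$study_id, what, format(lo))
    if (!length(j))
      stopf("study %s: %s range edge %s does not align with the study's bins",
            row$study_id, what, format(hi))
    if (j[1] <= i[1]) stopf("study %s: empty %s range", row$study_id, what)
    bins <- seq.int(i[1], j[1] - 1L)
    c(case = sum(row$case_counts[bins]), control = sum(row$control_counts[bins]))
  }
  exposed <- pick(exposed_range, "exposed")
  referent <- pick(referent_range, "referent")
  c(a = unname(exposed["case"]), b = unname(exposed["control"]),
    c = unname(referent["case"]), d = unname(referent["control"]))
}
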