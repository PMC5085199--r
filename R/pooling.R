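## Inverse-variance pooling: fixed effect and DerSimonian-Laird random
## effects, heterogeneity statistics, subgroups, contrasts, leave-one-out.
##
## All arithmetic stays on the log (or logit) scale; exponentiation /
## inverse-logit happens only at the reporting boundary (CI columns and
## print methods).

.as_estimates <- function(estimates) {
  if (!is.data.frame(estimates) || !all(c("y", "v") %in% names(estimates)))
    stopf("expected an estimates data.frame with columns y and v")
  if (is.null(estimates$study_id))
    estimates$study_id <- paste0("study_", seq_len(nrow(estimates)))
  if (is.null(estimates$measure)) estimates$measure <- "log_rom"
  estimates
}

new_pooled_result <- function(estimates, y_pooled, se_pooled, Q, tau_squared,
                              weights, model, alpha) {
  k <- nrow(estimates)
  df <- k - 1L
  zcrit <- stats::qnorm(1 - alpha / 2)
  z <- y_pooled / se_pooled
  measure <- estimates$measure[1]
  back <- report_transform(measure)
  structure(list(
    k = k,
    measure = measure,
    y_pooled = y_pooled,
    se_pooled = se_pooled,
    est_pooled = back(y_pooled),
    ci_low = back(y_pooled - zcrit * se_pooled),
    ci_high = back(y_pooled + zcrit * se_pooled),
    z = z,
    p_z = 2 * stats::pnorm(-abs(z)),
    Q = Q,
    df = df,
    p_q = if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    i_squared = if (df >= 1) i_squared(Q, df) else 0,
    tau_squared = tau_squared,
    weights = stats::setNames(weights / sum(weights), estimates$study_id),
    model = model,
    alpha = alpha,
    estimates = estimates
  ), class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s-effect pooled %s (k = %d)\n",
              if (x$model == "fixed") "Fixed" else "Random", x$measure, x$k))
  cat(sprintf("  estimate %.*f (%.*f-%.*f), z = %.*f, p = %.3g\n",
              digits, x$est_pooled, digits, x$ci_low, digits, x$ci_high,
              digits, x$z, x$p_z))
  cat(sprintf("  Q = %.*f (df = %d, p = %.3g), I2 = %.1f%%, tau2 = %.*f\n",
              digits, x$Q, x$df, x$p_q, 100 * x$i_squared, digits, x$tau_squared))
  invisible(x)
}

#' Heterogeneity I-squared
#'
#' \eqn{I^2 = (Q - df)/Q}, truncated at zero; the fraction of total
#' variation in study effects attributable to between-study heterogeneity.
#'
#' @param Q Cochran's Q statistic (non-negative).
#' @param df degrees of freedom, `k - 1 >= 1`.
#' @return a value in `[0, 1)`.
#' @export
i_squared <- function(Q, df) {
  if (any(Q < 0)) stopf("Q must be non-negative")
  if (any(df < 1 | df != floor(df))) stopf("df must be a positive integer")
  ifelse(Q > 0, pmax(0, (Q - df) / Q), 0)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Weights \eqn{w_i = 1/v_i}; pooled effect \eqn{\sum w_i y_i / \sum w_i};
#' Cochran's \eqn{Q = \sum w_i (y_i - \bar y)^2} with `k - 1` df.
#'
#' @param estimates an `estimates` data.frame (columns `study_id, y, v,
#'   measure`), e.g. from [log_rom()].
#' @param alpha two-sided CI level (default 0.05 for a 95\% CI).
#' @return a `pooled_result` (log-scale effect plus back-transformed CI,
#'   Q, I-squared, weights).
#' @export
pool_fixed <- function(estimates, alpha = 0.05) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 1) stopf("pool_fixed: need at least one estimate")
  if (any(estimates$v <= 0)) stopf("pool_fixed: variances must be positive")
  w <- 1 / estimates$v
  y_f <- sum(w * estimates$y) / sum(w)
  Q <- sum(w * (estimates$y - y_f)^2)
  new_pooled_result(estimates, y_f, sqrt(1 / sum(w)), Q,
                    tau_squared = 0, weights = w, model = "fixed", alpha = alpha)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance,
#' \deqn{\tau^2 = \max\!\left(0, \frac{Q - (k-1)}{\sum w_i - \sum w_i^2/\sum w_i}\right)}
#' with fixed-effect weights \eqn{w_i = 1/v_i}; random-effects weights
#' \eqn{w_i^* = 1/(v_i + \tau^2)}.  Q, I-squared and their p-value are the
#' fixed-weight quantities.  When \eqn{Q \le k - 1} the estimator truncates
#' to \eqn{\tau^2 = 0} and the result coincides with [pool_fixed()] exactly.
#' A single study is returned as itself with \eqn{\tau^2 = 0}.
#'
#' @inheritParams pool_fixed
#' @return a `pooled_result` with `model = "random"`.
#' @export
pool_dl <- function(estimates, alpha = 0.05) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 1) stopf("pool_dl: need at least one estimate")
  if (any(estimates$v <= 0)) stopf("pool_dl: variances must be positive")
  fixed <- pool_fixed(estimates, alpha = alpha)
  if (k == 1) {
    out <- new_pooled_result(estimates, estimates$y, sqrt(estimates$v), 0,
                             tau_squared = 0, weights = 1, model = "random",
                             alpha = alpha)
    return(out)
  }
  w <- 1 / estimates$v
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (C > 0) max(0, (fixed$Q - (k - 1)) / C) else 0
  w_star <- 1 / (estimates$v + tau2)
  y_r <- sum(w_star * estimates$y) / sum(w_star)
  new_pooled_result(estimates, y_r, sqrt(1 / sum(w_star)), fixed$Q,
                    tau_squared = tau2, weights = w_star, model = "random",
                    alpha = alpha)
}

#' Stratified (subgroup) pooling
#'
#' Splits the study table by one stratification factor and runs [pool_dl()]
#' independently within each level.  Records with a missing factor value
#' form their own `"unknown"` level so that the union of levels is the
#' input set.
#'
#' @param records validated study table.
#' @param factor name of a column of `records` to stratify by
#'   (e.g. `"ethnicity"`, `"size_class"`, `"age_group"`, `"design"`).
#' @param measure function mapping a study table to estimates
#'   (default [log_rom]).
#' @param alpha CI level passed through.
#' @return named list of `pooled_result`, one per level, with per-level
#'   case/control totals attached as attributes `n_case`/`n_control`.
#' @export
subgroup_pool <- function(records, factor, measure = log_rom, alpha = 0.05) {
  if (!factor %in% names(records))
    stopf("subgroup_pool: '%s' is not a column of the study table", factor)
  f <- as.character(records[[factor]])
  f[is.na(f)] <- "unknown"
  out <- lapply(split(records, f), function(sub) {
    res <- pool_dl(measure(sub), alpha = alpha)
    attr(res, "n_case") <- sum(sub$n_case)
    attr(res, "n_control") <- sum(sub$n_control)
    res
  })
  out[order(names(out))]
}

#' Contrast two pooled results
#'
#' Two-sample z-test on the analysis (log) scale:
#' \eqn{z = (y_a - y_b)/\sqrt{se_a^2 + se_b^2}}, two-sided normal p-value.
#' Used, e.g., to compare the pooled ratio in large versus small tumours or
#' advanced versus localised stage.
#'
#' @param a,b `pooled_result` objects on the same measure scale.
#' @return list with `z` and `p`.
#' @export
compare_two_pooled <- function(a, b) {
  stopifnot(inherits(a, "pooled_result"), inherits(b, "pooled_result"))
  if (a$measure != b$measure)
    stopf("compare_two_pooled: results are on different measure scales")
  z <- (a$y_pooled - b$y_pooled) / sqrt(a$se_pooled^2 + b$se_pooled^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools with [pool_dl()] after omitting each study in turn; shows how
#' much any single study drives the summary effect and the heterogeneity.
#'
#' @inheritParams pool_fixed
#' @return object of class `loo_result`: a list of `pooled_result`s named by
#'   the omitted study; `summary()`/`as.data.frame()` give one row per
#'   omission.
#' @export
leave_one_out <- function(estimates, alpha = 0.05) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 3) stopf("leave_one_out: need at least 3 studies")
  results <- lapply(seq_len(k), function(i) pool_dl(estimates[-i, ], alpha = alpha))
  names(results) <- estimates$study_id
  structure(results, class = "loo_result")
}

#' @export
as.data.frame.loo_result <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(id) {
    r <- x[[id]]
    data.frame(omitted = id, k = r$k, est = r$est_pooled,
               ci_low = r$ci_low, ci_high = r$ci_high, p_z = r$p_z,
               tau_squared = r$tau_squared, i_squared = r$i_squared,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.loo_result <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) if (is.numeric(col)) round(col, digits) else col)
  cat(sprintf("Leave-one-out sensitivity analysis (%d omissions)\n", nrow(df)))
  print(df, row.names = FALSE)
  invisible(x)
}

## Table-1-shaped summary: one row per pooled_result
pooled_table <- function(results, labels = names(results)) {
  do.call(rbind, Map(function(r, lab) {
    data.frame(subgroup = lab, k = r$k,
               n_case = attr(r, "n_case") %||% NA_integer_,
               n_control = attr(r, "n_control") %||% NA_integer_,
               est = r$est_pooled, ci_low = r$ci_low, ci_high = r$ci_high,
               p_z = r$p_z, p_q = r$p_q, i_squared_pct = 100 * r$i_squared,
               tau_squared = r$tau_squared, stringsAsFactors = FALSE)
  }, results, labels))
}
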