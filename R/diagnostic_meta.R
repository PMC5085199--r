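## Cut-off-grouped diagnostic-accuracy meta-analysis: per-study sensitivity
## and specificity on the logit scale, pooled likelihood ratios, the
## clinical-utility quadrant, and the Moses-Littenberg summary ROC.

.cutoff_groups <- c("lt0.5", "0.5to1.5", "1.5to2.5", "gt3.5")

#' Map a numeric biomarker cut-off to its named band
#'
#' Bands: `lt0.5` (< 0.5), `0.5to1.5` (0.5--1.5), `1.5to2.5` (1.5--2.5,
#' exclusive on the left) and `gt3.5` (> 3.5), in mU/L.  Cut-offs in
#' (2.5, 3.5] belong to no named band; they map to `NA` with a warning
#' rather than being silently assigned.
#'
#' @param cutoff numeric vector of cut-off values, mU/L.
#' @return character vector of band labels (`NA` where unassignable).
#' @export
assign_cutoff_group <- function(cutoff) {
  out <- ifelse(cutoff < 0.5, "lt0.5",
         ifelse(cutoff <= 1.5, "0.5to1.5",
         ifelse(cutoff <= 2.5, "1.5to2.5",
         ifelse(cutoff > 3.5, "gt3.5", NA_character_))))
  if (anyNA(out))
    warnf("cut-off(s) %s fall in (2.5, 3.5], which belongs to no named band; returned NA",
          paste(format(cutoff[is.na(out)]), collapse = ", "))
  out
}

#' Per-study sensitivity and specificity with logit-scale estimates
#'
#' `sens = tp/(tp+fn)`, `spec = tn/(tn+fp)`.  When any of the four cells is
#' zero, `correction` (default 0.5) is added to every cell of that study
#' before anything is computed, so all downstream quantities stay finite.
#' Logit-scale variances are `1/tp + 1/fn` and `1/tn + 1/fp` on the
#' (possibly corrected) cells.
#'
#' @param studies validated diagnostic table (see
#'   [validate_diagnostic_table()]) or any data.frame with `study_id, tp,
#'   fp, fn, tn`.
#' @param correction continuity correction for zero cells.
#' @return data.frame with per-study `sens`, `spec`, `logit_sens`,
#'   `v_logit_sens`, `logit_spec`, `v_logit_spec` and the corrected cells.
#' @export
sens_spec <- function(studies, correction = 0.5) {
  need <- c("study_id", "tp", "fp", "fn", "tn")
  missing_cols <- setdiff(need, names(studies))
  if (length(missing_cols))
    stopf("sens_spec: missing column(s) %s", paste(missing_cols, collapse = ", "))
  if (any(studies$tp + studies$fn < 1) || any(studies$fp + studies$tn < 1))
    stopf("sens_spec: each study needs at least one diseased and one non-diseased subject")
  zero <- with(studies, tp == 0 | fp == 0 | fn == 0 | tn == 0)
  adj <- ifelse(zero, correction, 0)
  tp <- studies$tp + adj; fp <- studies$fp + adj
  fn <- studies$fn + adj; tn <- studies$tn + adj
  data.frame(study_id = studies$study_id,
             sens = tp / (tp + fn), spec = tn / (tn + fp),
             logit_sens = log(tp / fn), v_logit_sens = 1 / tp + 1 / fn,
             logit_spec = log(tn / fp), v_logit_spec = 1 / tn + 1 / fp,
             tp = tp, fp = fp, fn = fn, tn = tn,
             corrected = zero, stringsAsFactors = FALSE)
}

#' Pool proportions on the logit scale
#'
#' DerSimonian-Laird pooling of logit-scale estimates, back-transformed
#' through the inverse logit — the engine behind pooled sensitivity and
#' specificity.
#'
#' @param estimates an `estimates` data.frame whose `measure` is
#'   `logit_sens` or `logit_spec` (any logit-scale estimates work).
#' @param alpha CI level.
#' @return a `pooled_result`; `est_pooled`, `ci_low`, `ci_high` are on the
#'   proportion scale.
#' @export
pool_logit <- function(estimates, alpha = 0.05) {
  estimates <- .as_estimates(estimates)
  if (!all(startsWith(estimates$measure, "logit")))
    stopf("pool_logit: estimates must be on the logit scale")
  pool_dl(estimates, alpha = alpha)
}

#' Positive and negative likelihood ratios
#'
#' `PLR = sens/(1 - spec)`, `NLR = (1 - sens)/spec`.  Inputs must lie
#' strictly inside (0, 1): a zero-cell study must have been continuity
#' corrected upstream (see [sens_spec()]).
#'
#' @param sens,spec proportions in (0, 1); vectors recycle.
#' @return data.frame with columns `plr` and `nlr`.
#' @export
plr_nlr <- function(sens, spec) {
  if (any(sens <= 0 | sens >= 1 | spec <= 0 | spec >= 1))
    stopf("plr_nlr: sens and spec must lie strictly in (0, 1); apply a continuity correction upstream")
  data.frame(plr = sens / (1 - spec), nlr = (1 - sens) / spec)
}

#' Clinical-utility quadrant of a likelihood-ratio pair
#'
#' A clinically useful test has `PLR > 10` and `NLR < 0.1` (both strict).
#' A test meeting only the PLR bound can confirm disease
#' (`confirmation_only`), only the NLR bound can exclude it
#' (`exclusion_only`); otherwise `not_useful`.
#'
#' @param plr,nlr positive likelihood-ratio values; vectors recycle.
#' @return character vector of quadrant labels.
#' @export
lr_classify <- function(plr, nlr) {
  if (any(plr <= 0 | nlr <= 0)) stopf("lr_classify: likelihood ratios must be positive")
  ifelse(plr > 10 & nlr < 0.1, "clinically_useful",
  ifelse(plr > 10, "confirmation_only",
  ifelse(nlr < 0.1, "exclusion_only", "not_useful")))
}

## DL pooling of log likelihood ratios with delta-method variances
.pool_log_lr <- function(ss, which = c("plr", "nlr"), alpha = 0.05) {
  which <- match.arg(which)
  y <- if (which == "plr") {
    log((ss$tp / (ss$tp + ss$fn)) / (ss$fp / (ss$fp + ss$tn)))
  } else {
    log((ss$fn / (ss$tp + ss$fn)) / (ss$tn / (ss$fp + ss$tn)))
  }
  v <- if (which == "plr") {
    1 / ss$tp - 1 / (ss$tp + ss$fn) + 1 / ss$fp - 1 / (ss$fp + ss$tn)
  } else {
    1 / ss$fn - 1 / (ss$tp + ss$fn) + 1 / ss$tn - 1 / (ss$fp + ss$tn)
  }
  pool_dl(new_estimates(ss$study_id, y, v, paste0("log_", which)), alpha = alpha)
}

## Moses-Littenberg coefficients from per-study TPR/FPR
.moses_fit <- function(ss, weighted = FALSE) {
  ## logit(FPR) = log(fp/tn); D = logit(TPR) - logit(FPR), S = their sum
  lt <- ss$logit_sens
  lf <- log(ss$fp / ss$tn)
  D <- lt - lf
  S <- lt + lf
  w <- if (weighted) 1 / (1 / ss$tp + 1 / ss$fn + 1 / ss$fp + 1 / ss$tn) else rep(1, nrow(ss))
  fit <- stats::lm(D ~ S, weights = w)
  list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
       D = D, S = S)
}

#' SROC curve ordinate
#'
#' The Moses-Littenberg summary ROC maps a false-positive rate to
#' \deqn{TPR(FPR) = \mathrm{expit}\!\left(\frac{a + (1+b)\,\mathrm{logit}(FPR)}{1-b}\right).}
#'
#' @param fpr false-positive rate(s) in (0, 1).
#' @param a,b regression intercept and slope of `D` on `S`.
#' @return true-positive rate(s).
#' @export
sroc_curve <- function(fpr, a, b) {
  expit((a + (1 + b) * logit(fpr)) / (1 - b))
}

#' Moses-Littenberg summary ROC meta-analysis
#'
#' For each study, `D = logit(TPR) - logit(FPR)` (the log diagnostic odds
#' ratio) and `S = logit(TPR) + logit(FPR)` (a threshold proxy); the line
#' `D = a + b S` is fitted by unweighted least squares (set
#' `weighted = TRUE` for inverse-variance weights on D).  The implied
#' summary curve is integrated numerically over the full FPR domain (0, 1)
#' to give the area under the SROC (AUSROC); the curve runs from (0,0) to
#' (1,1) whenever `|b| < 1`.  When `|b| >= 1` the back-transform is not
#' monotone: the coefficients are reported and the area is `NA`.
#'
#' Alongside the curve, the summary pools sensitivity and specificity on
#' the logit scale and the likelihood ratios on the log scale (all
#' DerSimonian-Laird), and classifies the pooled pair on the
#' clinical-utility quadrant.  The AUSROC confidence interval is a
#' nonparametric bootstrap over studies (percentile method).
#'
#' @param studies diagnostic table (`study_id, tp, fp, fn, tn`, optionally
#'   `cutoff_group`) with at least 3 studies.
#' @param correction zero-cell continuity correction (see [sens_spec()]).
#' @param weighted use inverse-variance weights in the D-on-S regression.
#' @param alpha CI level.
#' @param boot number of bootstrap resamples for the AUSROC CI (0 disables).
#' @param seed optional integer seed for the bootstrap.
#' @return object of class `sroc_summary`: pooled sens/spec/PLR/NLR with
#'   CIs, `moses_a`, `moses_b`, `ausroc` (+ CI), `utility` label, `k`,
#'   `cutoff_group`.
#' @export
sroc_moses <- function(studies, correction = 0.5, weighted = FALSE,
                       alpha = 0.05, boot = 2000, seed = NULL) {
  ss <- sens_spec(studies, correction = correction)
  k <- nrow(ss)
  if (k < 3) stopf("sroc_moses: need at least 3 studies")
  fit <- .moses_fit(ss, weighted = weighted)
  ausroc <- .ausroc(fit$a, fit$b)

  ausroc_ci <- c(NA_real_, NA_real_)
  if (boot > 0 && !is.na(ausroc)) {
    if (!is.null(seed)) set.seed(seed)
    areas <- vapply(seq_len(boot), function(i) {
      idx <- sample.int(k, k, replace = TRUE)
      sub <- ss[idx, ]
      if (length(unique(sub$study_id)) < 2) return(NA_real_)
      f <- try(.moses_fit(sub, weighted = weighted), silent = TRUE)
      if (inherits(f, "try-error") || is.na(f$b)) NA_real_ else .ausroc(f$a, f$b)
    }, numeric(1))
    ausroc_ci <- unname(stats::quantile(areas, c(alpha / 2, 1 - alpha / 2),
                                        na.rm = TRUE))
  }

  p_sens <- pool_logit(new_estimates(ss$study_id, ss$logit_sens,
                                     ss$v_logit_sens, "logit_sens"), alpha)
  p_spec <- pool_logit(new_estimates(ss$study_id, ss$logit_spec,
                                     ss$v_logit_spec, "logit_spec"), alpha)
  p_plr <- .pool_log_lr(ss, "plr", alpha)
  p_nlr <- .pool_log_lr(ss, "nlr", alpha)

  group <- if ("cutoff_group" %in% names(studies) &&
               length(unique(studies$cutoff_group)) == 1)
    studies$cutoff_group[1] else NA_character_

  structure(list(
    cutoff_group = group, k = k,
    pooled_sens = p_sens, pooled_spec = p_spec,
    pooled_plr = p_plr, pooled_nlr = p_nlr,
    moses_a = fit$a, moses_b = fit$b,
    ausroc = ausroc, ausroc_ci = ausroc_ci,
    utility = lr_classify(max(p_plr$est_pooled, .Machine$double.eps),
                          max(p_nlr$est_pooled, .Machine$double.eps)),
    per_study = ss
  ), class = "sroc_summary")
}

## area under the Moses-Littenberg curve over FPR in (0,1)
.ausroc <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || abs(b) >= 1) return(NA_real_)
  stats::integrate(function(x) sroc_curve(x, a, b), 0, 1,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}

#' @export
print.sroc_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Moses-Littenberg SROC summary (k = %d%s)\n", x$k,
              if (!is.na(x$cutoff_group)) paste0(", cut-off band ", x$cutoff_group) else ""))
  fmt <- function(p) sprintf("%.*f (%.*f-%.*f)", digits, p$est_pooled,
                             digits, p$ci_low, digits, p$ci_high)
  cat("  pooled sensitivity:", fmt(x$pooled_sens), "\n")
  cat("  pooled specificity:", fmt(x$pooled_spec), "\n")
  cat("  pooled PLR:", fmt(x$pooled_plr), " NLR:", fmt(x$pooled_nlr),
      " ->", x$utility, "\n")
  cat(sprintf("  D = %.3f + %.3f S; AUSROC = %s (%.3f-%.3f)\n",
              x$moses_a, x$moses_b,
              if (is.na(x$ausroc)) "undefined (|b| >= 1)" else sprintf("%.*f", digits, x$ausroc),
              x$ausroc_ci[1], x$ausroc_ci[2]))
  invisible(x)
}

#' Diagnostic meta-analysis stratified by cut-off band
#'
#' Runs [sroc_moses()] within each cut-off band present in the table
#' (bands with fewer than 3 studies are skipped with a warning) and
#' returns one summary per band plus a table shaped like a diagnostic
#' summary table (band, k, pooled spec CI, sens CI, AUSROC CI).
#'
#' @inheritParams sroc_moses
#' @return list with `summaries` (named list of `sroc_summary`) and
#'   `table` (data.frame).
#' @export
diagnostic_meta_by_group <- function(studies, correction = 0.5,
                                     weighted = FALSE, alpha = 0.05,
                                     boot = 2000, seed = NULL) {
  if (!"cutoff_group" %in% names(studies))
    stopf("diagnostic_meta_by_group: studies need a cutoff_group column")
  groups <- split(studies, studies$cutoff_group)
  summaries <- list()
  for (g in names(groups)) {
    if (nrow(groups[[g]]) < 3) {
      warnf("cut-off band %s has %d studies (< 3); skipped", g, nrow(groups[[g]]))
      next
    }
    summaries[[g]] <- sroc_moses(groups[[g]], correction = correction,
                                 weighted = weighted, alpha = alpha,
                                 boot = boot, seed = seed)
  }
  table <- do.call(rbind, lapply(names(summaries), function(g) {
    s <- summaries[[g]]
    data.frame(cutoff_group = g, k = s$k,
               spec = s$pooled_spec$est_pooled,
               spec_low = s$pooled_spec$ci_low, spec_high = s$pooled_spec$ci_high,
               sens = s$pooled_sens$est_pooled,
               sens_low = s$pooled_sens$ci_low, sens_high = s$pooled_sens$ci_high,
               plr = s$pooled_plr$est_pooled, nlr = s$pooled_nlr$est_pooled,
               ausroc = s$ausroc, ausroc_low = s$ausroc_ci[1],
               ausroc_high = s$ausroc_ci[2], utility = s$utility,
               stringsAsFactors = FALSE)
  }))
  list(summaries = summaries, table = table)
}

#' Likelihood-ratio matrix rows
#'
#' One row per study with its (corrected) PLR, NLR and clinical-utility
#' quadrant, ready to write as the likelihood-matrix report.
#'
#' @inheritParams sens_spec
#' @return data.frame `study_id, cutoff_group, plr, nlr, quadrant`.
#' @export
lr_matrix <- function(studies, correction = 0.5) {
  ss <- sens_spec(studies, correction = correction)
  lr <- plr_nlr(ss$sens, ss$spec)
  data.frame(study_id = ss$study_id,
             cutoff_group = if ("cutoff_group" %in% names(studies))
               studies$cutoff_group else NA_character_,
             plr = lr$plr, nlr = lr$nlr,
             quadrant = lr_classify(lr$plr, lr$nlr),
             stringsAsFactors = FALSE)
}
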