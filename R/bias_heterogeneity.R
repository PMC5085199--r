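## Small-study-effect diagnostics (Egger regression, Begg rank correlation)
## and plot-ready funnel / Galbraith coordinates.

#' Egger regression test for small-study effects
#'
#' Regresses the standardized effect \eqn{y_i/se_i} on the precision
#' \eqn{1/se_i} by ordinary least squares and t-tests the intercept against
#' zero on `k - 2` df.  A nonzero intercept signals funnel-plot asymmetry.
#' (This parameterization is algebraically the weighted regression of
#' \eqn{y_i} on \eqn{se_i} with weights \eqn{1/v_i}; the slope estimates the
#' underlying pooled effect.)
#'
#' @param estimates an `estimates` data.frame with at least 3 studies and
#'   at least two distinct standard errors.
#' @return object of class `egger_result`: `intercept`, `intercept_se`,
#'   `t`, `p`, `slope`, `df`.
#' @export
egger_test <- function(estimates) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 3) stopf("egger_test: need at least 3 studies (df = k - 2 >= 1)")
  se <- sqrt(estimates$v)
  if (length(unique(round(se, 12))) < 2)
    stopf("egger_test: all standard errors equal; precision is collinear with the intercept")
  x <- 1 / se
  z <- estimates$y / se
  fit <- stats::lm(z ~ x)
  co <- summary(fit)$coefficients
  structure(list(intercept = co[1, 1], intercept_se = co[1, 2],
                 t = co[1, 3], p = co[1, 4], slope = co[2, 1],
                 df = k - 2L, k = k), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger regression test (k = %d): intercept = %.4f (SE %.4f), t = %.3f on %d df, p = %.4f\n",
              x$k, x$intercept, x$intercept_se, x$t, x$df, x$p))
  invisible(x)
}

## Kendall S statistic (sum over pairs of sign products) and tie-corrected tau
.kendall_S <- function(x, y) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  sum(sign(x[pairs[1, ]] - x[pairs[2, ]]) * sign(y[pairs[1, ]] - y[pairs[2, ]]))
}

.kendall_tau_b <- function(x, y) {
  n <- length(x)
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  S <- .kendall_S(x, y)
  denom <- sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
  if (denom == 0) stopf("begg_test: all values tied in one variable; tau undefined")
  list(S = S, tau = S / denom, tied = tie_term(x) > 0 || tie_term(y) > 0)
}

## exact two-sided p for S by enumeration over all permutations of y
.kendall_exact_p <- function(x, y) {
  n <- length(x)
  pr <- utils::combn(n, 2); i1 <- pr[1, ]; i2 <- pr[2, ]
  sx <- sign(x[i1] - x[i2])
  sy <- sign(outer(y, y, "-"))
  S_obs <- sum(sx * sy[cbind(i1, i2)])
  perms <- .permutations(n)
  S_all <- vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    sum(sx * sy[cbind(p[i1], p[i2])])
  }, numeric(1))
  mean(abs(S_all) >= abs(S_obs))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

#' Begg and Mazumdar adjusted rank correlation test
#'
#' Kendall correlation between the standardized effect deviates
#' \eqn{(y_i - \bar y_F)/\sqrt{v_i - 1/\sum w}} (where \eqn{\bar y_F} is the
#' fixed-effect pooled value) and the sampling variances \eqn{v_i}.  For
#' `k <= 8` the p-value is exact, by enumeration over all permutations of
#' the variance ranks; for larger k a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param estimates an `estimates` data.frame with at least 3 studies.
#' @return object of class `begg_result`: `kendall_tau`, `p`,
#'   `continuity_corrected` (TRUE when the normal approximation was used),
#'   `ties` flag.
#' @export
begg_test <- function(estimates) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 3) stopf("begg_test: need at least 3 studies")
  w <- 1 / estimates$v
  y_f <- sum(w * estimates$y) / sum(w)
  v_star <- estimates$v - 1 / sum(w)
  if (any(v_star <= 0))
    v_star <- pmax(v_star, .Machine$double.eps)  # guard: dominant single study
  u <- (estimates$y - y_f) / sqrt(v_star)
  kb <- .kendall_tau_b(u, estimates$v)
  if (k <= 8) {
    p <- .kendall_exact_p(u, estimates$v)
    cc <- FALSE
  } else {
    n <- k
    tcnt <- function(v) table(v)[table(v) > 1]
    varS <- n * (n - 1) * (2 * n + 5)
    for (v in list(u, estimates$v)) {
      t <- as.numeric(tcnt(v))
      if (length(t)) varS <- varS - sum(t * (t - 1) * (2 * t + 5))
    }
    varS <- varS / 18
    t1 <- as.numeric(tcnt(u)); t2 <- as.numeric(tcnt(estimates$v))
    if (length(t1) && length(t2)) {
      varS <- varS +
        sum(t1 * (t1 - 1)) * sum(t2 * (t2 - 1)) / (2 * n * (n - 1)) +
        sum(t1 * (t1 - 1) * (t1 - 2)) * sum(t2 * (t2 - 1) * (t2 - 2)) /
          (9 * n * (n - 1) * (n - 2))
    }
    zst <- if (kb$S == 0) 0 else (kb$S - sign(kb$S)) / sqrt(varS)
    p <- 2 * stats::pnorm(-abs(zst))
    cc <- TRUE
  }
  structure(list(kendall_tau = kb$tau, p = min(p, 1), k = k,
                 continuity_corrected = cc, ties = kb$tied),
            class = "begg_result")
}

#' @export
print.begg_result <- function(x, ...) {
  cat(sprintf("Begg adjusted rank correlation test (k = %d): tau = %.4f, p = %.4f%s\n",
              x$k, x$kendall_tau, x$p,
              if (x$continuity_corrected) " (normal approx., continuity corrected)" else " (exact)"))
  invisible(x)
}

#' Funnel plot coordinates
#'
#' One point per study (effect, standard error) plus pseudo-confidence
#' guide lines \eqn{\bar y \pm z_{1-\alpha/2} \cdot se} over
#' `se` in `[0, max(se)]`, symmetric about the pooled effect.
#'
#' @param estimates an `estimates` data.frame.
#' @param pooled a `pooled_result` providing the centre line.
#' @param n_guide number of guide-line support points (endpoints included).
#' @return list with `points` (study_id, y, se) and `guides`
#'   (se, lower, upper) data.frames.
#' @export
funnel_data <- function(estimates, pooled, n_guide = 50) {
  estimates <- .as_estimates(estimates)
  stopifnot(inherits(pooled, "pooled_result"))
  se <- sqrt(estimates$v)
  zc <- stats::qnorm(1 - pooled$alpha / 2)
  grid <- seq(0, max(se), length.out = n_guide)
  list(points = data.frame(study_id = estimates$study_id, y = estimates$y,
                           se = se, stringsAsFactors = FALSE),
       guides = data.frame(se = grid,
                           lower = pooled$y_pooled - zc * grid,
                           upper = pooled$y_pooled + zc * grid))
}

#' Galbraith (radial) plot coordinates with outlier flags
#'
#' Plots the standardized effect \eqn{z_i = y_i/se_i} against the precision
#' \eqn{x_i = 1/se_i}.  The reference line is the no-intercept weighted fit
#' \eqn{\hat b = \sum x_i z_i / \sum x_i^2} (identically the fixed-effect
#' pooled estimate).  Studies whose residual from that line exceeds 2 in
#' absolute value (strictly) are flagged as heterogeneity contributors —
#' the conventional +/-2 band of the radial plot.
#'
#' @param estimates an `estimates` data.frame with at least 2 studies.
#' @return data.frame with `study_id, x, y, residual, outlier`; the fitted
#'   slope is attached as attribute `slope` and the flagged count as
#'   `n_outliers`.
#' @export
galbraith_data <- function(estimates) {
  estimates <- .as_estimates(estimates)
  if (nrow(estimates) < 2) stopf("galbraith_data: need at least 2 studies")
  se <- sqrt(estimates$v)
  x <- 1 / se
  z <- estimates$y / se
  b <- sum(x * z) / sum(x^2)
  resid <- z - b * x
  out <- data.frame(study_id = estimates$study_id, x = x, y = z,
                    residual = resid, outlier = abs(resid) > 2,
                    stringsAsFactors = FALSE)
  attr(out, "slope") <- b
  attr(out, "n_outliers") <- sum(out$outlier)
  out
}
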