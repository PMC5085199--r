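## Random-effects meta-regression with REML estimation of the residual
## between-study variance.

## design matrix + coding record from a covariate table
.code_covariates <- function(covariates, moderators) {
  coding <- list()
  cols <- list()
  for (m in moderators) {
    x <- covariates[[m]]
    if (is.numeric(x)) {
      cols[[m]] <- x
      coding[[m]] <- list(type = "numeric")
    } else if (m == "size_class" ||
               all(unique(stats::na.omit(as.character(x))) %in%
                   c("small", "moderate", "large"))) {
      ## ordered class index: small = 0, moderate = 1, large = 2
      idx <- match(as.character(x), c("small", "moderate", "large")) - 1L
      cols[[m]] <- idx
      coding[[m]] <- list(type = "ordered_index",
                          levels = c(small = 0, moderate = 1, large = 2))
    } else {
      f <- factor(as.character(x))
      if (nlevels(f) < 2)
        stopf("meta_regress: covariate '%s' is constant across studies", m)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(m, ":", levels(f)[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
      coding[[m]] <- list(type = "treatment", reference = levels(f)[1],
                          levels = levels(f))
    }
  }
  X <- cbind(intercept = rep(1, nrow(covariates)), do.call(cbind, cols))
  list(X = X, coding = coding)
}

## restricted log-likelihood of tau2 for y ~ X with known sampling variances v
.reml_loglik <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  beta <- solve(XtWX, XtW %*% y)
  r <- y - X %*% beta
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus +
            sum(w * r^2))
}

#' Random-effects meta-regression (REML)
#'
#' Fits \eqn{y_i = x_i'\beta + u_i + \epsilon_i} with
#' \eqn{u_i \sim N(0, \tau^2)} and known sampling variances
#' \eqn{\epsilon_i \sim N(0, v_i)}.  The residual between-study variance
#' \eqn{\tau^2} is estimated by restricted maximum likelihood (bounded
#' one-dimensional search, convergence tolerance 1e-8, truncation at 0);
#' coefficients come from weighted least squares at \eqn{\hat\tau^2} with
#' normal (z) tests.
#'
#' Categorical covariates are coded automatically: `size_class` as an
#' ordered index (small/moderate/large = 0/1/2), other factors by treatment
#' contrasts against the alphabetically first level.  The coding used is
#' returned in `covariate_coding`.  Moderators are tested singly by
#' default; pass `joint = TRUE` to fit several at once.
#'
#' @param estimates an `estimates` data.frame (see [log_rom()]).
#' @param covariates data.frame keyed by `study_id` with covariate columns.
#' @param moderators character vector of covariate column names (default:
#'   all non-`study_id` columns).
#' @param method `"reml"` (the only implemented estimator).
#' @param joint fit all moderators in one model instead of requiring one.
#' @param tau2_max upper bound of the REML search.
#' @return object of class `meta_regression_fit`: `coefficients`
#'   (data.frame with estimate, se, z, p), `tau_squared_resid`, `k`,
#'   `covariate_coding`.
#' @export
meta_regress <- function(estimates, covariates, moderators = NULL,
                         method = "reml", joint = FALSE, tau2_max = 10) {
  method <- match.arg(method, "reml")
  estimates <- .as_estimates(estimates)
  if (!"study_id" %in% names(covariates))
    stopf("meta_regress: covariate table needs a study_id column")
  moderators <- moderators %||% setdiff(names(covariates), "study_id")
  if (length(moderators) > 1 && !joint)
    stopf("meta_regress: %d moderators supplied; modifiers are tested singly by default (set joint = TRUE for a joint model)",
          length(moderators))
  idx <- match(estimates$study_id, covariates$study_id)
  if (anyNA(idx))
    stopf("meta_regress: no covariates for study/studies %s",
          paste(estimates$study_id[is.na(idx)], collapse = ", "))
  covariates <- covariates[idx, , drop = FALSE]
  for (m in moderators) {
    if (!m %in% names(covariates))
      stopf("meta_regress: unknown covariate '%s'", m)
    if (length(unique(covariates[[m]])) < 2)
      stopf("meta_regress: covariate '%s' is constant across studies", m)
    if (anyNA(covariates[[m]]))
      stopf("meta_regress: covariate '%s' has missing values", m)
  }

  coded <- .code_covariates(covariates, moderators)
  X <- coded$X
  y <- estimates$y
  v <- estimates$v
  k <- length(y)
  p <- ncol(X)
  if (k < p + 2)
    stopf("meta_regress: %d studies cannot support %d coefficients (need k >= p + 2)", k, p)
  if (qr(X)$rank < p) stopf("meta_regress: singular design (collinear covariates)")

  opt <- stats::optimize(function(t2) .reml_loglik(t2, y, v, X),
                         interval = c(0, tau2_max), maximum = TRUE, tol = 1e-8)
  ## optimize() can miss the boundary; prefer 0 when it is at least as good
  tau2 <- if (.reml_loglik(0, y, v, X) >= opt$objective) 0 else opt$maximum

  w <- 1 / (v + tau2)
  XtWX <- t(X * w) %*% X
  beta <- drop(solve(XtWX, t(X * w) %*% y))
  vcov <- solve(XtWX)
  se <- sqrt(diag(vcov))
  z <- beta / se
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta, se = se,
                              z = z, p = 2 * stats::pnorm(-abs(z)),
                              row.names = NULL, stringsAsFactors = FALSE),
    tau_squared_resid = tau2,
    k = k,
    covariate_coding = coded$coding,
    vcov = vcov,
    reml_loglik = .reml_loglik(tau2, y, v, X),
    moderators = moderators
  ), class = "meta_regression_fit")
}

#' @export
print.meta_regression_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects meta-regression (REML), k = %d, residual tau2 = %.4g\n",
              x$k, x$tau_squared_resid))
  co <- x$coefficients
  co[] <- lapply(co, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Test study-level effect modifiers one at a time
#'
#' Convenience wrapper running [meta_regress()] once per moderator, the way
#' candidate sources of heterogeneity (ethnicity, sample size, design,
#' quality, ...) are usually screened.
#'
#' @inheritParams meta_regress
#' @return named list of `meta_regression_fit` objects.
#' @export
meta_regress_each <- function(estimates, covariates, moderators = NULL,
                              method = "reml") {
  moderators <- moderators %||% setdiff(names(covariates), "study_id")
  stats::setNames(lapply(moderators, function(m)
    meta_regress(estimates, covariates, moderators = m, method = method)),
    moderators)
}
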