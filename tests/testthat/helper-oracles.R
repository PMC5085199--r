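# Independent brute-force oracles. These deliberately use different code
# paths (explicit loops, full-matrix algebra, dense grids) from the package
# implementation so that agreement is informative.

make_estimates <- function(y, v,
                           ids = if (length(y)) paste0("s", seq_along(y)) else character(0),
                           measure = "log_rom") {
  data.frame(study_id = ids, y = y, v = v,
             measure = rep_len(measure, length(y)), stringsAsFactors = FALSE)
}

# direct-summation fixed-effect + DerSimonian-Laird oracle
oracle_dl <- function(y, v, alpha = 0.05) {
  k <- length(y)
  w <- numeric(k); for (i in 1:k) w[i] <- 1 / v[i]
  sw <- 0; swy <- 0; sw2 <- 0
  for (i in 1:k) { sw <- sw + w[i]; swy <- swy + w[i] * y[i]; sw2 <- sw2 + w[i]^2 }
  yf <- swy / sw
  Q <- 0; for (i in 1:k) Q <- Q + w[i] * (y[i] - yf)^2
  C <- sw - sw2 / sw
  tau2 <- if (k >= 2 && C > 0) max(0, (Q - (k - 1)) / C) else 0
  ws <- numeric(k); for (i in 1:k) ws[i] <- 1 / (v[i] + tau2)
  sws <- sum(ws)
  yr <- sum(ws * y) / sws
  list(y_fixed = yf, se_fixed = sqrt(1 / sw), Q = Q, tau2 = tau2,
       y_random = yr, se_random = sqrt(1 / sws),
       w_fixed = w / sw, w_random = ws / sws)
}

# closed-form two-parameter least squares (normal equations)
oracle_ols2 <- function(x, z) {
  n <- length(x)
  sx <- sum(x); sz <- sum(z); sxx <- sum(x^2); sxz <- sum(x * z)
  slope <- (n * sxz - sx * sz) / (n * sxx - sx^2)
  intercept <- (sz - slope * sx) / n
  resid <- z - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_int <- sqrt(s2 * sxx / (n * sxx - sx^2))
  list(intercept = intercept, slope = slope, se_intercept = se_int,
       t = intercept / se_int, p = 2 * pt(-abs(intercept / se_int), n - 2))
}

# restricted log-likelihood via full-matrix algebra (dense V, generic solve)
oracle_reml_loglik <- function(tau2, y, v, X) {
  V <- diag(v + tau2, length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX) %*% t(X) %*% Vi %*% y
  r <- y - X %*% beta
  -0.5 * (sum(log(diag(V))) + log(det(XtViX)) + drop(t(r) %*% Vi %*% r))
}

oracle_reml_grid <- function(y, v, X, grid = seq(0, 5, by = 1e-3)) {
  ll <- vapply(grid, function(t2) oracle_reml_loglik(t2, y, v, X), numeric(1))
  list(tau2 = grid[which.max(ll)], loglik = max(ll), grid = grid, ll = ll)
}

# Kendall S and exact permutation p by direct enumeration (recursive perms)
oracle_kendall <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[i] - x[j]) * sign(y[i] - y[j])
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  Sp <- vapply(perm_all(seq_len(n)), function(p) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(x[i] - x[j]) * sign(y[p[i]] - y[p[j]])
    s
  }, numeric(1))
  list(S = S, p = mean(abs(Sp) >= abs(S)))
}

# a small heterogeneous toy set used across oracle-equivalence tests
toy_sets <- list(
  list(y = c(0.2, -0.1, 0.5), v = c(0.04, 0.09, 0.02)),
  list(y = c(1.1, 0.9, 1.4, 0.6), v = c(0.2, 0.05, 0.5, 0.1)),
  list(y = c(0, 0.3, -0.2, 0.8, 0.1, 0.45), v = c(0.01, 0.04, 0.02, 0.3, 0.07, 0.12))
)
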