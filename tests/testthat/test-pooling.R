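test_that("a single study is returned as itself", {
  e <- make_estimates(0.4, 0.09)
  f <- pool_fixed(e)
  expect_equal(f$y_pooled, 0.4)
  expect_equal(f$se_pooled, 0.3)
  expect_equal(f$Q, 0)
  r <- pool_dl(e)
  expect_equal(r$y_pooled, 0.4)
  expect_equal(r$tau_squared, 0)
  expect_error(pool_fixed(make_estimates(numeric(0), numeric(0))), "at least one")
})

test_that("two equal-variance studies pool to their midpoint with Q = 0.5", {
  e <- make_estimates(c(0, 1), c(1, 1))
  f <- pool_fixed(e)
  expect_equal(f$y_pooled, 0.5)
  expect_equal(f$Q, 0.5)
  # Q = 0.5 <= df = 1, so tau2 truncates to zero and random equals fixed
  r <- pool_dl(e)
  expect_equal(r$tau_squared, 0)
  expect_equal(r$y_pooled, f$y_pooled)
  expect_equal(r$se_pooled, f$se_pooled)
})

test_that("identical estimates show no heterogeneity", {
  e <- make_estimates(rep(0.3, 5), rep(0.04, 5))
  r <- pool_dl(e)
  expect_equal(r$y_pooled, 0.3)
  expect_equal(r$Q, 0)
  expect_equal(r$i_squared, 0)
  expect_equal(r$tau_squared, 0)
})

test_that("pooling agrees with the direct-summation oracle to 1e-10", {
  for (tset in toy_sets) {
    o <- oracle_dl(tset$y, tset$v)
    e <- make_estimates(tset$y, tset$v)
    f <- pool_fixed(e); r <- pool_dl(e)
    expect_equal(f$y_pooled, o$y_fixed, tolerance = 1e-10)
    expect_equal(f$se_pooled, o$se_fixed, tolerance = 1e-10)
    expect_equal(f$Q, o$Q, tolerance = 1e-10)
    expect_equal(r$tau_squared, o$tau2, tolerance = 1e-10)
    expect_equal(r$y_pooled, o$y_random, tolerance = 1e-10)
    expect_equal(r$se_pooled, o$se_random, tolerance = 1e-10)
    expect_equal(unname(r$weights), o$w_random, tolerance = 1e-10)
    # invariants: weights sum to one, pooled value inside the data range
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    expect_true(f$y_pooled >= min(tset$y) && f$y_pooled <= max(tset$y))
    expect_true(r$se_pooled >= f$se_pooled - 1e-14)
  }
})

test_that("pooling matches metafor's DerSimonian-Laird fit", {
  skip_if_not_installed("metafor")
  for (tset in toy_sets) {
    fit <- metafor::rma(yi = tset$y, vi = tset$v, method = "DL")
    r <- pool_dl(make_estimates(tset$y, tset$v))
    expect_equal(r$y_pooled, as.numeric(fit$beta), tolerance = 1e-8)
    expect_equal(r$se_pooled, fit$se, tolerance = 1e-8)
    expect_equal(r$tau_squared, fit$tau2, tolerance = 1e-8)
    expect_equal(r$Q, fit$QE, tolerance = 1e-8)
  }
})

test_that("I-squared follows (Q - df)/Q with truncation at zero", {
  expect_equal(i_squared(10, 5), 0.5)
  expect_equal(i_squared(3, 5), 0)
  expect_equal(i_squared(200, 55), 0.725)
  expect_equal(i_squared(0, 5), 0)
  expect_error(i_squared(-1, 5), "non-negative")
  expect_error(i_squared(10, 0), "positive integer")
  # monotone increasing in Q at fixed df
  qs <- seq(6, 60, by = 3)
  expect_true(all(diff(i_squared(qs, 5)) > 0))
})

test_that("dominant heterogeneity drives random-effects weights toward 1/k", {
  # tiny sampling variances + wildly different effects force a huge tau2,
  # the equal-weighting limit of the DL estimator
  e <- make_estimates(c(-5, 0, 5, 10), rep(1e-6, 4))
  r <- pool_dl(e)
  expect_true(r$tau_squared > 1)
  expect_equal(unname(r$weights), rep(0.25, 4), tolerance = 1e-4)
})

test_that("subgroup pooling equals pooling of the manual subsets", {
  sim <- simulate_rom_studies(rom_sim_config(k = 24, seed = 9))
  grp <- subgroup_pool(sim$studies, "ethnicity")
  expect_setequal(names(grp), unique(sim$studies$ethnicity))
  expect_equal(sum(vapply(grp, `[[`, 0, "k")), nrow(sim$studies))
  for (lev in names(grp)) {
    manual <- pool_dl(log_rom(sim$studies[sim$studies$ethnicity == lev, ]))
    expect_equal(grp[[lev]]$y_pooled, manual$y_pooled)
    expect_equal(grp[[lev]]$tau_squared, manual$tau_squared)
  }
  # missing factor values form their own level
  s2 <- sim$studies
  s2$tnm_stage <- NA_character_
  s2$tnm_stage[1:5] <- "I_II"
  grp2 <- subgroup_pool(s2, "tnm_stage")
  expect_setequal(names(grp2), c("I_II", "unknown"))
  expect_equal(grp2$unknown$k, nrow(s2) - 5)
  expect_error(subgroup_pool(sim$studies, "no_such_field"), "not a column")
})

test_that("the two-sample contrast behaves as a normal z-test", {
  e1 <- make_estimates(c(0.2, 0.3, 0.4), c(0.02, 0.03, 0.04))
  a <- pool_dl(e1)
  expect_equal(compare_two_pooled(a, a)$z, 0)
  expect_equal(compare_two_pooled(a, a)$p, 1)
  # construct b displaced by exactly 1.96 joint SEs
  b <- a
  b$y_pooled <- a$y_pooled + 1.96 * sqrt(2) * a$se_pooled
  ct <- compare_two_pooled(a, b)
  expect_equal(abs(ct$z), 1.96)
  expect_equal(ct$p, 2 * pnorm(-1.96))
  # antisymmetry of z, symmetry of p
  expect_equal(compare_two_pooled(b, a)$z, -ct$z)
  expect_equal(compare_two_pooled(b, a)$p, ct$p)
})

test_that("leave-one-out reproduces pooling on each manual subset", {
  tset <- toy_sets[[3]]
  e <- make_estimates(tset$y, tset$v)
  loo <- leave_one_out(e)
  expect_length(loo, nrow(e))
  for (i in seq_len(nrow(e))) {
    manual <- pool_dl(e[-i, ])
    expect_equal(loo[[e$study_id[i]]]$y_pooled, manual$y_pooled)
    expect_equal(loo[[e$study_id[i]]]$tau_squared, manual$tau_squared)
  }
  expect_error(leave_one_out(e[1:2, ]), "at least 3")
})

test_that("omitting an extreme outlier minimizes the residual heterogeneity", {
  e <- make_estimates(c(0.3, 0.32, 0.29, 0.31, 5), rep(0.01, 5))
  loo <- leave_one_out(e)
  taus <- vapply(loo, `[[`, 0, "tau_squared")
  expect_equal(names(which.min(taus)), "s5")
  # homogeneous studies: every omission gives the same pooled value
  eh <- make_estimates(rep(0.4, 4), rep(0.02, 4))
  looh <- leave_one_out(eh)
  expect_true(all(abs(vapply(looh, `[[`, 0, "y_pooled") - 0.4) < 1e-14))
})
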