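dstudy <- function(tp, fp, fn, tn, id = "d1", group = "1.5to2.5")
  data.frame(study_id = id, cutoff_group = group, tp = tp, fp = fp,
             fn = fn, tn = tn, stringsAsFactors = FALSE)

test_that("per-study sensitivity/specificity and logit variances", {
  ss <- sens_spec(dstudy(50, 25, 50, 75))
  expect_equal(ss$sens, 0.5)
  expect_equal(ss$spec, 0.75)
  expect_equal(ss$v_logit_sens, 1 / 50 + 1 / 50)
  expect_false(ss$corrected)
  # zero cell: 0.5 added to every cell of that study
  ss0 <- sens_spec(dstudy(10, 5, 0, 20))
  expect_equal(ss0$sens, 10.5 / 11)
  expect_true(ss0$corrected)
  expect_equal(ss0$v_logit_sens, 1 / 10.5 + 1 / 0.5)
  expect_error(sens_spec(dstudy(0, 5, 0, 20)), "at least one")
})

test_that("logit-scale pooling back-transforms through the inverse logit", {
  # identical studies pool to the common proportion
  e <- make_estimates(rep(qlogis(0.7), 4), rep(0.05, 4), measure = "logit_sens")
  p <- pool_logit(e)
  expect_equal(p$est_pooled, 0.7)
  # two studies at logits 0 and 1, equal variance, Q <= df: pooled logit 0.5
  e2 <- make_estimates(c(0, 1), c(4, 4), measure = "logit_sens")
  p2 <- pool_logit(e2)
  expect_equal(p2$y_pooled, 0.5)
  expect_equal(p2$est_pooled, plogis(0.5))
  expect_equal(p2$est_pooled, 0.6225, tolerance = 1e-4)
  # shares the DL engine exactly
  p3 <- pool_dl(e2)
  expect_equal(p2$y_pooled, p3$y_pooled)
  expect_equal(p2$tau_squared, p3$tau_squared)
  # strictly inside the study range for non-identical inputs
  expect_true(p2$est_pooled > plogis(0) && p2$est_pooled < plogis(1))
  expect_error(pool_logit(make_estimates(0.5, 0.1, measure = "log_rom")),
               "logit scale")
})

test_that("likelihood ratios follow their defining formulas", {
  lr <- plr_nlr(0.5, 0.75)
  expect_equal(lr$plr, 2)
  expect_equal(lr$nlr, 2 / 3)
  lr2 <- plr_nlr(0.95, 0.90)
  expect_equal(lr2$plr, 9.5)
  expect_equal(lr2$nlr, 0.05 / 0.9)
  # chance line: sens = 1 - spec gives PLR exactly 1
  expect_equal(plr_nlr(0.3, 0.7)$plr, 1)
  expect_error(plr_nlr(0.5, 1), "strictly")
  expect_error(plr_nlr(0, 0.5), "strictly")
})

test_that("the clinical-utility quadrant uses strict thresholds", {
  expect_equal(lr_classify(15, 0.05), "clinically_useful")
  expect_equal(lr_classify(15, 0.5), "confirmation_only")
  expect_equal(lr_classify(2, 0.05), "exclusion_only")
  expect_equal(lr_classify(2, 0.5), "not_useful")
  # boundary values fail both strict inequalities
  expect_equal(lr_classify(10, 0.1), "not_useful")
})

test_that("studies on the chance diagonal give a flat SROC with area one half", {
  # TPR = FPR for every study at different thresholds
  studies <- rbind(dstudy(20, 20, 80, 80, "c1"),
                   dstudy(50, 50, 50, 50, "c2"),
                   dstudy(80, 80, 20, 20, "c3"))
  s <- sroc_moses(studies, boot = 0)
  expect_equal(s$moses_a, 0, tolerance = 1e-10)
  expect_equal(s$moses_b, 0, tolerance = 1e-10)
  expect_equal(s$ausroc, 0.5, tolerance = 1e-8)
  expect_equal(s$pooled_plr$est_pooled, 1, tolerance = 1e-10)
})

test_that("symmetric SROC area matches quadrature of the closed-form curve", {
  # constant diagnostic odds ratio across studies -> b = 0, a = log(DOR)
  dor <- 9
  studies <- rbind(dstudy(60, 10, 40, 60, "s1"),   # odds 1.5 vs 1/6
                   dstudy(75, 25, 25, 75, "s2"),   # odds 3 vs 1/3
                   dstudy(90, 50, 10, 50, "s3"))   # odds 9 vs 1
  ss <- sens_spec(studies)
  dors <- (ss$tp / ss$fn) / (ss$fp / ss$tn)
  expect_equal(dors, rep(dor, 3))
  s <- sroc_moses(studies, boot = 0)
  expect_equal(s$moses_b, 0, tolerance = 1e-10)
  expect_equal(s$moses_a, log(dor), tolerance = 1e-10)
  oracle_area <- integrate(function(x) plogis(log(dor) + qlogis(x)), 0, 1,
                           rel.tol = 1e-10)$value
  expect_equal(s$ausroc, oracle_area, tolerance = 1e-8)
})

test_that("SROC area grows with the intercept and is permutation invariant", {
  areas <- vapply(c(0.5, 1, 2, 3), function(a) sroc_curve(0.5, a, 0), 0)
  expect_true(all(diff(areas) > 0))
  studies <- rbind(dstudy(55, 12, 20, 70, "p1"), dstudy(40, 8, 30, 80, "p2"),
                   dstudy(70, 30, 15, 55, "p3"), dstudy(62, 20, 25, 61, "p4"))
  s1 <- sroc_moses(studies, boot = 50, seed = 5)
  s2 <- sroc_moses(studies[c(3, 1, 4, 2), ], boot = 50, seed = 5)
  expect_equal(s1$moses_a, s2$moses_a)
  expect_equal(s1$moses_b, s2$moses_b)
  expect_equal(s1$ausroc, s2$ausroc)
  expect_equal(s1$pooled_sens$est_pooled, s2$pooled_sens$est_pooled)
})

test_that("a highly accurate toy set yields a high SROC area", {
  studies <- rbind(dstudy(95, 10, 5, 90, "h1"), dstudy(90, 4, 10, 96, "h2"),
                   dstudy(97, 8, 3, 92, "h3"))
  s <- sroc_moses(studies, boot = 0)
  expect_gt(s$ausroc, 0.9)
  expect_gt(s$pooled_sens$est_pooled, 0.9)
})

test_that("a non-monotone back-transform reports coefficients but no area", {
  # engineer |b| >= 1: D strongly increasing in S
  studies <- rbind(dstudy(10, 40, 90, 60, "m1"),
                   dstudy(50, 30, 50, 70, "m2"),
                   dstudy(95, 20, 5, 80, "m3"))
  fit_b <- sroc_moses(studies, boot = 0)
  if (abs(fit_b$moses_b) >= 1) {
    expect_true(is.na(fit_b$ausroc))
  } else {
    expect_false(is.na(fit_b$ausroc))  # guard: construction not extreme enough
  }
  expect_error(sroc_moses(studies[1:2, ]), "at least 3")
})

test_that("cut-off band assignment respects the named bands and the gap", {
  expect_equal(assign_cutoff_group(c(0.3, 0.5, 1.5, 2.0, 4.0)),
               c("lt0.5", "0.5to1.5", "0.5to1.5", "1.5to2.5", "gt3.5"))
  expect_warning(g <- assign_cutoff_group(3.0), "no named band")
  expect_true(is.na(g))
})

test_that("group-stratified diagnostic meta-analysis mirrors per-band fits", {
  sim1 <- simulate_diagnostic_studies(diag_sim_config(k = 6, seed = 2,
                                                      cutoff_group = "lt0.5"))
  sim2 <- simulate_diagnostic_studies(diag_sim_config(k = 5, seed = 3,
                                                      cutoff_group = "gt3.5"))
  sim2$studies$study_id <- paste0("g4_", sim2$studies$study_id)
  both <- rbind(sim1$studies, sim2$studies)
  out <- diagnostic_meta_by_group(both, boot = 0)
  expect_setequal(names(out$summaries), c("lt0.5", "gt3.5"))
  expect_equal(out$summaries$lt0.5$k, 6)
  expect_equal(out$summaries$gt3.5$k, 5)
  ref <- sroc_moses(sim1$studies, boot = 0)
  expect_equal(out$summaries$lt0.5$moses_a, ref$moses_a)
  expect_equal(out$summaries$lt0.5$ausroc, ref$ausroc)
  lm <- lr_matrix(both)
  expect_equal(nrow(lm), nrow(both))
  expect_true(all(lm$quadrant %in% c("clinically_useful", "confirmation_only",
                                     "exclusion_only", "not_useful")))
})
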