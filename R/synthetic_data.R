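## Synthetic study-level data with known truth.
##
## The generator mirrors the generative structure the pooled analysis
## assumes: a between-study normal random effect on the log case/control
## mean ratio, strictly positive right-skewed within-study biomarker
## values (lognormal by default, gamma available), and -- when bin edges
## are supplied -- category counts tabulated from the *same* latent draws,
## so the ratio-of-means arm and the odds-ratio/diagnostic arm are
## internally consistent by construction.

#' Configuration for the ratio-of-means study generator
#'
#' Defaults emulate a literature of the kind the package analyses: 56
#' comparisons (the size of a typical biomarker meta-analysis corpus), a
#' true case/control ratio of 1.44 with between-study SD 0.3 on the log
#' scale, control means centred near 1.5 mU/L with 35\% between-study
#' spread, within-study coefficient of variation 0.8 (serum TSH is
#' strongly right-skewed), and sample sizes spanning the small (< 200
#' cases) to large (> 500 cases) bands.
#'
#' @param k number of studies.
#' @param true_log_rom true mean log ratio of means (mu).
#' @param tau between-study SD of the log ratio (>= 0).
#' @param control_mean_log_location,control_mean_log_scale meanlog/sdlog of
#'   the lognormal draw of each study's control-arm mean, mU/L.
#' @param cv_case,cv_control within-study coefficient of variation.
#' @param n_case_range,n_control_range integer ranges for per-arm sample
#'   sizes (drawn uniformly).
#' @param small_study_effect bias added to each study's log ratio in
#'   proportion to its standard error (0 = none); positive values inflate
#'   imprecise studies, the signature of small-study effects.
#' @param bin_edges optional interior biomarker cut points, mU/L; when
#'   given, category counts are tabulated from the simulated values over
#'   the breaks `c(0, bin_edges, Inf)`.
#' @param family within-study distribution, `"lognormal"` or `"gamma"`.
#' @param seed integer seed; all randomness flows from it.
#' @return a `rom_sim_config` list.
#' @export
rom_sim_config <- function(k = 56, true_log_rom = log(1.44), tau = 0.3,
                           control_mean_log_location = log(1.5),
                           control_mean_log_scale = 0.35,
                           cv_case = 0.8, cv_control = 0.8,
                           n_case_range = c(30, 800),
                           n_control_range = c(50, 2000),
                           small_study_effect = 0, bin_edges = NULL,
                           family = c("lognormal", "gamma"), seed = 1) {
  family <- match.arg(family)
  stopifnot(k >= 1, tau >= 0, cv_case > 0, cv_control > 0,
            length(n_case_range) == 2, length(n_control_range) == 2,
            n_case_range[1] >= 1, n_control_range[1] >= 1,
            n_case_range[1] <= n_case_range[2],
            n_control_range[1] <= n_control_range[2])
  if (!is.null(bin_edges) && any(diff(bin_edges) <= 0))
    stopf("bin_edges must be strictly increasing")
  structure(as.list(environment()), class = "rom_sim_config")
}

## draw n positive values with mean m and coefficient of variation cv
.draw_positive <- function(n, m, cv, family) {
  if (family == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, rate = shape / m)
  }
}

#' Simulate ratio-of-means studies with known truth
#'
#' Per study i: the true log ratio is \eqn{\theta_i = \mu + \tau u_i}
#' (`u_i` standard normal); control values are drawn from a positive
#' right-skewed distribution with the study's control mean and
#' `cv_control`; case values likewise with mean multiplied by
#' \eqn{e^{\theta_i}}.  Observed means and SDs are *sample* statistics of
#' the drawn values, so the delta-method variance is exercised against
#' genuine sampling noise.  With `small_study_effect` s > 0, the observed
#' case mean is inflated by \eqn{e^{s\,\widehat{se}_i}} after drawing.
#' Category counts, when requested, are direct tabulations of the same
#' values.
#'
#' @param cfg a [rom_sim_config()].
#' @return list with `studies` (a validated study table), `categories`
#'   (list of [category_counts()] records, or `NULL`), and `truth`
#'   (`mu`, `tau`, per-study `theta`, `seed`).
#' @export
simulate_rom_studies <- function(cfg) {
  stopifnot(inherits(cfg, "rom_sim_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  theta <- cfg$true_log_rom + cfg$tau * stats::rnorm(k)
  n_case <- sample(cfg$n_case_range[1]:cfg$n_case_range[2], k, replace = TRUE)
  n_control <- sample(cfg$n_control_range[1]:cfg$n_control_range[2], k, replace = TRUE)
  ctrl_mean <- stats::rlnorm(k, cfg$control_mean_log_location,
                             cfg$control_mean_log_scale)
  ethnicity <- sample(c("Asian", "Caucasian", "Other"), k, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15))
  age_group <- sample(c("adult", "children"), k, replace = TRUE, prob = c(0.9, 0.1))
  design <- sample(c("retrospective_cross_sectional", "other"), k,
                   replace = TRUE, prob = c(0.8, 0.2))
  quality <- sample(5:9, k, replace = TRUE)

  rows <- vector("list", k)
  cats <- if (!is.null(cfg$bin_edges)) vector("list", k) else NULL
  breaks <- if (!is.null(cfg$bin_edges)) c(0, cfg$bin_edges, Inf)
  for (i in seq_len(k)) {
    x_ctrl <- .draw_positive(n_control[i], ctrl_mean[i], cfg$cv_control, cfg$family)
    x_case <- .draw_positive(n_case[i], ctrl_mean[i] * exp(theta[i]),
                             cfg$cv_case, cfg$family)
    m_case <- mean(x_case); s_case <- stats::sd(x_case)
    m_ctrl <- mean(x_ctrl); s_ctrl <- stats::sd(x_ctrl)
    if (cfg$small_study_effect != 0) {
      se_i <- sqrt(s_case^2 / (n_case[i] * m_case^2) +
                   s_ctrl^2 / (n_control[i] * m_ctrl^2))
      m_case <- m_case * exp(cfg$small_study_effect * se_i)
    }
    rows[[i]] <- data.frame(
      study_id = sprintf("sim%03d", i),
      label = sprintf("Synthetic study %d", i),
      ethnicity = ethnicity[i], age_group = age_group[i], design = design[i],
      quality_score = quality[i],
      n_case = n_case[i], n_control = n_control[i],
      mean_case = m_case, sd_case = s_case,
      mean_control = m_ctrl, sd_control = s_ctrl,
      stringsAsFactors = FALSE)
    if (!is.null(cats))
      cats[[i]] <- category_counts(
        sprintf("sim%03d", i), breaks,
        as.integer(table(cut(x_case, breaks, right = FALSE))),
        as.integer(table(cut(x_ctrl, breaks, right = FALSE))))
  }
  studies <- validate_rom_table(do.call(rbind, rows))
  if (!is.null(cats)) names(cats) <- studies$study_id
  list(studies = studies, categories = cats,
       truth = list(mu = cfg$true_log_rom, tau = cfg$tau, theta = theta,
                    seed = cfg$seed))
}

#' Configuration for the diagnostic-study generator
#'
#' Study-level (logit sensitivity, logit specificity) pairs are drawn from
#' a bivariate normal; cell counts are then binomial.  Defaults describe a
#' moderately accurate, moderately heterogeneous biomarker threshold:
#' mean sensitivity 0.75 and specificity 0.80 with SD 0.4 on the logit
#' scale and the negative sens/spec correlation characteristic of
#' threshold variation across studies.
#'
#' @param k number of studies.
#' @param mean_logit_sens,mean_logit_spec bivariate-normal means.
#' @param sd_logit_sens,sd_logit_spec between-study SDs (>= 0).
#' @param correlation sens/spec correlation in `[-1, 1]`.
#' @param n_case_range,n_control_range per-arm sample-size ranges.
#' @param cutoff_group band label stamped on every generated study.
#' @param seed integer seed.
#' @return a `diag_sim_config` list.
#' @export
diag_sim_config <- function(k = 25,
                            mean_logit_sens = stats::qlogis(0.75),
                            mean_logit_spec = stats::qlogis(0.80),
                            sd_logit_sens = 0.4, sd_logit_spec = 0.4,
                            correlation = -0.3,
                            n_case_range = c(50, 500),
                            n_control_range = c(50, 500),
                            cutoff_group = "1.5to2.5", seed = 1) {
  stopifnot(k >= 1, sd_logit_sens >= 0, sd_logit_spec >= 0,
            correlation >= -1, correlation <= 1,
            n_case_range[1] >= 1, n_control_range[1] >= 1)
  structure(as.list(environment()), class = "diag_sim_config")
}

#' Simulate diagnostic 2x2 studies with known truth
#'
#' Per study, `(logit sens, logit spec)` is drawn from the configured
#' bivariate normal; then `tp ~ Binomial(n_case, sens)` and
#' `tn ~ Binomial(n_control, spec)` with `fn`/`fp` as complements.
#'
#' @param cfg a [diag_sim_config()].
#' @return list with `studies` (validated diagnostic table) and `truth`
#'   (latent per-study sens/spec and the configured means).
#' @export
simulate_diagnostic_studies <- function(cfg) {
  stopifnot(inherits(cfg, "diag_sim_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  z1 <- stats::rnorm(k)
  z2 <- cfg$correlation * z1 + sqrt(1 - cfg$correlation^2) * stats::rnorm(k)
  l_sens <- cfg$mean_logit_sens + cfg$sd_logit_sens * z1
  l_spec <- cfg$mean_logit_spec + cfg$sd_logit_spec * z2
  sens <- expit(l_sens); spec <- expit(l_spec)
  n_case <- sample(cfg$n_case_range[1]:cfg$n_case_range[2], k, replace = TRUE)
  n_control <- sample(cfg$n_control_range[1]:cfg$n_control_range[2], k, replace = TRUE)
  tp <- stats::rbinom(k, n_case, sens)
  tn <- stats::rbinom(k, n_control, spec)
  studies <- validate_diagnostic_table(data.frame(
    study_id = sprintf("dsim%03d", seq_len(k)),
    cutoff_group = cfg$cutoff_group,
    tp = tp, fp = n_control - tn, fn = n_case - tp, tn = tn,
    stringsAsFactors = FALSE))
  list(studies = studies,
       truth = list(mean_logit_sens = cfg$mean_logit_sens,
                    mean_logit_spec = cfg$mean_logit_spec,
                    latent_sens = sens, latent_spec = spec, seed = cfg$seed))
}

#' Write a simulated bundle to the CSV dialects the readers accept
#'
#' Emits `studies.csv` (rom schema), optionally `categories.csv` (long
#' form) and `truth.json`; every table carries the seed in a header
#' comment.
#'
#' @param sim result of [simulate_rom_studies()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  header <- sprintf("# generated by rommeta simulate, seed %d", sim$truth$seed)
  p <- file.path(dir, "studies.csv")
  writeLines(header, p)
  suppressWarnings(utils::write.table(sim$studies, p, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE, na = ""))
  files <- c(files, p)
  if (!is.null(sim$categories)) {
    long <- do.call(rbind, lapply(sim$categories, function(r) {
      nb <- length(r$case_counts)
      data.frame(study_id = r$study_id, bin_low = r$bin_edges[seq_len(nb)],
                 bin_high = r$bin_edges[-1], case_count = r$case_counts,
                 control_count = r$control_counts, stringsAsFactors = FALSE)
    }))
    p <- file.path(dir, "categories.csv")
    writeLines(header, p)
    suppressWarnings(utils::write.table(long, p, sep = ",", row.names = FALSE,
                                        quote = FALSE, append = TRUE))
    files <- c(files, p)
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  invisible(files)
}
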