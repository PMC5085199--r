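## End-to-end pipeline: read -> effects -> pooling/subgroups/meta-regression
## -> bias diagnostics -> diagnostic arm -> table-shaped TSV reports plus a
## machine-readable JSON of every number (the single source of truth).

#' Analysis configuration
#'
#' @param studies path to a rom-schema study CSV, or an already validated
#'   study table.
#' @param categories optional path to a category-count CSV (or list of
#'   [category_counts()]), enabling the odds-ratio arm.
#' @param diagnostic optional path to a diagnostic CSV (or validated
#'   table), enabling the SROC arm.
#' @param convert_median treat the study CSV as median/min/max and convert.
#' @param subgroups factor columns to stratify by.
#' @param contrasts named list of two-level clinical factors to contrast
#'   (default: the optional tumour/stage/node/histology columns present).
#' @param moderators covariate columns for single-moderator meta-regression.
#' @param exposed_range,referent_range biomarker ranges (mU/L) defining the
#'   odds-ratio exposure and referent categories.
#' @param alpha two-sided CI level.
#' @param boot bootstrap resamples for the AUSROC CI.
#' @param seed integer seed for the (bootstrap) randomness.
#' @param out_dir directory for the TSV/JSON reports, or `NULL` to skip
#'   writing.
#' @param verbose print progress to stderr.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(studies, categories = NULL, diagnostic = NULL,
                            convert_median = FALSE,
                            subgroups = c("ethnicity", "age_group", "design",
                                          "size_class"),
                            contrasts = NULL,
                            moderators = c("ethnicity", "size_class",
                                           "design", "quality_score"),
                            exposed_range = c(4.2, Inf),
                            referent_range = c(0, 0.4),
                            alpha = 0.05, boot = 2000, seed = 1,
                            out_dir = NULL, verbose = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "analysis_config")
}

.pipeline_log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full meta-analysis pipeline
#'
#' Executes every stage the inputs support: overall fixed/random pooling of
#' the log ratio of means, subgroup tables, contrasts between two-level
#' clinical factors, single-moderator REML meta-regression, leave-one-out
#' sensitivity analysis, Egger and Begg tests, funnel and Galbraith
#' coordinates, category-count odds-ratio pooling, and the cut-off-banded
#' diagnostic SROC arm.  With `out_dir` set, table-shaped TSVs and a
#' `report.json` holding every computed number are written alongside a run
#' log.  The run is deterministic given inputs and seed.
#'
#' @param cfg an [analysis_config()].
#' @return the report bundle (named list), invisibly when writing.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  studies <- .stage("study_io", {
    if (is.character(cfg$studies))
      read_study_table(cfg$studies, "rom", convert_median = cfg$convert_median)
    else validate_rom_table(cfg$studies, convert_median = cfg$convert_median)
  })
  .pipeline_log(cfg, "loaded %d studies", nrow(studies))
  est <- .stage("effect_measures", log_rom(studies))

  overall_fixed <- .stage("pooling", pool_fixed(est, alpha = cfg$alpha))
  overall_random <- .stage("pooling", pool_dl(est, alpha = cfg$alpha))
  attr(overall_random, "n_case") <- sum(studies$n_case)
  attr(overall_random, "n_control") <- sum(studies$n_control)

  subgroups <- .stage("pooling", {
    out <- list()
    for (f in intersect(cfg$subgroups, names(studies)))
      out[[f]] <- subgroup_pool(studies, f, alpha = cfg$alpha)
    out
  })

  contrast_factors <- cfg$contrasts %||%
    intersect(c("tumour_size_class", "tnm_stage", "node_metastasis", "histology"),
              names(studies)[colSums(!is.na(studies)) > 0])
  contrasts <- .stage("pooling", {
    out <- list()
    for (f in contrast_factors) {
      lv <- stats::na.omit(unique(studies[[f]]))
      if (length(lv) != 2) next
      grp <- subgroup_pool(studies[!is.na(studies[[f]]), ], f, alpha = cfg$alpha)
      if (!all(lv %in% names(grp))) next
      ct <- compare_two_pooled(grp[[lv[1]]], grp[[lv[2]]])
      out[[f]] <- list(levels = lv, pooled = grp[lv], z = ct$z, p = ct$p)
    }
    out
  })

  metareg <- .stage("meta_regression", {
    mods <- intersect(cfg$moderators, names(studies))
    mods <- mods[vapply(mods, function(m)
      length(unique(stats::na.omit(studies[[m]]))) >= 2, logical(1))]
    if (length(mods))
      meta_regress_each(est, studies[c("study_id", mods)], moderators = mods)
    else list()
  })

  loo <- if (nrow(studies) >= 3)
    .stage("pooling", leave_one_out(est, alpha = cfg$alpha)) else NULL
  egger <- if (nrow(studies) >= 3) .stage("bias_heterogeneity", egger_test(est)) else NULL
  begg <- if (nrow(studies) >= 3) .stage("bias_heterogeneity", begg_test(est)) else NULL
  funnel <- .stage("bias_heterogeneity", funnel_data(est, overall_random))
  galbraith <- .stage("bias_heterogeneity", galbraith_data(est))

  or_arm <- NULL
  if (!is.null(cfg$categories)) {
    or_arm <- .stage("effect_measures", {
      cats <- if (is.character(cfg$categories))
        read_study_table(cfg$categories, "categories") else cfg$categories
      ests <- do.call(rbind, lapply(cats, function(row) {
        cells <- categories_to_or(row, cfg$exposed_range, cfg$referent_range)
        log_or(cells["a"], cells["b"], cells["c"], cells["d"],
               study_id = row$study_id)
      }))
      list(estimates = ests, pooled = pool_dl(ests, alpha = cfg$alpha))
    })
  }

  diag_arm <- NULL
  if (!is.null(cfg$diagnostic)) {
    diag_arm <- .stage("diagnostic_meta", {
      d <- if (is.character(cfg$diagnostic))
        read_study_table(cfg$diagnostic, "diagnostic") else
        validate_diagnostic_table(cfg$diagnostic)
      by_group <- diagnostic_meta_by_group(d, alpha = cfg$alpha,
                                           boot = cfg$boot, seed = cfg$seed)
      c(by_group, list(lr_matrix = lr_matrix(d)))
    })
  }

  bundle <- list(
    config = cfg[setdiff(names(cfg), c("studies", "categories", "diagnostic"))],
    n_studies = nrow(studies),
    studies = studies,
    estimates = est,
    overall = list(fixed = overall_fixed, random = overall_random),
    subgroups = subgroups,
    contrasts = contrasts,
    meta_regression = metareg,
    leave_one_out = loo,
    egger = egger, begg = begg,
    funnel = funnel, galbraith = galbraith,
    or_arm = or_arm,
    diagnostic = diag_arm
  )
  if (!is.null(cfg$out_dir)) {
    write_report_bundle(bundle, cfg$out_dir)
    return(invisible(bundle))
  }
  bundle
}

.pooled_json <- function(r) {
  if (is.null(r)) return(NULL)
  list(k = r$k, measure = r$measure, y_pooled = r$y_pooled,
       se_pooled = r$se_pooled, est = r$est_pooled,
       ci_low = r$ci_low, ci_high = r$ci_high, z = r$z, p_z = r$p_z,
       Q = r$Q, df = r$df, p_q = r$p_q, i_squared = r$i_squared,
       tau_squared = r$tau_squared, weights = as.list(r$weights))
}

#' Write the report bundle as TSV tables plus a JSON source of truth
#'
#' Emits `overall.tsv`, one `subgroup_<factor>.tsv` per stratification,
#' `contrasts.tsv`, `meta_regression.tsv`, `leave_one_out.tsv`,
#' `bias_tests.tsv`, `funnel.tsv`, `galbraith.tsv`, `odds_ratio.tsv`,
#' `diagnostic.tsv`, `lr_matrix.tsv` (as applicable), a `report.json`
#' holding every number at full precision, and `run.log`.  TSV numbers are
#' rounded to 2 decimals; the JSON is not rounded.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wtsv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 2)
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }

  wtsv(pooled_table(list(fixed = bundle$overall$fixed,
                         random = bundle$overall$random)), "overall.tsv")
  for (f in names(bundle$subgroups))
    wtsv(pooled_table(bundle$subgroups[[f]]), paste0("subgroup_", f, ".tsv"))
  if (length(bundle$contrasts)) {
    wtsv(do.call(rbind, lapply(names(bundle$contrasts), function(f) {
      ct <- bundle$contrasts[[f]]
      data.frame(factor = f, level_a = ct$levels[1], level_b = ct$levels[2],
                 est_a = ct$pooled[[1]]$est_pooled,
                 est_b = ct$pooled[[2]]$est_pooled, z = ct$z, p = ct$p,
                 stringsAsFactors = FALSE)
    })), "contrasts.tsv")
  }
  if (length(bundle$meta_regression)) {
    wtsv(do.call(rbind, lapply(names(bundle$meta_regression), function(m) {
      fit <- bundle$meta_regression[[m]]
      cbind(moderator = m, fit$coefficients,
            tau_squared_resid = fit$tau_squared_resid)
    })), "meta_regression.tsv")
  }
  if (!is.null(bundle$leave_one_out))
    wtsv(as.data.frame(bundle$leave_one_out), "leave_one_out.tsv")
  if (!is.null(bundle$egger)) {
    wtsv(data.frame(test = c("egger", "begg"),
                    statistic = c(bundle$egger$t, bundle$begg$kendall_tau),
                    p = c(bundle$egger$p, bundle$begg$p)), "bias_tests.tsv")
  }
  wtsv(bundle$funnel$points, "funnel.tsv")
  wtsv(bundle$galbraith, "galbraith.tsv")
  if (!is.null(bundle$or_arm))
    wtsv(pooled_table(list(high_vs_low = bundle$or_arm$pooled)), "odds_ratio.tsv")
  if (!is.null(bundle$diagnostic)) {
    wtsv(bundle$diagnostic$table, "diagnostic.tsv")
    wtsv(bundle$diagnostic$lr_matrix, "lr_matrix.tsv")
  }

  json <- list(
    n_studies = bundle$n_studies,
    overall = lapply(bundle$overall, .pooled_json),
    subgroups = lapply(bundle$subgroups, function(g) lapply(g, .pooled_json)),
    contrasts = lapply(bundle$contrasts, function(ct)
      list(levels = ct$levels, z = ct$z, p = ct$p,
           pooled = lapply(ct$pooled, .pooled_json))),
    meta_regression = lapply(bundle$meta_regression, function(fit)
      list(coefficients = fit$coefficients,
           tau_squared_resid = fit$tau_squared_resid, k = fit$k,
           covariate_coding = fit$covariate_coding)),
    leave_one_out = if (!is.null(bundle$leave_one_out))
      as.data.frame(bundle$leave_one_out),
    egger = if (!is.null(bundle$egger)) unclass(bundle$egger),
    begg = if (!is.null(bundle$begg)) unclass(bundle$begg),
    galbraith = list(slope = attr(bundle$galbraith, "slope"),
                     n_outliers = attr(bundle$galbraith, "n_outliers"),
                     points = bundle$galbraith),
    or_arm = if (!is.null(bundle$or_arm))
      list(pooled = .pooled_json(bundle$or_arm$pooled)),
    diagnostic = if (!is.null(bundle$diagnostic))
      list(table = bundle$diagnostic$table,
           lr_matrix = bundle$diagnostic$lr_matrix)
  )
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  files <- c(files, p)

  p <- file.path(dir, "run.log")
  writeLines(c(sprintf("rommeta %s", as.character(utils::packageVersion("rommeta"))),
               sprintf("R %s", getRversion()),
               sprintf("date %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               sprintf("seed %s", bundle$config$seed),
               sprintf("alpha %s", bundle$config$alpha),
               sprintf("n_studies %d", bundle$n_studies)), p)
  files <- c(files, p)
  invisible(files)
}
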