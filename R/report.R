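#' Read a run configuration from YAML
#'
#' A run configuration lists input paths (cohort CSV, incidence-curve CSVs),
#' the outcomes to analyse, the percentile scheme, bootstrap count, seed and
#' output directory.  In-memory equivalents (a cohort data frame, incidence
#' curves) may be supplied directly to the `run_*` functions instead.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

resolve_cohort <- function(x) {
  if (is.character(x)) read_carrier_cohort(x) else validate_carrier_cohort(x)
}
resolve_curve <- function(x) {
  if (is.character(x)) read_incidence_curve(x) else x
}

write_report_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# generated by carrierprs; seed=%s", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Retrospective association report
#'
#' Runs the full weighted retrospective analysis for each requested outcome:
#' weight calibration against the external incidence curve, the continuous
#' per-SD model with and without family-history adjustment, the
#' categorical-percentile model, the age-varying model, and Harrell's C.
#' Mirrors the layout of published association tables (one row per outcome,
#' model and term).
#'
#' @param cohort A `carrier_cohort` data frame or CSV path.
#' @param incidence Named list of [incidence_curve()]s (or CSV paths), one
#'   per outcome.
#' @param outcomes Outcomes to analyse (subset of `"breast"`,
#'   `"er_positive"`, `"er_negative"`, `"ovarian"`).
#' @param covariates Adjustment covariates (default birth cohort + four
#'   principal components).
#' @param percentile_edges Percentile boundaries for the categorical model.
#' @param n_bootstrap Bootstrap replicates for the C-statistic SE.
#' @param seed Integer seed (bootstrap and any resampling).
#' @param outdir Optional directory: tidy CSVs are written there with a
#'   seed-stamped header comment.
#' @param age_bins Calibration age bins (see
#'   [calibrate_sampling_weights()]).
#' @return A list with data frames `associations`, `categorical`,
#'   `age_varying`, `concordance`, plus per-outcome fit objects in `fits`.
#' @export
run_retrospective <- function(cohort, incidence,
                              outcomes = c("breast", "ovarian"),
                              covariates = c("birth_year", "pc1", "pc2",
                                             "pc3", "pc4"),
                              percentile_edges = c(5, 10, 20, 40, 60, 80, 90, 95),
                              n_bootstrap = 0, seed = 1L, outdir = NULL,
                              age_bins = c(18, seq(25, 70, by = 5), 80)) {
  cohort <- resolve_cohort(cohort)
  assoc <- list(); cats <- list(); av <- list(); conc <- list(); fits <- list()
  for (oc in outcomes) {
    cur <- resolve_curve(incidence[[oc]])
    if (is.null(cur)) stop("retrospective stage: no incidence curve for outcome '", oc, "'")
    ds <- build_analysis_dataset(cohort, outcome = oc, covariates = covariates)
    cal <- calibrate_sampling_weights(ds, cur, age_bins = age_bins)
    ds <- add_fh_indicators(cal$dataset)
    n_aff <- sum(ds$event); n_un <- nrow(ds) - n_aff
    message("outcome ", oc, ": ", n_un, " unaffected / ", n_aff, " affected")

    fit0 <- fit_weighted_cox(ds, covariates = c("prs", covariates))
    fit_fh <- fit_weighted_cox(ds, covariates = c("prs", "fh1", "fh2", covariates))
    row <- function(fit, model) {
      pr <- fit$hr_table[fit$hr_table$term == "prs", ]
      data.frame(outcome = oc, model = model, term = "prs",
                 hr = pr$hr, ci_lower = pr$ci_lower, ci_upper = pr$ci_upper,
                 p = pr$p, n_unaffected = n_un, n_affected = n_aff)
    }
    assoc[[paste0(oc, 0)]] <- row(fit0, "no_fh_adjustment")
    assoc[[paste0(oc, 1)]] <- row(fit_fh, "fh_adjusted")

    # categorical percentiles: thresholds from unaffected carriers
    pv <- structure(list(carrier_ids = ds$carrier_id, raw = ds$prs,
                         standardized = ds$prs, reference_sd = 1,
                         reference_mean = 0), class = "prs_vector")
    pc <- assign_percentiles(pv, ds$carrier_id[ds$event == 0],
                             scheme_edges = percentile_edges)
    cf <- categorical_percentile_fit(ds, pc$category, pc$scheme,
                                     covariates = covariates)
    cats[[oc]] <- cbind(outcome = oc, cf$per_bin,
                        lrt_p_vs_continuous = cf$lrt$p)

    tv <- fit_time_varying_prs(ds, covariates = covariates,
                               split = if (sum(ds$event) > 400) "years" else "events")
    av[[oc]] <- data.frame(outcome = oc,
                           term = c("prs", "prs_x_age"),
                           hr = tv$hr_table$hr[1:2],
                           ci_lower = tv$hr_table$ci_lower[1:2],
                           ci_upper = tv$hr_table$ci_upper[1:2],
                           p = tv$hr_table$p[1:2])

    ci <- concordance_index(ds, fit0, n_bootstrap = n_bootstrap, seed = seed)
    conc[[oc]] <- data.frame(outcome = oc, c_statistic = ci$c_statistic,
                             bootstrap_se = ci$bootstrap_se,
                             n_bootstrap = ci$n_bootstrap)
    fits[[oc]] <- list(continuous = fit0, fh_adjusted = fit_fh,
                       categorical = cf, age_varying = tv,
                       weights = cal$scheme)
  }
  out <- list(associations = do.call(rbind, c(assoc, make.row.names = FALSE)),
              categorical = do.call(rbind, c(cats, make.row.names = FALSE)),
              age_varying = do.call(rbind, c(av, make.row.names = FALSE)),
              concordance = do.call(rbind, c(conc, make.row.names = FALSE)),
              fits = fits, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("associations", "categorical", "age_varying", "concordance"))
      write_report_csv(out[[nm]], file.path(outdir, paste0("retrospective_", nm, ".csv")),
                       seed)
  }
  out
}

#' Prospective validation report
#'
#' Left-truncated Cox fits on the prospective follow-up period, one row per
#' outcome with the number of women at risk, incident cancers, per-SD HR,
#' CI and p-value.
#'
#' @inheritParams run_retrospective
#' @return A list with `table` (the report data frame) and `fits`.
#' @export
run_prospective <- function(cohort, outcomes = c("breast", "ovarian"),
                            covariates = c("birth_year", "pc1", "pc2",
                                           "pc3", "pc4"),
                            seed = 1L, outdir = NULL) {
  cohort <- resolve_cohort(cohort)
  rows <- list(); fits <- list()
  for (oc in outcomes) {
    fit <- fit_prospective_cox(cohort, outcome = oc,
                               model_covariates = c("prs", covariates))
    pr <- fit$hr_table[fit$hr_table$term == "prs", ]
    rows[[oc]] <- data.frame(outcome = oc, n_at_risk = fit$n,
                             incident_cancers = fit$n_events,
                             hr = pr$hr, ci_lower = pr$ci_lower,
                             ci_upper = pr$ci_upper, p = pr$p)
    fits[[oc]] <- fit
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_report_csv(tab, file.path(outdir, "prospective_associations.csv"), seed)
  }
  list(table = tab, fits = fits, seed = seed)
}

#' Absolute-risk prediction report
#'
#' Runs the constrained penetrance solver for each configured gene-cancer
#' combination and tabulates cumulative and 10-year risks by PRS percentile,
#' optionally for subgroups with their own average incidence curves.
#'
#' @param specs A list of specifications, each a list with `gene`, `cancer`,
#'   `hr` (per-SD hazard ratio), `incidence` (curve or CSV path), and
#'   optionally `subgroups` (named list of curves) and `hr_age_interaction`
#'   (per-year interaction HR).
#' @param percentiles Percentiles to tabulate.
#' @param mixture_bins Number of equal-probability PRS mixture bins.
#' @param seed Recorded in output headers (the solver is deterministic).
#' @param outdir Optional output directory for tidy CSVs.
#' @return A list with `risks` (data frame: gene, cancer, group, age,
#'   percentile, cumulative_risk, ten_year_risk) and `surfaces`.
#' @export
run_risk_prediction <- function(specs, percentiles = c(5, 10, 25, 50, 75, 90, 95),
                                mixture_bins = 201, seed = 1L, outdir = NULL) {
  mix <- discretize_standard_normal(n_bins = mixture_bins)
  rows <- list(); surfaces <- list()
  for (sp in specs) {
    if (is.null(sp$incidence))
      stop("risk-prediction stage: missing incidence curve for ",
           sp$gene, " ", sp$cancer)
    beta1 <- if (is.null(sp$hr_age_interaction)) 0 else log(sp$hr_age_interaction)
    groups <- c(list(overall = resolve_curve(sp$incidence)),
                lapply(sp$subgroups, resolve_curve))
    for (g in names(groups)) {
      surf <- solve_constrained_hazard(groups[[g]], beta0 = log(sp$hr),
                                       beta1 = beta1, mixture = mix)
      tab <- surface_table(surf, percentiles)
      key <- paste(sp$gene, sp$cancer, g, sep = ".")
      rows[[key]] <- cbind(gene = sp$gene, cancer = sp$cancer, group = g, tab)
      surfaces[[key]] <- surf
    }
  }
  risks <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_report_csv(risks, file.path(outdir, "predicted_risks.csv"), seed)
  }
  list(risks = risks, surfaces = surfaces, seed = seed)
}
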