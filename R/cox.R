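#' Fit a stratified, weighted Cox model with family-clustered variance
#'
#' Maximises the sampling-weighted stratified Cox partial likelihood (Efron
#' tie handling by default) on the age scale and reports robust
#' (cluster-sandwich) variances aggregated over families, so that related
#' carriers do not understate uncertainty.  With unit weights and entry age 0
#' this is an ordinary stratified Cox fit.
#'
#' @param dataset An `analysis_dataset`, normally after
#'   [calibrate_sampling_weights()] for retrospective data.
#' @param covariates Character vector of covariate columns; defaults to the
#'   PRS alone.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @param stratify Use the country x Ashkenazi stratum column?  Default
#'   `TRUE`.
#' @return An object of class `cox_fit`: list with `coefficients` (log-HRs),
#'   `robust_covariance`, `naive_covariance`, `loglik` (null, fitted),
#'   `n`, `n_events`, `hr_table` (HR, 95% CI from robust SEs, Wald p),
#'   `covariates`, and the underlying [survival::coxph()] `fit`.
#' @export
fit_weighted_cox <- function(dataset, covariates = "prs",
                             ties = c("efron", "breslow"), stratify = TRUE) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(dataset))
  miss <- setdiff(all.vars(stats::reformulate(covariates)), names(dataset))
  if (length(miss)) stop("covariate column(s) not in dataset: ",
                         paste(miss, collapse = ", "))
  X <- stats::model.matrix(
    stats::reformulate(covariates, intercept = FALSE), data = dataset)
  if (qr(X)$rank < ncol(X))
    stop("collinear covariates: design matrix is rank deficient")

  rhs <- covariates
  if (stratify && !is.null(dataset$stratum) &&
      length(unique(dataset$stratum)) > 1L)
    rhs <- c(rhs, "strata(stratum)")
  use_cluster <- !is.null(dataset$cluster)
  if (use_cluster) rhs <- c(rhs, "cluster(cluster)")
  lhs <- if (any(dataset$entry_age > 0))
    "survival::Surv(entry_age, exit_age, event)"
  else "survival::Surv(exit_age, event)"
  fml <- stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))

  fit <- survival::coxph(fml, data = dataset, weights = dataset$sampling_weight,
                         ties = ties, robust = TRUE, x = FALSE, model = FALSE)
  if (any(!is.finite(fit$coefficients)) ||
      any(abs(fit$coefficients) > 15))
    stop("monotone likelihood suspected: coefficient estimate diverged (",
         paste(signif(fit$coefficients, 3), collapse = ", "), ")")
  new_cox_fit(fit, dataset, covariates)
}

new_cox_fit <- function(fit, dataset, covariates) {
  beta <- fit$coefficients
  vr <- fit$var                                 # robust when cluster/robust
  vn <- if (!is.null(fit$naive.var)) fit$naive.var else fit$var
  dimnames(vr) <- dimnames(vn) <- list(names(beta), names(beta))
  se <- sqrt(diag(vr))
  hr <- data.frame(term = names(beta), hr = exp(beta),
                   ci_lower = exp(beta - 1.96 * se),
                   ci_upper = exp(beta + 1.96 * se),
                   p = 2 * stats::pnorm(-abs(beta / se)),
                   row.names = NULL)
  structure(list(coefficients = beta,
                 robust_covariance = vr, naive_covariance = vn,
                 loglik = fit$loglik, n = fit$n, n_events = fit$nevent,
                 hr_table = hr, covariates = covariates, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Weighted Cox fit:", x$n_events, "events /", x$n, "subjects\n")
  print(transform(x$hr_table, hr = signif(hr, 4), ci_lower = signif(ci_lower, 4),
                  ci_upper = signif(ci_upper, 4), p = signif(p, 3)), ...)
  invisible(x)
}

#' Linear predictor of a fitted Cox model on its dataset
#' @param object A `cox_fit`.
#' @param dataset Dataset to score (defaults to refit data inside `fit`).
#' @param ... Unused.
#' @return Numeric linear predictor (centred as in `coxph`).
#' @export
predict.cox_fit <- function(object, dataset = NULL, ...) {
  if (is.null(dataset)) return(unname(object$fit$linear.predictors))
  X <- stats::model.matrix(stats::reformulate(object$covariates, intercept = FALSE),
                           data = dataset)
  as.numeric(X %*% object$coefficients)
}

#' Fit a Cox model with an age-varying PRS effect
#'
#' Models the log hazard ratio of the standardized PRS as linear in age,
#' \eqn{\beta(t) = \beta_0 + \beta_1 (t - c)}, by treating the PRS as a
#' time-varying covariate on the age scale: episodes are split so the
#' covariate entering each risk set at age \eqn{t} is `prs * (t - c)`.
#'
#' With `split = "events"` episodes are cut at every distinct event age
#' (exact risk-set evaluation, preferable for modest cohorts).  With
#' `split = "years"` they are cut at integer ages, so a risk-set member's
#' interaction covariate is evaluated at the end of the current year of age
#' (at most one year late); this keeps the expanded data small for large
#' cohorts and matches the resolution of year-recorded ages.
#'
#' @inheritParams fit_weighted_cox
#' @param age_center Age \eqn{c} at which the main effect is evaluated
#'   (default 0: main effect at birth, the conventional parameterisation
#'   when reporting the interaction as a per-year HR).
#' @param split `"events"` or `"years"` episode cutting (see above).
#' @return A `cox_fit` whose terms include `prs` (main effect at
#'   `age_center`) and `prs_x_age` (per-year interaction).
#' @export
fit_time_varying_prs <- function(dataset, covariates = character(),
                                 age_center = 0,
                                 split = c("events", "years"),
                                 ties = c("efron", "breslow"),
                                 stratify = TRUE) {
  split <- match.arg(split)
  ties <- match.arg(ties)
  cuts <- if (split == "events") sort(unique(dataset$exit_age[dataset$event == 1L]))
  else seq(floor(min(dataset$entry_age)), ceiling(max(dataset$exit_age)))
  dat <- dataset
  dat$.id <- seq_len(nrow(dat))
  sp <- survival::survSplit(
    Surv(entry_age, exit_age, event) ~ ., data = dat, cut = cuts,
    start = "entry_age", end = "exit_age", event = "event")
  sp$prs_x_age <- sp$prs * (sp$exit_age - age_center)
  class(sp) <- c("analysis_dataset", "data.frame")
  attr(sp, "outcome") <- attr(dataset, "outcome")
  fit_weighted_cox(sp, covariates = c("prs", "prs_x_age", covariates),
                   ties = ties, stratify = stratify)
}

#' Likelihood ratio test between nested Cox fits
#'
#' Uses the (sampling-weighted) partial log-likelihoods.  With calibrated
#' sampling weights the statistic is a weighted pseudo-likelihood ratio;
#' its chi-square reference is an approximation, which is noted in a
#' message.
#'
#' @param nested,full `cox_fit` objects fitted to the same dataset and
#'   weights, with the nested model's covariates a subset of the full
#'   model's.
#' @return A list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "cox_fit"), inherits(full, "cox_fit"))
  if (!all(nested$covariates %in% full$covariates))
    stop("models are not nested: nested covariates must be a subset of the full model's")
  if (nested$n != full$n || nested$n_events != full$n_events)
    stop("models were fitted to different datasets")
  df <- length(full$coefficients) - length(nested$coefficients)
  if (df < 0) stop("full model has fewer parameters than the nested model")
  stat <- max(0, 2 * (full$loglik[2] - nested$loglik[2]))
  w <- full$fit$weights
  if (!is.null(w) && any(abs(w - 1) > 1e-12))
    message("LRT computed from weighted pseudo-likelihoods; ",
            "chi-square reference is approximate")
  list(statistic = stat, df = df,
       p = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Group-specific PRS associations and heterogeneity test
#'
#' Fits a model in which the per-SD PRS log-HR differs by a grouping factor
#' (country, pathogenic-variant class, or variant-location group), via a
#' PRS-by-group interaction coded as one PRS slope per group.  Reports the
#' per-group HRs, a likelihood ratio test against the common-slope model,
#' and (for two groups) a Wald p-value for the pairwise difference in
#' log-HRs.
#'
#' @inheritParams fit_weighted_cox
#' @param group_var Name of the grouping column in `dataset`.
#' @param covariates Additional adjustment covariates (the group main effect
#'   is always included unless the groups coincide with the strata).
#' @return A list with `per_group` (data frame: group, HR, CI, p), `fit`
#'   (full interaction `cox_fit`), `lrt` (heterogeneity test), and `wald_p`
#'   (two-group difference; `NA` otherwise).
#' @export
interaction_models <- function(dataset, group_var, covariates = character(),
                               ties = c("efron", "breslow"), stratify = TRUE) {
  ties <- match.arg(ties)
  if (!group_var %in% names(dataset)) stop("no column '", group_var, "' in dataset")
  g <- factor(as.character(dataset[[group_var]]))
  if (nlevels(g) < 2L) stop("grouping variable has a single level; nothing to compare")
  if (any(tapply(dataset$event, g, sum) == 0))
    stop("every group needs at least one event")
  dataset$.group <- g
  full <- fit_weighted_cox(dataset,
                           covariates = c(".group", ".group:prs", covariates),
                           ties = ties, stratify = stratify)
  nested <- fit_weighted_cox(dataset, covariates = c(".group", "prs", covariates),
                             ties = ties, stratify = stratify)
  df <- length(full$coefficients) - length(nested$coefficients)
  stat <- max(0, 2 * (full$loglik[2] - nested$loglik[2]))
  lrt <- list(statistic = stat, df = df,
              p = stats::pchisq(stat, df, lower.tail = FALSE))

  idx <- grep(":prs$", names(full$coefficients))
  beta <- full$coefficients[idx]
  se <- sqrt(diag(full$robust_covariance)[idx])
  per_group <- data.frame(
    group = sub("^\\.group(.*):prs$", "\\1", names(beta)),
    hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)), row.names = NULL)
  wald_p <- NA_real_
  if (length(idx) == 2L) {
    v <- full$robust_covariance[idx, idx]
    d <- beta[1] - beta[2]
    wald_p <- 2 * stats::pnorm(-abs(d / sqrt(v[1, 1] + v[2, 2] - 2 * v[1, 2])))
  }
  list(per_group = per_group, fit = full, lrt = lrt, wald_p = wald_p)
}

#' Categorical PRS-percentile associations
#'
#' Fits per-category hazard ratios against the reference percentile bin
#' (default 40-60) and compares the categorical model with the continuous
#' per-SD model by adding the category indicators on top of the continuous
#' score (likelihood ratio test on the added indicators).  Also returns the
#' HR expected at each bin under the continuous fit,
#' \eqn{\exp(\beta \, E[z \mid \mathrm{bin}])} for a standard-normal score,
#' for percentile-curve comparisons.
#'
#' @inheritParams fit_weighted_cox
#' @param category Factor of percentile categories per row (first level =
#'   reference), e.g. from [assign_percentiles()].
#' @param scheme The `percentile_scheme` that produced `category`.
#' @return A list with `fit` (categorical `cox_fit`), `per_bin` (data frame:
#'   bin label, HR, CI, expected HR under the continuous model), and `lrt`
#'   (categorical-beyond-continuous test).
#' @export
categorical_percentile_fit <- function(dataset, category, scheme,
                                       covariates = character(),
                                       ties = c("efron", "breslow"),
                                       stratify = TRUE) {
  ties <- match.arg(ties)
  stopifnot(length(category) == nrow(dataset))
  tab <- table(category)
  if (any(tab == 0)) {
    empty <- names(tab)[tab == 0]
    warning("empty percentile bin(s) ", paste(empty, collapse = ", "),
            " dropped from the factor")
    category <- droplevels(category)
  }
  if (sum(dataset$event[category == levels(category)[1L]]) == 0)
    stop("reference percentile bin has no events")
  dataset$.prs_cat <- category
  fit_cat <- fit_weighted_cox(dataset, covariates = c(".prs_cat", covariates),
                              ties = ties, stratify = stratify)
  fit_cont <- fit_weighted_cox(dataset, covariates = c("prs", covariates),
                               ties = ties, stratify = stratify)
  fit_both <- fit_weighted_cox(dataset,
                               covariates = c("prs", ".prs_cat", covariates),
                               ties = ties, stratify = stratify)
  df <- length(fit_both$coefficients) - length(fit_cont$coefficients)
  stat <- max(0, 2 * (fit_both$loglik[2] - fit_cont$loglik[2]))
  lrt <- list(statistic = stat, df = df,
              p = stats::pchisq(stat, df, lower.tail = FALSE))

  mix <- discretize_standard_normal(scheme$bin_edges)
  beta_cont <- fit_cont$coefficients["prs"]
  ref_bin <- scheme$reference_bin
  expected_hr <- exp(beta_cont * (mix$representative_z - mix$representative_z[ref_bin]))
  idx <- grep("^\\.prs_cat", names(fit_cat$coefficients))
  est <- stats::setNames(rep(1, length(scheme$labels)), scheme$labels)
  lo <- hi <- est
  beta <- fit_cat$coefficients[idx]
  se <- sqrt(diag(fit_cat$robust_covariance)[idx])
  lab <- sub("^\\.prs_cat", "", names(beta))
  est[lab] <- exp(beta); lo[lab] <- exp(beta - 1.96 * se); hi[lab] <- exp(beta + 1.96 * se)
  per_bin <- data.frame(bin = scheme$labels, hr = unname(est),
                        ci_lower = unname(lo), ci_upper = unname(hi),
                        expected_hr_continuous = expected_hr, row.names = NULL)
  per_bin$ci_lower[scheme$reference_bin] <- per_bin$ci_upper[scheme$reference_bin] <- NA
  list(fit = fit_cat, per_bin = per_bin, lrt = lrt, continuous_fit = fit_cont)
}

#' Left-truncated Cox fit on the prospective follow-up period
#'
#' Builds the prospective analysis dataset (entry at recruitment, carriers
#' affected at or before recruitment excluded) and fits an unweighted Cox
#' model with the same stratification and family clustering as the
#' retrospective analysis.  Prospective person-time is unaffected by
#' clinic-based ascertainment of prevalent cases, so no sampling weights are
#' applied.
#'
#' @inheritParams build_analysis_dataset
#' @inheritParams fit_weighted_cox
#' @return A `cox_fit`; the attached dataset counts appear as `n` (women at
#'   risk) and `n_events` (incident cancers).
#' @export
fit_prospective_cox <- function(cohort, outcome = "breast",
                                covariates = "prs",
                                model_covariates = covariates,
                                ties = c("efron", "breslow"),
                                stratify = TRUE, ...) {
  ties <- match.arg(ties)
  cohort_cols <- intersect(c("birth_year", "pc1", "pc2", "pc3", "pc4"),
                           names(cohort))
  ds <- build_analysis_dataset(cohort, outcome = outcome, mode = "prospective",
                               covariates = cohort_cols, ...)
  if (sum(ds$event) == 0) stop("no incident events in the prospective follow-up")
  fit_weighted_cox(ds, covariates = model_covariates, ties = ties,
                   stratify = stratify)
}
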