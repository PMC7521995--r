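#' Configuration for carrier-cohort simulation
#'
#' Collects the generative assumptions behind the analysis into one record:
#' a standard-normal standardized PRS with correlation 0.5 between
#' first-degree relatives, a proportional-hazards PRS effect on the cancer
#' hazard (optionally log-linear in age), competing censoring by
#' risk-reducing surgery and end of follow-up, clinic-style oversampling of
#' affected carriers, and ER-status assignment with missingness.  The
#' average age-specific incidence curve is the input; the PRS-conditional
#' baseline hazard consistent with it is derived internally with the
#' constrained solver, so the simulated marginal incidence reproduces the
#' input curve.
#'
#' @param n_carriers Cohort size to return.
#' @param gene `"BRCA1"` or `"BRCA2"` (label only).
#' @param cancer `"breast"` or `"ovarian"`: which event the hazard generates.
#' @param beta0 Per-SD log hazard ratio of the standardized PRS.
#' @param beta1 Per-year change in the log hazard ratio (default 0).
#' @param reference_age Age at which `beta0` applies (default 18).
#' @param incidence An [incidence_curve()]: average carrier incidence for
#'   the cancer, covering ages 18-80.
#' @param ascertainment_affected_fraction Target fraction of affected
#'   carriers in the returned cohort (`NULL` = population sampling, no
#'   oversampling).
#' @param family_size_probs Probabilities of family sizes 1, 2, 3.
#' @param prs_family_correlation PRS correlation between relatives
#'   (default 0.5, first-degree).
#' @param mastectomy_rate Annual hazard of risk-reducing bilateral
#'   mastectomy from age 30.
#' @param rrso_rate Annual hazard of risk-reducing salpingo-oophorectomy
#'   from age 35.
#' @param followup_range Range of the age at last follow-up (uniform).
#' @param recruit_range Range of recruitment ages (uniform).
#' @param prospective_followup_years Mean prospective follow-up after
#'   recruitment (exponential); `NULL` uses the retrospective follow-up age.
#' @param er_positive_fraction P(ER-positive | breast cancer).
#' @param er_missing_fraction P(ER status missing | breast cancer).
#' @param birth_year_range,n_countries,ashkenazi_fraction Covariate
#'   plumbing for stratification and adjustment.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_carriers = 1000,
                              gene = c("BRCA1", "BRCA2"),
                              cancer = c("breast", "ovarian"),
                              beta0 = log(1.3), beta1 = 0,
                              reference_age = 18,
                              incidence,
                              ascertainment_affected_fraction = 0.5,
                              family_size_probs = c(0.5, 0.3, 0.2),
                              prs_family_correlation = 0.5,
                              mastectomy_rate = 0.004,
                              rrso_rate = 0.008,
                              followup_range = c(20, 80),
                              recruit_range = c(20, 60),
                              prospective_followup_years = 5,
                              er_positive_fraction = 0.35,
                              er_missing_fraction = 0.30,
                              birth_year_range = c(1930, 1990),
                              n_countries = 3,
                              ashkenazi_fraction = 0.1,
                              seed = 1L) {
  gene <- match.arg(gene)
  cancer <- match.arg(cancer)
  if (missing(incidence) || !inherits(incidence, "incidence_curve"))
    stop("an incidence_curve must be supplied as the average carrier incidence")
  stopifnot(n_carriers >= 1, is.finite(beta0), is.finite(beta1),
            prs_family_correlation >= 0, prs_family_correlation <= 1,
            mastectomy_rate >= 0, rrso_rate >= 0,
            er_positive_fraction >= 0, er_positive_fraction <= 1,
            er_missing_fraction >= 0, er_missing_fraction <= 1)
  if (!is.null(ascertainment_affected_fraction) &&
      (ascertainment_affected_fraction <= 0 || ascertainment_affected_fraction >= 1))
    stop("ascertainment_affected_fraction must lie in (0,1) or be NULL")
  family_size_probs <- family_size_probs / sum(family_size_probs)
  structure(as.list(environment()), class = "simulation_config")
}

# Annual baseline hazard (ages 18..79) consistent with the average carrier
# incidence under the PRS mixture; uses the constrained solver with a fine
# discretization of the standard normal.
baseline_from_average <- function(config) {
  surf <- solve_constrained_hazard(config$incidence, config$beta0, config$beta1,
                                   reference_age = config$reference_age,
                                   mixture = discretize_standard_normal(n_bins = 201),
                                   age_range = c(18, 80))
  list(ages = surf$age_grid, lam0 = surf$baseline_hazard)
}

# Draw latent cancer onset ages for PRS values z under hazard
# lam0(t) * exp((beta0 + beta1 (t - ref)) z), piecewise constant on annual
# intervals [ages[i], ages[i]+1); uniform jitter within the event year.
# Returns Inf when no onset before the end of the grid.
draw_event_ages <- function(z, lam0, ages, beta0, beta1, reference_age) {
  n <- length(z)
  nT <- length(lam0)
  t0 <- ages[seq_len(nT)]
  e <- stats::rexp(n)
  if (beta1 == 0) {
    cumh <- cumsum(lam0)
    thresh <- e / exp(beta0 * z)
    k <- findInterval(thresh, cumh) + 1L       # first year with cum hazard > thresh
    onset <- ifelse(k > nT, Inf, NA_real_)
    hit <- k <= nT
    if (any(hit)) {
      prev <- c(0, cumh)[k[hit]]
      frac <- (thresh[hit] - prev) / lam0[k[hit]]
      onset[hit] <- t0[k[hit]] + frac
    }
  } else {
    bt <- beta0 + beta1 * (t0 - reference_age)
    H <- exp(outer(z, bt)) * rep(lam0, each = n)   # n x nT annual hazards
    CH <- t(apply(H, 1L, cumsum))
    hit_mat <- CH >= e
    k <- apply(hit_mat, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
    onset <- rep(Inf, n)
    hit <- !is.na(k)
    if (any(hit)) {
      rows <- seq_len(n)[hit]
      idx <- cbind(rows, k[hit])
      prev <- ifelse(k[hit] > 1L, CH[cbind(rows, pmax(k[hit] - 1L, 1L))], 0)
      frac <- (e[hit] - prev) / H[idx]
      onset[hit] <- t0[k[hit]] + frac
    }
  }
  onset
}

# Latent source population of m+ carriers in families; everything that does
# not depend on retrospective/prospective handling is drawn here so both
# generators share one stream.
sim_source_population <- function(config, m, base, id0 = 0L, fam0 = 0L) {
  sizes <- integer(0)
  while (sum(sizes) < m)
    sizes <- c(sizes, sample(1:3, size = max(64L, ceiling(m / 2)),
                             replace = TRUE, prob = config$family_size_probs))
  sizes <- sizes[seq_len(which(cumsum(sizes) >= m)[1L])]
  n <- sum(sizes)
  fam <- rep(seq_along(sizes), sizes)
  rho <- config$prs_family_correlation
  u_f <- stats::rnorm(length(sizes))
  z <- sqrt(rho) * u_f[fam] + sqrt(1 - rho) * stats::rnorm(n)

  onset <- draw_event_ages(z, base$lam0, base$ages, config$beta0, config$beta1,
                           config$reference_age)
  mx <- if (config$mastectomy_rate > 0) 30 + stats::rexp(n, config$mastectomy_rate) else rep(Inf, n)
  rrso <- if (config$rrso_rate > 0) 35 + stats::rexp(n, config$rrso_rate) else rep(Inf, n)
  fu <- stats::runif(n, config$followup_range[1L], config$followup_range[2L])
  recruit <- stats::runif(n, config$recruit_range[1L], config$recruit_range[2L])
  prosp_fu <- if (is.null(config$prospective_followup_years)) rep(NA_real_, n)
  else stats::rexp(n, 1 / config$prospective_followup_years)
  data.frame(
    carrier_id = sprintf("C%07d", id0 + seq_len(n)),
    family_id = sprintf("F%06d", fam0 + fam),
    z = z, onset = onset, mx = mx, rrso = rrso, fu = fu,
    recruit = recruit, prosp_fu = prosp_fu,
    birth_year = round(stats::runif(n, config$birth_year_range[1L],
                                    config$birth_year_range[2L])),
    country = paste0("country", sample.int(config$n_countries, n, replace = TRUE)),
    ashkenazi = stats::rbinom(n, 1, config$ashkenazi_fraction),
    fh_breast = sample(0:2, n, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
    fh_ovarian = sample(0:2, n, replace = TRUE, prob = c(0.8, 0.13, 0.07)),
    variant_class = sample(c("I", "II"), n, replace = TRUE, prob = c(0.75, 0.25)),
    variant_location_group = sample(c("region1", "region2", "region3"), n,
                                    replace = TRUE),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    pc3 = stats::rnorm(n), pc4 = stats::rnorm(n),
    stringsAsFactors = FALSE)
}

source_to_records <- function(pop, config) {
  breast <- config$cancer == "breast"
  surgery <- if (breast) pop$mx else pop$rrso
  cens <- pmin(surgery, pop$fu, 80)
  affected <- pop$onset <= cens
  ev <- ifelse(affected, pop$onset, NA_real_)
  rec <- data.frame(
    carrier_id = pop$carrier_id, family_id = pop$family_id,
    gene = config$gene, birth_year = pop$birth_year, country = pop$country,
    ashkenazi = pop$ashkenazi,
    age_recruit = pmin(pop$recruit, pop$fu),
    age_last_followup = pop$fu,
    age_bc = if (breast) ev else NA_real_,
    er_status = NA_character_,
    age_oc = if (breast) NA_real_ else ev,
    age_mastectomy = ifelse(pop$mx < pmin(pop$onset, pop$fu, 80), pop$mx, NA_real_),
    age_rrso = ifelse(pop$rrso < pmin(if (breast) Inf else pop$onset, pop$fu, 80),
                      pop$rrso, NA_real_),
    fh_breast = pop$fh_breast, fh_ovarian = pop$fh_ovarian,
    variant_class = pop$variant_class,
    variant_location_group = pop$variant_location_group,
    pc1 = pop$pc1, pc2 = pop$pc2, pc3 = pop$pc3, pc4 = pop$pc4,
    prs_standardized = pop$z, stringsAsFactors = FALSE)
  if (breast) {
    n_aff <- sum(affected)
    if (n_aff) {
      er <- ifelse(stats::runif(n_aff) < config$er_positive_fraction,
                   "positive", "negative")
      er[stats::runif(n_aff) < config$er_missing_fraction] <- NA
      rec$er_status[affected] <- er
    }
  }
  list(records = rec, affected = affected)
}

#' Simulate an ascertained retrospective carrier cohort
#'
#' Generates carrier families with correlated standard-normal PRS, draws
#' cancer onset ages from the PRS-proportional hazard consistent with the
#' configured average incidence, superimposes risk-reducing surgery and
#' end-of-follow-up censoring, and then applies two-phase outcome-dependent
#' sampling: affected carriers are included preferentially until the target
#' affected fraction is reached, emulating recruitment through cancer
#' genetics clinics.
#'
#' @param config A [simulation_config()].
#' @return A list of class `carrier_simulation` with
#'   \item{cohort}{a `carrier_cohort` data frame of `n_carriers` records;}
#'   \item{truth}{the generating parameters: `beta0`, `beta1`,
#'     `reference_age`, `incidence`, `n_source` (size of the simulated
#'     source population), `source_affected_fraction`, `seed`.}
#' @export
simulate_retrospective_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  base <- baseline_from_average(config)
  n <- config$n_carriers
  frac <- config$ascertainment_affected_fraction

  aff_pool <- list(); un_pool <- list()
  n_aff_want <- if (is.null(frac)) 0L else round(n * frac)
  n_un_want <- if (is.null(frac)) 0L else n - n_aff_want
  got_aff <- 0L; got_un <- 0L; n_source <- 0L; src_aff <- 0L
  id0 <- 0L; fam0 <- 0L; guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L)
      stop("target affected fraction unattainable: source population grew to ",
           n_source, " with only ", src_aff, " affected")
    need <- if (is.null(frac)) n - n_source
    else {
      rate <- if (n_source > 0) max(src_aff / n_source, 0.01) else 0.25
      ceiling(max((n_aff_want - got_aff) / rate * 1.25,
                  (n_un_want - got_un) * 1.25, 64))
    }
    pop <- sim_source_population(config, need, base, id0 = id0, fam0 = fam0)
    id0 <- id0 + nrow(pop)
    fam0 <- fam0 + length(unique(pop$family_id))
    res <- source_to_records(pop, config)
    n_source <- n_source + nrow(pop)
    src_aff <- src_aff + sum(res$affected)
    if (is.null(frac)) {
      aff_pool[[length(aff_pool) + 1L]] <- res$records
      if (n_source >= n) break
    } else {
      aff_pool[[length(aff_pool) + 1L]] <- res$records[res$affected, , drop = FALSE]
      un_pool[[length(un_pool) + 1L]] <- res$records[!res$affected, , drop = FALSE]
      got_aff <- got_aff + sum(res$affected)
      got_un <- got_un + sum(!res$affected)
      if (got_aff >= n_aff_want && got_un >= n_un_want) break
    }
  }
  cohort <- if (is.null(frac)) {
    do.call(rbind, aff_pool)[seq_len(n), , drop = FALSE]
  } else {
    rbind(do.call(rbind, aff_pool)[seq_len(n_aff_want), , drop = FALSE],
          do.call(rbind, un_pool)[seq_len(n_un_want), , drop = FALSE])
  }
  cohort <- cohort[order(cohort$carrier_id), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort <- validate_carrier_cohort(cohort)
  truth <- list(beta0 = config$beta0, beta1 = config$beta1,
                reference_age = config$reference_age,
                incidence = config$incidence,
                cancer = config$cancer, gene = config$gene,
                n_source = n_source,
                source_affected_fraction = src_aff / n_source,
                seed = config$seed)
  structure(list(cohort = cohort, truth = truth), class = "carrier_simulation")
}

#' Simulate a prospective carrier cohort
#'
#' Carriers are recruited at a random age, those already affected at
#' recruitment (or with no follow-up beyond it) are excluded, and incident
#' events arise from the same PRS-proportional hazard during the prospective
#' follow-up period.  No outcome-dependent sampling is applied.
#'
#' @param config A [simulation_config()];
#'   `prospective_followup_years` sets the mean exponential follow-up after
#'   recruitment (`NULL` keeps the retrospective follow-up age so that with
#'   recruitment at age 0 the generator reduces to the unascertained
#'   retrospective one).
#' @return A `carrier_simulation` list (`cohort`, `truth`);
#'   `truth$n_incident` counts incident events.
#' @export
simulate_prospective_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  base <- baseline_from_average(config)
  n <- config$n_carriers
  breast <- config$cancer == "breast"

  keep <- list(); got <- 0L; id0 <- 0L; fam0 <- 0L; guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L) stop("could not accumulate the requested prospective cohort")
    pop <- sim_source_population(config,
                                 if (got == 0L) n
                                 else max(ceiling((n - got) * 1.6), 64L),
                                 base, id0 = id0, fam0 = fam0)
    id0 <- id0 + nrow(pop)
    fam0 <- fam0 + length(unique(pop$family_id))
    fu_end <- if (is.null(config$prospective_followup_years)) pop$fu
    else pmin(pop$recruit + pop$prosp_fu, 80)
    surgery <- if (breast) pop$mx else pop$rrso
    cens <- pmin(surgery, fu_end, 80)
    eligible <- pop$onset > pop$recruit & cens > pop$recruit &
      surgery > pop$recruit
    pop <- pop[eligible, , drop = FALSE]
    cens <- cens[eligible]; fu_end <- fu_end[eligible]
    affected <- pop$onset <= cens
    ev <- ifelse(affected, pop$onset, NA_real_)
    rec <- data.frame(
      carrier_id = pop$carrier_id, family_id = pop$family_id,
      gene = config$gene, birth_year = pop$birth_year, country = pop$country,
      ashkenazi = pop$ashkenazi,
      age_recruit = pop$recruit,
      age_last_followup = pmax(fu_end, ifelse(affected, pop$onset, 0)),
      age_bc = if (breast) ev else NA_real_,
      er_status = NA_character_,
      age_oc = if (breast) NA_real_ else ev,
      age_mastectomy = ifelse(pop$mx < pmin(pop$onset, fu_end, 80), pop$mx, NA_real_),
      age_rrso = ifelse(pop$rrso < pmin(if (breast) Inf else pop$onset, fu_end, 80),
                        pop$rrso, NA_real_),
      fh_breast = pop$fh_breast, fh_ovarian = pop$fh_ovarian,
      variant_class = pop$variant_class,
      variant_location_group = pop$variant_location_group,
      pc1 = pop$pc1, pc2 = pop$pc2, pc3 = pop$pc3, pc4 = pop$pc4,
      prs_standardized = pop$z, stringsAsFactors = FALSE)
    if (breast && any(affected)) {
      er <- ifelse(stats::runif(sum(affected)) < config$er_positive_fraction,
                   "positive", "negative")
      er[stats::runif(sum(affected)) < config$er_missing_fraction] <- NA
      rec$er_status[affected] <- er
    }
    keep[[length(keep) + 1L]] <- rec
    got <- got + nrow(rec)
    if (got >= n) break
  }
  cohort <- do.call(rbind, keep)[seq_len(n), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort <- validate_carrier_cohort(cohort)
  n_inc <- if (breast) sum(!is.na(cohort$age_bc)) else sum(!is.na(cohort$age_oc))
  truth <- list(beta0 = config$beta0, beta1 = config$beta1,
                reference_age = config$reference_age,
                incidence = config$incidence, cancer = config$cancer,
                gene = config$gene, n_incident = n_inc, seed = config$seed)
  structure(list(cohort = cohort, truth = truth), class = "carrier_simulation")
}

#' Simulate Hardy-Weinberg genotype dosages for a weight table
#'
#' Each SNP's dosage is Binomial(2, f) at the table's effect-allele
#' frequency; columns are labelled with the table's effect alleles so no
#' harmonisation is needed.
#'
#' @param weights A `prs_weight_table` with `effect_allele_frequency`.
#' @param n Number of carriers.
#' @param seed Integer seed.
#' @return A [dosage_matrix()].
#' @export
simulate_genotypes <- function(weights, n, seed = 1L) {
  stopifnot(inherits(weights, "prs_weight_table"))
  f <- weights$effect_allele_frequency
  if (is.null(f) || any(is.na(f)))
    stop("simulate_genotypes requires effect_allele_frequency for every SNP")
  set.seed(seed)
  m <- vapply(f, function(fi) as.numeric(stats::rbinom(n, 2L, fi)), numeric(n))
  if (n == 1L) m <- matrix(m, nrow = 1L)
  dosage_matrix(m, carrier_ids = sprintf("C%07d", seq_len(n)),
                variant_ids = weights$variant_id,
                effect_allele = weights$effect_allele,
                other_allele = weights$other_allele)
}

#' Build a piecewise-constant incidence fixture with a given cumulative risk
#'
#' Produces a smooth annual incidence curve on ages 18-80 whose
#' single-decrement cumulative risk at age 80, \eqn{1 - \exp(-\int
#' \bar\lambda)}, equals `cumulative_target` exactly.  Shapes: `"breast"`
#' peaks in midlife (around age 47), `"ovarian"` rises late (around age 62),
#' `"flat"` is constant.
#'
#' @param cumulative_target Cumulative risk by age 80, in (0, 1).
#' @param shape `"breast"`, `"ovarian"`, or `"flat"`.
#' @param label Optional label for the curve.
#' @return An [incidence_curve()] on annual intervals 18-80.
#' @examples
#' cur <- make_incidence_fixture(0.72, "breast")
#' cumulative_risk(cur, 80)  # 0.72
#' @export
make_incidence_fixture <- function(cumulative_target,
                                   shape = c("breast", "ovarian", "flat"),
                                   label = NULL) {
  shape <- match.arg(shape)
  if (!is.finite(cumulative_target) || cumulative_target <= 0 ||
      cumulative_target >= 1)
    stop("cumulative_target must lie strictly in (0, 1)")
  ages <- 18:79
  s <- switch(shape,
              breast = exp(-((ages - 47) / 15)^2) + 0.02,
              ovarian = exp(-((ages - 62) / 12)^2) + 0.005,
              flat = rep(1, length(ages)))
  scale <- -log(1 - cumulative_target) / sum(s)
  incidence_curve(ages, ages + 1, scale * s, label = label)
}
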