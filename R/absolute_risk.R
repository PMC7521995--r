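#' Discretize the standard normal PRS into percentile categories
#'
#' The standardized PRS is taken to be standard normal in the carrier
#' population.  Each percentile category is represented by its probability
#' mass (the bin width) and the mean of the standard normal truncated to the
#' bin, \eqn{E[z \mid a < z < b] = (\phi(a) - \phi(b)) / (\Phi(b) - \Phi(a))}.
#'
#' @param bin_edges Increasing percentile boundaries strictly inside
#'   (0, 100); `n_bins` equal-probability bins are used instead when
#'   `bin_edges` is `NULL`.
#' @param n_bins Number of equal-probability bins when `bin_edges` is `NULL`
#'   (default 201, fine enough that discretization bias in headline risks is
#'   negligible).
#' @return An object of class `prs_mixture`: data frame with
#'   `representative_z`, `probability`, `lower_z`, `upper_z`.
#' @examples
#' m <- discretize_standard_normal(c(5, 10, 20, 40, 60, 80, 90, 95))
#' sum(m$probability)                    # 1
#' m$representative_z[9]                 # ~2.063, mean of the top 5%
#' @export
discretize_standard_normal <- function(bin_edges = NULL, n_bins = 201) {
  probs <- if (is.null(bin_edges)) seq(0, 1, length.out = n_bins + 1L)
  else {
    edges <- sort(unique(as.numeric(bin_edges)))
    if (any(edges <= 0 | edges >= 100)) stop("bin_edges must lie strictly in (0, 100)")
    c(0, edges / 100, 1)
  }
  a <- stats::qnorm(probs[-length(probs)])
  b <- stats::qnorm(probs[-1L])
  p <- diff(probs)
  z <- (stats::dnorm(a) - stats::dnorm(b)) / p
  structure(data.frame(representative_z = z, probability = p,
                       lower_z = a, upper_z = b),
            class = c("prs_mixture", "data.frame"))
}

rr_at_age <- function(z, age, beta0, beta1 = 0, reference_age = 0) {
  exp((beta0 + beta1 * (age - reference_age)) * z)
}

#' Solve the constrained baseline hazard over a PRS mixture
#'
#' Given an external average incidence curve for carriers, a per-SD log
#' hazard ratio (optionally linear in age), and a discretized PRS mixture,
#' solves for the PRS-specific penetrance curves whose mixture-average
#' age-specific incidence reproduces the external incidence at every age.
#'
#' The hazard for category \eqn{k} at age \eqn{t} is
#' \eqn{\lambda_0(t)\,RR_k(t)} with \eqn{RR_k(t) = \exp\{(\beta_0 + \beta_1
#' (t - c)) z_k\}}.  On an annual grid the baseline hazard is chosen at each
#' age so that the prevalence-weighted average annual disease probability
#' among women still unaffected equals the external annual probability
#' exactly:
#' \deqn{\sum_k p_k S_k(t) e^{-\lambda_0(t) RR_k(t)} =
#'       e^{-\bar\lambda(t)} \sum_k p_k S_k(t),}
#' solved by Newton iteration (the first-order ratio
#' \eqn{\bar\lambda \sum p_k S_k / \sum p_k S_k RR_k} is the starting
#' value).  Survivals are then depleted multiplicatively, so high-PRS
#' categories thin out of the unaffected pool with age (depletion of
#' susceptibles) and the mixture-average cumulative risk reproduces the
#' external cumulative risk to solver precision.
#'
#' @param external An [incidence_curve()] of average carrier incidence
#'   covering the age grid.
#' @param beta0 Per-SD log hazard ratio.
#' @param beta1 Per-year change in the log hazard ratio (default 0:
#'   age-constant effect).
#' @param reference_age Age at which `beta0` applies when `beta1 != 0`
#'   (default the first grid age).
#' @param mixture A `prs_mixture` (default 201 equal-probability bins).
#' @param age_range Annual age grid limits, default 20 to 80.
#' @return An object of class `penetrance_surface`: list with `age_grid`
#'   (ages 20..80), `baseline_hazard` (per year, one per grid interval),
#'   `survival` and `cumulative_risk` (matrices, ages x categories),
#'   `mixture`, `mixture_average_risk` (\eqn{\bar F(t)}), `beta0`, `beta1`,
#'   `reference_age`.
#' @export
solve_constrained_hazard <- function(external, beta0, beta1 = 0,
                                     reference_age = NULL,
                                     mixture = discretize_standard_normal(),
                                     age_range = c(20, 80)) {
  stopifnot(inherits(external, "incidence_curve"), inherits(mixture, "prs_mixture"))
  if (!is.finite(beta0) || !is.finite(beta1)) stop("log hazard ratios must be finite")
  ages <- seq(age_range[1L], age_range[2L])
  if (is.null(reference_age)) reference_age <- ages[1L]
  if (external$age_start[1L] > ages[1L] ||
      external$age_end[nrow(external)] < ages[length(ages)])
    stop("external curve does not cover the age grid [",
         ages[1L], ", ", ages[length(ages)], "]")
  K <- nrow(mixture)
  p <- mixture$probability
  z <- mixture$representative_z
  nT <- length(ages) - 1L
  S <- matrix(1, nrow = length(ages), ncol = K)
  lam0 <- numeric(nT)
  # external annual cumulative hazard over [t, t+1)
  lam_bar <- cumulative_hazard(external, ages[-1L]) -
    cumulative_hazard(external, ages[-length(ages)])

  for (i in seq_len(nT)) {
    rr <- rr_at_age(z, ages[i], beta0, beta1, reference_age)
    s <- S[i, ]
    ps <- p * s
    target <- sum(ps) * exp(-lam_bar[i])
    if (lam_bar[i] <= 0) {
      lam0[i] <- 0
    } else {
      # Newton on f(l) = sum(ps * exp(-l * rr)) - target, decreasing in l
      l <- lam_bar[i] * sum(ps) / sum(ps * rr)
      for (it in 1:50) {
        e <- exp(-l * rr)
        f <- sum(ps * e) - target
        fp <- -sum(ps * rr * e)
        step <- f / fp
        l <- l - step
        if (l < 0) l <- 1e-12
        if (abs(step) < 1e-14 * max(l, 1e-12)) break
      }
      lam0[i] <- l
    }
    S[i + 1L, ] <- s * exp(-lam0[i] * rr)
  }
  Fk <- 1 - S
  if (any(as.numeric(S %*% p) < 1e-12))
    stop("external incidence implies cumulative risk >= 1 before the end of the grid")
  structure(list(age_grid = ages, baseline_hazard = lam0,
                 survival = S, cumulative_risk = Fk, mixture = mixture,
                 mixture_average_risk = as.numeric(1 - S %*% p),
                 beta0 = beta0, beta1 = beta1, reference_age = reference_age,
                 external = external),
            class = "penetrance_surface")
}

#' @export
print.penetrance_surface <- function(x, ...) {
  cat("Penetrance surface on ages", min(x$age_grid), "-", max(x$age_grid),
      "with", nrow(x$mixture), "PRS categories\n")
  cat("mixture-average cumulative risk at", max(x$age_grid), "=",
      signif(x$mixture_average_risk[length(x$age_grid)], 4), "\n")
  invisible(x)
}

#' Cumulative risk curves at exact PRS percentiles
#'
#' Evaluates the solved baseline hazard at \eqn{z = \Phi^{-1}(pct/100)} for
#' the requested percentiles: the cumulative risk of a woman sitting exactly
#' at that percentile of the PRS distribution.
#'
#' @param surface A `penetrance_surface` from [solve_constrained_hazard()].
#' @param percentiles Percentiles in (0, 100), e.g. `c(5, 50, 95)`.
#' @return A data frame with `age`, `percentile`, `z`, `cumulative_risk`.
#' @export
risk_by_percentile <- function(surface, percentiles = c(5, 10, 25, 50, 75, 90, 95)) {
  stopifnot(inherits(surface, "penetrance_surface"))
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly in (0, 100)")
  ages <- surface$age_grid
  nT <- length(ages) - 1L
  out <- lapply(percentiles, function(pct) {
    zq <- stats::qnorm(pct / 100)
    rr <- rr_at_age(zq, ages[-length(ages)], surface$beta0, surface$beta1,
                    surface$reference_age)
    surv <- cumprod(c(1, exp(-surface$baseline_hazard * rr)))
    data.frame(age = ages, percentile = pct, z = zq,
               cumulative_risk = 1 - surv)
  })
  do.call(rbind, out)
}

#' Ten-year conditional risk at a PRS percentile
#'
#' The probability of disease within `[a, a + 10]` given disease-free
#' survival to age `a`:
#' \eqn{[F(a+10) - F(a)] / [1 - F(a)]}.
#'
#' @inheritParams risk_by_percentile
#' @param percentile A single percentile in (0, 100).
#' @param age Starting age(s) `a`; `a` and `a + 10` must lie on the grid.
#' @return Numeric vector of 10-year risks.
#' @export
ten_year_risk <- function(surface, percentile, age) {
  stopifnot(inherits(surface, "penetrance_surface"), length(percentile) == 1L)
  curve <- risk_by_percentile(surface, percentile)
  i0 <- match(age, curve$age)
  i1 <- match(age + 10, curve$age)
  if (any(is.na(i0)) || any(is.na(i1)))
    stop("age and age + 10 must lie on the surface's age grid")
  F0 <- curve$cumulative_risk[i0]
  F1 <- curve$cumulative_risk[i1]
  if (any(F0 >= 1 - 1e-12)) stop("cumulative risk already 1 at the starting age")
  (F1 - F0) / (1 - F0)
}

#' Subgroup penetrance surfaces
#'
#' Runs the constrained solver independently for each subgroup (e.g. family
#' history present/absent, or variant-location groups), using
#' subgroup-specific external average incidence curves and a shared per-SD
#' hazard ratio.
#'
#' @param external_by_group Named list of [incidence_curve()]s, one per
#'   subgroup.
#' @inheritParams solve_constrained_hazard
#' @return Named list of `penetrance_surface` objects.
#' @export
subgroup_risks <- function(external_by_group, beta0, beta1 = 0,
                           reference_age = NULL,
                           mixture = discretize_standard_normal(),
                           age_range = c(20, 80)) {
  if (!length(external_by_group) || is.null(names(external_by_group)) ||
      any(names(external_by_group) == ""))
    stop("external_by_group must be a named list with one curve per group")
  lapply(external_by_group, function(cur) {
    if (is.null(cur)) stop("missing incidence curve for a group")
    solve_constrained_hazard(cur, beta0, beta1, reference_age, mixture, age_range)
  })
}

#' Tidy export of a penetrance surface
#'
#' @param surface A `penetrance_surface`.
#' @param percentiles Percentiles to tabulate.
#' @param ten_year_ages Starting ages for 10-year risks (must have
#'   `age + 10` on the grid).
#' @return Data frame with `age`, `percentile`, `cumulative_risk`,
#'   `ten_year_risk` (`NA` where `age + 10` leaves the grid).
#' @export
surface_table <- function(surface, percentiles = c(5, 10, 25, 50, 75, 90, 95),
                          ten_year_ages = NULL) {
  tab <- risk_by_percentile(surface, percentiles)
  if (is.null(ten_year_ages))
    ten_year_ages <- surface$age_grid[surface$age_grid + 10 <= max(surface$age_grid)]
  tab$ten_year_risk <- NA_real_
  for (pct in percentiles) {
    sel <- tab$percentile == pct & tab$age %in% ten_year_ages
    tab$ten_year_risk[sel] <- ten_year_risk(surface, pct, tab$age[sel])
  }
  tab[, c("age", "percentile", "cumulative_risk", "ten_year_risk")]
}
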