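#' Calibrate ascertainment sampling weights against external incidence
#'
#' Carriers recruited through cancer genetics clinics over-represent affected
#' women, so an unweighted Cox fit on the retrospective cohort is biased.
#' The weighted-cohort correction assigns age- and disease-specific sampling
#' weights so that the weighted age-specific incidence in the sample agrees
#' with established external incidence for carriers.
#'
#' Within each age bin \eqn{j} (binned by the age at which follow-up ends):
#' \itemize{
#'   \item \eqn{q_j} = observed fraction of affected among carriers exiting
#'     in the bin;
#'   \item \eqn{p_j} = expected fraction, computed as the expected number of
#'     events under the external incidence given the cohort's person-time in
#'     the bin, divided by the number of exits in the bin;
#'   \item affected carriers get weight \eqn{p_j/q_j}, unaffected
#'     \eqn{(1-p_j)/(1-q_j)}.
#' }
#' The weighted affected fraction within each bin then equals \eqn{p_j}
#' exactly.  Bins default to 18-25, 5-year intervals to 70, then 70-80 (the
#' tails are widened so that every bin holds both affected and unaffected
#' exits in moderately sized cohorts).
#'
#' @param dataset An `analysis_dataset` (see [build_analysis_dataset()]).
#' @param external An [incidence_curve()] of established carrier incidence
#'   for the outcome.
#' @param age_bins Increasing vector of bin breaks covering all exit ages.
#' @param merge_sparse When `TRUE`, a bin whose exits are all affected or
#'   all unaffected (or empty) is merged into its left neighbour with a
#'   warning instead of raising an error; useful for unattended pipelines
#'   on modest cohorts where tail bins can be sparse.
#' @return A list with
#'   \item{scheme}{class `sampling_weight_scheme`: data frame of
#'     `age_start`, `age_end`, `n_exits`, `n_affected`, `observed_fraction`
#'     (q), `target_fraction` (p), `weight_affected`, `weight_unaffected`.}
#'   \item{dataset}{the input dataset with `sampling_weight` filled in.}
#' @export
calibrate_sampling_weights <- function(dataset, external,
                                       age_bins = c(18, seq(25, 70, by = 5), 80),
                                       merge_sparse = FALSE) {
  stopifnot(inherits(dataset, "analysis_dataset"), inherits(external, "incidence_curve"))
  age_bins <- sort(unique(as.numeric(age_bins)))
  if (length(age_bins) < 2L) stop("need at least one age bin")
  if (min(dataset$exit_age) < age_bins[1L] || max(dataset$exit_age) > age_bins[length(age_bins)])
    stop("age_bins do not cover all exit ages (",
         signif(min(dataset$exit_age), 4), "-", signif(max(dataset$exit_age), 4), ")")
  if (merge_sparse) {
    repeat {
      nb <- length(age_bins) - 1L
      if (nb < 2L) break
      bin <- pmin(findInterval(dataset$exit_age, age_bins), nb)
      ne <- tabulate(bin, nb)
      na <- tabulate(bin[dataset$event == 1L], nb)
      bad <- which(ne == 0L | na == 0L | na == ne)
      if (!length(bad)) break
      drop <- if (bad[1L] == 1L) 2L else bad[1L]   # merge into left neighbour
      warning("merging sparse calibration bin at age ", age_bins[drop],
              " into its neighbour")
      age_bins <- age_bins[-drop]
    }
  }
  nb <- length(age_bins) - 1L
  # bin of each subject's exit age; exits exactly at the top break go to the last bin
  bin <- pmin(findInterval(dataset$exit_age, age_bins), nb)

  n_exit <- tabulate(bin, nb)
  n_aff <- tabulate(bin[dataset$event == 1L], nb)
  if (any(n_exit == 0L))
    stop("age bin(s) with no exits: ",
         paste(sprintf("[%g,%g)", age_bins[which(n_exit == 0)],
                       age_bins[which(n_exit == 0) + 1L]), collapse = ", "),
         "; use coarser bins")

  # expected events per bin: each subject's person-time in the bin integrated
  # against the external hazard
  expected <- vapply(seq_len(nb), function(j) {
    lo <- pmax(dataset$entry_age, age_bins[j])
    hi <- pmin(dataset$exit_age, age_bins[j + 1L])
    at_risk <- hi > lo
    if (!any(at_risk)) return(0)
    sum(cumulative_hazard(external, hi[at_risk]) -
          cumulative_hazard(external, lo[at_risk]))
  }, numeric(1))

  p <- expected / n_exit
  q <- n_aff / n_exit
  bad_q <- q <= 0 | q >= 1
  if (any(bad_q))
    stop("observed affected fraction is 0 or 1 in bin(s) ",
         paste(sprintf("[%g,%g)", age_bins[which(bad_q)], age_bins[which(bad_q) + 1L]),
               collapse = ", "), "; use coarser bins")
  if (any(p <= 0 | p >= 1))
    stop("target affected fraction outside (0,1); external incidence ",
         "incompatible with the cohort's person-time in some bin")

  w_aff <- p / q
  w_un <- (1 - p) / (1 - q)
  dataset$sampling_weight <- ifelse(dataset$event == 1L, w_aff[bin], w_un[bin])

  scheme <- data.frame(age_start = age_bins[-length(age_bins)],
                       age_end = age_bins[-1L],
                       n_exits = n_exit, n_affected = n_aff,
                       observed_fraction = q, target_fraction = p,
                       weight_affected = w_aff, weight_unaffected = w_un)
  class(scheme) <- c("sampling_weight_scheme", "data.frame")
  list(scheme = scheme, dataset = dataset)
}
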