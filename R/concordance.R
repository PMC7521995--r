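#' Harrell's concordance with a family-cluster bootstrap
#'
#' Computes Harrell's C for a fitted model's linear predictor on the
#' analysis dataset: the proportion of usable pairs (an event versus a
#' subject still at risk at that event's age) ranked concordantly by the
#' risk score.  Pairs are formed within the country x Ashkenazi strata and
#' pooled across strata, weighting each stratum by its number of usable
#' pairs.  Standard errors come from a bootstrap that resamples whole
#' families, respecting the within-family correlation.
#'
#' @param dataset The `analysis_dataset` the model was fitted to.
#' @param fit A `cox_fit`, or a numeric risk score of length `nrow(dataset)`.
#' @param n_bootstrap Number of cluster-bootstrap replicates (0 skips the
#'   SE; published analyses used 1000).
#' @param seed Integer seed for the bootstrap.
#' @param stratify Pool pairs within strata (default `TRUE`).
#' @return A list with `c_statistic`, `bootstrap_se` (`NA` when
#'   `n_bootstrap = 0`), `n_bootstrap`, `n_pairs`.
#' @export
concordance_index <- function(dataset, fit, n_bootstrap = 0, seed = 1,
                              stratify = TRUE) {
  score <- if (inherits(fit, "cox_fit")) predict(fit, dataset) else as.numeric(fit)
  if (length(score) != nrow(dataset))
    stop("risk score length does not match the dataset")
  dat <- data.frame(entry_age = dataset$entry_age, exit_age = dataset$exit_age,
                    event = dataset$event, score = score,
                    stratum = if (stratify && !is.null(dataset$stratum))
                      dataset$stratum else "all",
                    cluster = if (!is.null(dataset$cluster)) dataset$cluster
                    else seq_len(nrow(dataset)))

  cfit <- survival::concordance(
    survival::Surv(entry_age, exit_age, event) ~ score + strata(stratum),
    data = dat, reverse = TRUE)
  counts <- if (is.matrix(cfit$count)) colSums(cfit$count) else cfit$count
  n_pairs <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no comparable pairs")

  se <- NA_real_
  if (n_bootstrap > 0) {
    set.seed(seed)
    fams <- split(seq_len(nrow(dat)), dat$cluster)
    cs <- vapply(seq_len(n_bootstrap), function(b) {
      take <- sample(length(fams), replace = TRUE)
      idx <- unlist(fams[take], use.names = FALSE)
      bd <- dat[idx, ]
      bc <- try(survival::concordance(
        survival::Surv(entry_age, exit_age, event) ~ score + strata(stratum),
        data = bd, reverse = TRUE), silent = TRUE)
      if (inherits(bc, "try-error")) NA_real_ else bc$concordance
    }, numeric(1))
    se <- stats::sd(cs, na.rm = TRUE)
  }
  list(c_statistic = unname(cfit$concordance), bootstrap_se = se,
       n_bootstrap = n_bootstrap, n_pairs = unname(n_pairs))
}
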