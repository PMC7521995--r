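# Independent oracles and small fixture builders used across the suite.

# Weighted Cox partial log-likelihood computed by direct enumeration of risk
# sets (Breslow form; identical to Efron when event times are untied).
# Independent of the fitting code: used to cross-check coxph-based fits.
brute_cox_loglik <- function(beta, time, status, z, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(status == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + w[i] * (beta * z[i] -
                         log(sum(w[at_risk] * exp(beta * z[at_risk]))))
  }
  ll
}

brute_cox_mle <- function(time, status, z, w = rep(1, length(time))) {
  stats::optimize(function(b) -brute_cox_loglik(b, time, status, z, w),
                  interval = c(-8, 8), tol = 1e-10)$minimum
}

# Harrell's C by exhaustive pair enumeration: usable pairs are an event and a
# subject whose observed exit is later (entry before the event age).
brute_concordance <- function(entry, exit, event, score) {
  conc <- disc <- tied <- 0
  n <- length(exit)
  for (i in which(event == 1)) {
    for (j in seq_len(n)) {
      if (j == i) next
      usable <- exit[j] > exit[i] && entry[j] < exit[i]
      if (!usable) next
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] < score[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# Minimal weight table for PRS arithmetic.
toy_weight_table <- function(weights = c(0.1, -0.2, 0.05),
                             freq = rep(0.5, length(weights))) {
  n <- length(weights)
  validate_weight_table(data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chromosome = rep("1", n), position = seq_len(n) * 1000L,
    effect_allele = rep("A", n), other_allele = rep("G", n),
    weight = weights, effect_allele_frequency = freq,
    stringsAsFactors = FALSE))
}

# One-row carrier record with overridable fields.
toy_carrier <- function(...) {
  rec <- list(carrier_id = "c1", family_id = "f1", gene = "BRCA1",
              birth_year = 1960, country = "A", ashkenazi = 0,
              age_recruit = 30, age_last_followup = 70, age_bc = NA_real_,
              er_status = NA_character_, age_oc = NA_real_,
              age_mastectomy = NA_real_, age_rrso = NA_real_,
              fh_breast = 0, fh_ovarian = 0, variant_class = "I",
              variant_location_group = "region1",
              pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0, prs_standardized = 0)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

toy_cohort <- function(...) {
  recs <- list(...)
  df <- do.call(rbind, recs)
  df$carrier_id <- paste0("c", seq_len(nrow(df)))
  validate_carrier_cohort(df)
}

# Hand-built analysis dataset (bypasses the cohort builder) for Cox oracles.
toy_dataset <- function(time, status, z, w = rep(1, length(time)),
                        entry = rep(0, length(time)),
                        stratum = rep("s", length(time)),
                        cluster = seq_along(time)) {
  ds <- data.frame(carrier_id = paste0("c", seq_along(time)),
                   entry_age = entry, exit_age = time, event = status,
                   stratum = stratum, cluster = cluster,
                   sampling_weight = w, prs = z, fh = 0)
  class(ds) <- c("analysis_dataset", "data.frame")
  ds
}

default_sim_config <- function(n = 4000, cancer = "breast", beta0 = log(1.3),
                               target = 0.72, seed = 11L, ...) {
  simulation_config(
    n_carriers = n, cancer = cancer, beta0 = beta0,
    incidence = make_incidence_fixture(target, cancer), seed = seed, ...)
}
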