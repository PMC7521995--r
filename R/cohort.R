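#' Validate a carrier cohort table
#'
#' A carrier cohort is one row per woman carrying a BRCA1 or BRCA2 pathogenic
#' variant.  Required columns:
#' `carrier_id`, `family_id`, `gene` (`"BRCA1"`/`"BRCA2"`), `birth_year`,
#' `country`, `ashkenazi` (0/1), `age_recruit`, `age_last_followup`,
#' `age_bc`, `er_status` (`"positive"`/`"negative"`/`NA`), `age_oc`,
#' `age_mastectomy`, `age_rrso`, `fh_breast`, `fh_ovarian` (0, 1, 2 for
#' none / one / two-plus affected relatives), `variant_class`
#' (`"I"`/`"II"`/`NA`), `variant_location_group`, `pc1`..`pc4`,
#' `prs_standardized`.  Event and surgery ages are `NA` when the event did
#' not occur.
#'
#' @param cohort A data frame.
#' @return The cohort with class `carrier_cohort` prepended.
#' @export
validate_carrier_cohort <- function(cohort) {
  need <- c("carrier_id", "family_id", "gene", "birth_year", "country",
            "ashkenazi", "age_recruit", "age_last_followup", "age_bc",
            "er_status", "age_oc", "age_mastectomy", "age_rrso", "fh_breast",
            "fh_ovarian", "variant_class", "variant_location_group",
            "pc1", "pc2", "pc3", "pc4", "prs_standardized")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$carrier_id)) stop("duplicate carrier_id in cohort")
  age_cols <- c("age_recruit", "age_last_followup", "age_bc", "age_oc",
                "age_mastectomy", "age_rrso")
  for (cl in age_cols) {
    a <- cohort[[cl]]
    if (any(!is.na(a) & (a <= 0 | a > 120)))
      stop("implausible ", cl, " outside (0, 120]")
  }
  for (ev in c("age_bc", "age_oc")) {
    late <- !is.na(cohort[[ev]]) & cohort[[ev]] > cohort$age_last_followup + 1e-9
    if (any(late))
      stop(ev, " after age_last_followup for carrier(s): ",
           paste(utils::head(cohort$carrier_id[late], 10), collapse = ", "))
  }
  if (!inherits(cohort, "carrier_cohort"))
    class(cohort) <- c("carrier_cohort", class(cohort))
  cohort
}

#' Read a carrier cohort from CSV
#'
#' Missing values are empty fields; ages are in years (fractional allowed).
#'
#' @param path Path to the CSV file.
#' @return A validated `carrier_cohort` data frame.
#' @export
read_carrier_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, na.strings = c("", "NA"), comment.char = "#")
  validate_carrier_cohort(df)
}

pmin_na <- function(...) {
  do.call(pmin, c(lapply(list(...), function(x) ifelse(is.na(x), Inf, x)),
                  na.rm = TRUE))
}

#' Build an outcome-specific analysis dataset
#'
#' Applies the study censoring rules to a carrier cohort and returns one
#' survival row per included carrier with age as the time scale.
#'
#' For the breast-cancer outcome a carrier is followed to the first of
#' breast cancer diagnosis, ovarian cancer diagnosis, risk-reducing bilateral
#' mastectomy, last follow-up, or age 80; she is an event only when breast
#' cancer comes first.  ER-specific outcomes use the same censoring but count
#' only diagnoses of the matching ER status as events — a diagnosis of the
#' opposite status censors at that age, and carriers with a breast cancer of
#' missing ER status are excluded.  The ovarian outcome censors at
#' risk-reducing salpingo-oophorectomy (RRSO) instead of mastectomy and, by
#' default, also at a breast cancer diagnosis
#' (`censor_ovarian_at_bc = FALSE` disables this).
#'
#' In retrospective mode entry age is 0 (the whole life course contributes to
#' the risk sets); in prospective mode entry is the recruitment age, and
#' carriers already affected at recruitment (or with no follow-up beyond it)
#' are excluded.
#'
#' @param cohort A `carrier_cohort` (see [validate_carrier_cohort()]).
#' @param outcome One of `"breast"`, `"er_positive"`, `"er_negative"`,
#'   `"ovarian"`.
#' @param mode `"retrospective"` (default) or `"prospective"`.
#' @param covariates Cohort columns carried through for model fitting; the
#'   standardized PRS is always carried (as column `prs`).
#' @param censor_ovarian_at_bc Should a breast-cancer diagnosis censor the
#'   ovarian analysis?  Default `TRUE`.
#' @param max_age Administrative censoring age (default 80).
#' @return An `analysis_dataset` data frame: `carrier_id`, `entry_age`,
#'   `exit_age`, `event`, `stratum` (country x Ashkenazi), `cluster`
#'   (family), `sampling_weight` (1 until calibrated), `prs`, plus the
#'   requested covariates and `fh` (outcome-relevant family-history
#'   category).
#' @export
build_analysis_dataset <- function(cohort,
                                   outcome = c("breast", "er_positive",
                                               "er_negative", "ovarian"),
                                   mode = c("retrospective", "prospective"),
                                   covariates = c("birth_year", "pc1", "pc2",
                                                  "pc3", "pc4"),
                                   censor_ovarian_at_bc = TRUE,
                                   max_age = 80) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  cohort <- validate_carrier_cohort(cohort)

  if (outcome %in% c("breast", "er_positive", "er_negative")) {
    exit <- pmin_na(cohort$age_bc, cohort$age_oc, cohort$age_mastectomy,
                    cohort$age_last_followup, max_age)
    is_bc_first <- !is.na(cohort$age_bc) & cohort$age_bc <= exit
    if (outcome == "breast") {
      event <- is_bc_first
      keep <- rep(TRUE, nrow(cohort))
    } else {
      want <- if (outcome == "er_positive") "positive" else "negative"
      er <- as.character(cohort$er_status)
      # carriers whose breast cancer has unknown ER status cannot be
      # classified for either subtype and are excluded entirely
      keep <- !(is_bc_first & (is.na(er) | !er %in% c("positive", "negative")))
      event <- is_bc_first & !is.na(er) & er == want
    }
    fh <- cohort$fh_breast
  } else {
    bc_censor <- if (censor_ovarian_at_bc) cohort$age_bc else NA_real_
    exit <- pmin_na(cohort$age_oc, cohort$age_rrso, bc_censor,
                    cohort$age_last_followup, max_age)
    event <- !is.na(cohort$age_oc) & cohort$age_oc <= exit
    keep <- rep(TRUE, nrow(cohort))
    fh <- cohort$fh_ovarian
  }

  entry <- if (mode == "retrospective") rep(0, nrow(cohort)) else cohort$age_recruit
  if (mode == "prospective") {
    if (any(is.na(entry))) stop("prospective mode requires age_recruit for all carriers")
    # exclude carriers affected (or censored) at/before recruitment
    keep <- keep & exit > entry
  }

  miss_cov <- setdiff(covariates, names(cohort))
  if (length(miss_cov)) stop("covariate column(s) not in cohort: ",
                             paste(miss_cov, collapse = ", "))

  ds <- data.frame(carrier_id = cohort$carrier_id,
                   entry_age = entry,
                   exit_age = exit,
                   event = as.integer(event),
                   stratum = paste0(cohort$country, ":",
                                    ifelse(cohort$ashkenazi > 0, "AJ", "nonAJ")),
                   cluster = cohort$family_id,
                   sampling_weight = 1,
                   prs = cohort$prs_standardized,
                   fh = fh,
                   stringsAsFactors = FALSE)
  for (cv in covariates) ds[[cv]] <- cohort[[cv]]
  ds <- ds[keep & ds$exit_age > ds$entry_age, , drop = FALSE]
  rownames(ds) <- NULL
  attr(ds, "outcome") <- outcome
  attr(ds, "mode") <- mode
  attr(ds, "covariates") <- covariates
  class(ds) <- c("analysis_dataset", "data.frame")
  ds
}

#' Expand the family-history category into indicator covariates
#'
#' Family history is coded as no affected relative, one, or two or more; the
#' model uses two indicators against the no-history baseline.
#'
#' @param dataset An `analysis_dataset` with an `fh` column.
#' @return The dataset with `fh1` (exactly one relative) and `fh2`
#'   (two or more) indicator columns.
#' @export
add_fh_indicators <- function(dataset) {
  if (is.null(dataset$fh)) stop("dataset has no 'fh' column")
  fh <- pmin(as.numeric(dataset$fh), 2)
  dataset$fh1 <- as.integer(fh == 1)
  dataset$fh2 <- as.integer(fh >= 2)
  dataset
}
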