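#' Compute a raw polygenic risk score
#'
#' The raw PRS of carrier \eqn{j} is the weighted sum of effect-allele
#' dosages, \eqn{\sum_i w_i g_{ij}}.  Missing dosages are handled per
#' `missing_policy`:
#' \describe{
#'   \item{`"mean_impute"`}{replace a missing dosage with its Hardy-Weinberg
#'     expectation `2 * effect_allele_frequency`; SNPs without a frequency are
#'     dropped for the affected carriers with a warning.  A SNP absent from
#'     the dosage matrix altogether and lacking a frequency is an error.}
#'   \item{`"drop"`}{missing dosages contribute 0 (the SNP is dropped for
#'     that carrier), with a warning.}
#'   \item{`"error"`}{any missing dosage is an error listing the variants.}
#' }
#'
#' @param weights A `prs_weight_table` (see [read_weight_table()]).
#' @param dosages A [dosage_matrix()], already oriented to the weight table's
#'   effect alleles (see [harmonize_dosages()]).
#' @param missing_policy One of `"mean_impute"` (default), `"drop"`,
#'   `"error"`.
#' @return An object of class `prs_vector`: a list with `carrier_ids`, `raw`,
#'   `standardized` (`NA` until [standardize_prs()] is applied),
#'   `reference_sd`, `reference_mean`.
#' @examples
#' wt <- validate_weight_table(data.frame(
#'   variant_id = c("rs1", "rs2", "rs3"), chromosome = "1",
#'   position = 1:3, effect_allele = "A", other_allele = "G",
#'   weight = c(0.1, -0.2, 0.05)))
#' dm <- dosage_matrix(matrix(c(1, 2, 0), 1), "c1", c("rs1", "rs2", "rs3"))
#' compute_prs(wt, dm)$raw   # -0.3
#' @export
compute_prs <- function(weights, dosages,
                        missing_policy = c("mean_impute", "drop", "error")) {
  stopifnot(inherits(weights, "prs_weight_table"), inherits(dosages, "dosage_matrix"))
  missing_policy <- match.arg(missing_policy)
  ids <- weights$variant_id
  present <- ids %in% dosages$variant_ids
  freq <- weights$effect_allele_frequency
  if (is.null(freq)) freq <- rep(NA_real_, nrow(weights))

  absent <- ids[!present]
  if (length(absent)) {
    if (missing_policy == "error")
      stop("variant(s) in weight table absent from dosages: ",
           paste(absent, collapse = ", "))
    no_f <- absent[is.na(freq[!present])]
    if (missing_policy == "mean_impute" && length(no_f))
      stop("cannot mean-impute variant(s) without effect_allele_frequency: ",
           paste(no_f, collapse = ", "))
  }

  g <- matrix(NA_real_, nrow = length(dosages$carrier_ids), ncol = nrow(weights),
              dimnames = list(dosages$carrier_ids, ids))
  g[, ids[present]] <- dosages$dosages[, ids[present], drop = FALSE]

  n_missing <- sum(is.na(g))
  if (n_missing) {
    if (missing_policy == "error") {
      bad <- ids[colSums(is.na(g)) > 0]
      stop("missing dosages for variant(s): ", paste(bad, collapse = ", "))
    }
    if (missing_policy == "mean_impute") {
      imp <- matrix(2 * freq, nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
      can <- is.na(g) & !is.na(imp)
      g[can] <- imp[can]
      if (any(is.na(g))) {
        dropped <- ids[colSums(is.na(g)) > 0]
        warning("no frequency for variant(s) ", paste(dropped, collapse = ", "),
                "; dropped for carriers with missing dosage")
      }
    } else {
      warning(n_missing, " missing dosage(s) dropped (contribute 0)")
    }
    g[is.na(g)] <- 0
  }

  raw <- as.numeric(g %*% weights$weight)
  structure(list(carrier_ids = dosages$carrier_ids, raw = raw,
                 standardized = rep(NA_real_, length(raw)),
                 reference_sd = NA_real_, reference_mean = NA_real_),
            class = "prs_vector")
}

#' Standardize a PRS against an external reference
#'
#' Divides the centred raw score by the standard deviation of the same PRS in
#' an external reference group, so that hazard ratios estimated per unit of
#' the standardized score are per reference-population SD and directly
#' comparable with population-based per-SD odds ratios.  Breast-cancer scores
#' are conventionally standardized to population-based controls; ovarian
#' scores to unaffected women in the analysis sample.
#'
#' @param prs A `prs_vector` from [compute_prs()].
#' @param reference_sd Positive SD of the raw PRS in the reference group.
#' @param reference_mean Mean of the raw PRS in the reference group
#'   (default 0, i.e. scaling only).
#' @return The `prs_vector` with `standardized` populated.
#' @export
standardize_prs <- function(prs, reference_sd, reference_mean = 0) {
  stopifnot(inherits(prs, "prs_vector"))
  if (!is.finite(reference_sd) || reference_sd <= 0)
    stop("reference_sd must be a positive number")
  prs$standardized <- (prs$raw - reference_mean) / reference_sd
  prs$reference_sd <- reference_sd
  prs$reference_mean <- reference_mean
  prs
}

#' @export
print.prs_vector <- function(x, ...) {
  cat("PRS for", length(x$carrier_ids), "carriers; raw mean",
      signif(mean(x$raw), 4), "sd", signif(stats::sd(x$raw), 4))
  if (!is.na(x$reference_sd))
    cat("; standardized to reference sd", signif(x$reference_sd, 4))
  cat("\n")
  invisible(x)
}

#' Assign PRS percentile categories
#'
#' Thresholds are empirical quantiles (type 7) of the PRS distribution in a
#' reference subset — conventionally the unaffected carriers for the disease
#' under assessment.  Every carrier is then labelled with the half-open
#' category `[lower, upper)` its score falls in.  The default edges give the
#' nine reporting categories 0-5, 5-10, 10-20, 20-40, 40-60 (reference),
#' 60-80, 80-90, 90-95, 95-100.
#'
#' @param prs A `prs_vector`; standardized scores are used when available,
#'   raw scores otherwise.
#' @param reference_ids Carrier ids forming the reference distribution.
#' @param scheme_edges Increasing percentile boundaries strictly inside
#'   (0, 100).
#' @param reference_bin Index of the category used as baseline in categorical
#'   fits; default the category containing the median.
#' @return A list with `scheme` (class `percentile_scheme`: `bin_edges`,
#'   `thresholds`, `labels`, `reference_bin`) and `category`, a factor per
#'   carrier whose levels are the category labels with the reference bin as
#'   first (baseline) level.
#' @export
assign_percentiles <- function(prs, reference_ids,
                               scheme_edges = c(5, 10, 20, 40, 60, 80, 90, 95),
                               reference_bin = NULL) {
  stopifnot(inherits(prs, "prs_vector"))
  vals <- if (all(is.na(prs$standardized))) prs$raw else prs$standardized
  ref <- vals[prs$carrier_ids %in% reference_ids]
  if (!length(ref)) stop("reference set is empty")
  edges <- sort(unique(as.numeric(scheme_edges)))
  if (any(edges <= 0 | edges >= 100)) stop("scheme_edges must lie strictly in (0, 100)")
  n_cat <- length(edges) + 1L
  if (length(ref) < n_cat)
    stop("reference set (n=", length(ref), ") smaller than the number of categories (", n_cat, ")")
  if (stats::sd(ref) == 0 || diff(range(ref)) == 0)
    stop("degenerate reference distribution: all reference PRS values identical")
  thresholds <- as.numeric(stats::quantile(ref, probs = edges / 100, type = 7))
  labels <- paste0(c(0, edges), "-", c(edges, 100))
  if (is.null(reference_bin)) reference_bin <- findInterval(50, c(0, edges))
  if (reference_bin < 1L || reference_bin > n_cat) stop("invalid reference_bin")
  # half-open [lower, upper): a value equal to a threshold goes to the upper bin
  cat_idx <- findInterval(vals, thresholds) + 1L
  category <- factor(labels[cat_idx],
                     levels = c(labels[reference_bin], labels[-reference_bin]))
  scheme <- structure(list(bin_edges = edges, thresholds = thresholds,
                           labels = labels, reference_bin = reference_bin),
                      class = "percentile_scheme")
  list(scheme = scheme, category = category)
}
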