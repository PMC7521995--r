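#' Age-specific incidence curves
#'
#' An incidence curve is a piecewise-constant hazard on contiguous, half-open
#' age intervals `[age_start, age_end)`, expressed as events per person-year.
#' Curves are used in two places: as the external average carrier incidence
#' that sampling weights are calibrated against, and as the average incidence
#' that the constrained penetrance solver reproduces across PRS categories.
#'
#' @param age_start,age_end Numeric vectors of interval bounds (years).
#'   Intervals must be contiguous and non-overlapping.
#' @param incidence Non-negative incidence per person-year on each interval.
#' @param label Optional character label (e.g. `"BRCA1 breast"`).
#' @return An object of class `incidence_curve`: a data frame with columns
#'   `age_start`, `age_end`, `incidence`.
#' @examples
#' flat <- incidence_curve(18, 80, 0.02)
#' cumulative_risk(flat, 80)
#' @export
incidence_curve <- function(age_start, age_end, incidence, label = NULL) {
  df <- data.frame(age_start = as.numeric(age_start),
                   age_end = as.numeric(age_end),
                   incidence = as.numeric(incidence))
  df <- df[order(df$age_start), , drop = FALSE]
  if (nrow(df) == 0L) stop("incidence curve has no intervals")
  if (any(!is.finite(df$incidence)) || any(df$incidence < 0))
    stop("incidences must be finite and non-negative")
  if (any(df$age_end <= df$age_start))
    stop("each interval must have age_end > age_start")
  if (nrow(df) > 1L && any(abs(df$age_start[-1L] - df$age_end[-nrow(df)]) > 1e-8))
    stop("intervals must be contiguous and non-overlapping")
  rownames(df) <- NULL
  structure(df, label = label, class = c("incidence_curve", "data.frame"))
}

#' Read an incidence curve from CSV
#'
#' Expects columns `age_start`, `age_end`, `incidence_per_year` (half-open
#' intervals `[age_start, age_end)`).
#'
#' @param path Path to a CSV file.
#' @param label Optional label attached to the curve.
#' @return An [incidence_curve()].
#' @export
read_incidence_curve <- function(path, label = NULL) {
  if (!file.exists(path)) stop("incidence file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("age_start", "age_end", "incidence_per_year")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("incidence file missing column(s): ",
                         paste(miss, collapse = ", "))
  incidence_curve(df$age_start, df$age_end, df$incidence_per_year, label = label)
}

#' Write an incidence curve to CSV
#' @param curve An [incidence_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence_curve <- function(curve, path) {
  stopifnot(inherits(curve, "incidence_curve"))
  out <- data.frame(age_start = curve$age_start, age_end = curve$age_end,
                    incidence_per_year = curve$incidence)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Hazard at given ages
#'
#' Looks up the piecewise-constant hazard; ages outside the covered range get
#' hazard 0.
#'
#' @param curve An [incidence_curve()].
#' @param ages Numeric vector of ages.
#' @return Numeric vector of hazards (per year).
#' @export
hazard_at <- function(curve, ages) {
  stopifnot(inherits(curve, "incidence_curve"))
  idx <- findInterval(ages, c(curve$age_start[1L], curve$age_end))
  out <- numeric(length(ages))
  ok <- idx >= 1L & idx <= nrow(curve) & ages < curve$age_end[nrow(curve)]
  out[ok] <- curve$incidence[idx[ok]]
  out
}

#' Cumulative hazard of an incidence curve
#'
#' Integrates the piecewise-constant hazard from the start of the curve to
#' `age`.
#'
#' @param curve An [incidence_curve()].
#' @param age Numeric vector of ages.
#' @return Cumulative hazard at each age.
#' @export
cumulative_hazard <- function(curve, age) {
  stopifnot(inherits(curve, "incidence_curve"))
  vapply(age, function(a) {
    lo <- pmax(curve$age_start, curve$age_start[1L])
    hi <- pmin(curve$age_end, a)
    sum(pmax(hi - lo, 0) * curve$incidence)
  }, numeric(1))
}

#' Cumulative risk implied by an incidence curve
#'
#' Single-decrement cumulative risk \eqn{1 - \exp(-\Lambda(a))}.
#'
#' @inheritParams cumulative_hazard
#' @return Cumulative risk at each age.
#' @export
cumulative_risk <- function(curve, age) {
  1 - exp(-cumulative_hazard(curve, age))
}
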