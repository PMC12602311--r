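#' Z-transform (mean centring, unit variance scaling)
#'
#' Standardises a vector against a reference population (by default itself),
#' retaining the transform parameters as attributes so values can be mapped
#' back to the original scale. Uses the sample SD (n-1 denominator). NAs are
#' ignored when computing the reference moments and propagate through the
#' transform.
#'
#' @param values Numeric vector.
#' @param reference Optional reference vector supplying mean/SD.
#' @return Numeric vector of z-scores with attributes `center` and `scale`.
#' @export
z_transform <- function(values, reference = values) {
  m <- mean(reference, na.rm = TRUE)
  s <- stats::sd(reference, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("reference has zero variance; cannot z-transform")
  structure((values - m) / s, center = m, scale = s)
}

#' Inverse of [z_transform()]
#' @param z Z-scored vector carrying `center`/`scale` attributes (or supply
#'   them explicitly).
#' @param center,scale Transform parameters.
#' @return Vector on the original scale.
#' @export
z_inverse <- function(z, center = attr(z, "center"), scale = attr(z, "scale")) {
  as.numeric(z) * scale + center
}

#' Outlier exclusion mask (mean +/- 3 SD)
#'
#' Returns TRUE for observations within three SDs of the mean, with mean and
#' SD computed once on the full vector (no iterative re-computation). A
#' constant vector has a degenerate band equal to the constant, so nothing is
#' excluded. NA observations are marked FALSE.
#'
#' @param values Numeric vector (>= 3 non-missing observations).
#' @param n_sd Width of the inclusion band in SDs (default 3).
#' @return Logical inclusion mask.
#' @export
exclude_outliers <- function(values, n_sd = 3) {
  ok <- is.finite(values)
  if (sum(ok) < 3) stop("need at least 3 observations to screen outliers")
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  mask <- ok & abs(values - m) <= n_sd * s
  mask[is.na(mask)] <- FALSE
  mask
}

#' Disease-stage classification from GENFI-CDR
#'
#' Carriers are mapped by their global GENFI-CDR score: 0 -> `CDR0`,
#' 0.5 -> `CDR0.5`, and 1/2/3 pooled into `CDR1plus`. All non-carriers are
#' pooled into one control group regardless of their CDR rating. A missing
#' CDR in a carrier yields `missing`.
#'
#' @param carrier Logical (vector) carrier status.
#' @param genfi_cdr Numeric global GENFI-CDR score(s) in {0, 0.5, 1, 2, 3};
#'   NA allowed.
#' @return Character vector of stage labels in
#'   `{CDR0, CDR0.5, CDR1plus, non-carrier, missing}`.
#' @export
classify_stage <- function(carrier, genfi_cdr) {
  stopifnot(length(carrier) == length(genfi_cdr))
  out <- rep("missing", length(carrier))
  out[!carrier] <- "non-carrier"
  out[carrier & !is.na(genfi_cdr) & genfi_cdr == 0] <- "CDR0"
  out[carrier & !is.na(genfi_cdr) & genfi_cdr == 0.5] <- "CDR0.5"
  out[carrier & !is.na(genfi_cdr) & genfi_cdr >= 1] <- "CDR1plus"
  out
}

#' Truncate longitudinal follow-up
#'
#' Keeps the baseline visit plus follow-ups at or before `max_years`; subjects
#' left with fewer than two visits are dropped. Used for the short-follow-up
#' sensitivity analysis (predictive ability over trial-length horizons of
#' about one year).
#'
#' @param visits Visit data frame with `subject_id` and `time_from_baseline`.
#' @param max_years Positive truncation horizon in years.
#' @return The truncated visit table, with attributes `n_dropped` (subjects
#'   removed) and `mean_followup` (mean of each retained subject's last visit
#'   time).
#' @export
truncate_followup <- function(visits, max_years) {
  if (max_years <= 0) stop("max_years must be > 0")
  keep <- visits$time_from_baseline == 0 |
          visits$time_from_baseline <= max_years
  v <- visits[keep, , drop = FALSE]
  counts <- table(v$subject_id)
  retained <- names(counts)[counts >= 2]
  dropped <- length(unique(visits$subject_id)) - length(retained)
  if (dropped > 0)
    message(dropped, " subject(s) dropped by follow-up truncation at ",
            max_years, " years")
  v <- v[v$subject_id %in% retained, , drop = FALSE]
  last <- tapply(v$time_from_baseline, v$subject_id, max)
  structure(v, n_dropped = dropped,
            mean_followup = if (length(last)) mean(last) else NA_real_)
}
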