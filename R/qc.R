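# Measurement-quality utilities: triplicate skinfold acceptance, technical
# error of measurement, repeatability CV, and ISCD least significant change.

#' Triplicate skinfold acceptance
#'
#' A skinfold site is measured three times; the value used downstream is the
#' arithmetic mean of the triplicate, accepted only when no measurement
#' deviates from the anchor by more than `tolerance` (default 10%) of the
#' anchor. The anchor is the triplicate median by default (configurable to
#' the mean). Rejected triplicates get a remeasure flag instead of a value.
#'
#' @param values Exactly three positive measurements, same units.
#' @param tolerance Relative tolerance, default 0.10.
#' @param anchor `"median"` (default) or `"mean"`.
#' @return List with `accepted` (logical), `mean` (the triplicate mean, or
#'   `NA` when rejected), and `max_deviation`.
#' @export
#' @examples
#' triplicate_mean_with_tolerance(c(10.0, 10.5, 9.8))   # accepted, mean 10.1
#' triplicate_mean_with_tolerance(c(10.0, 12.0, 10.1))  # remeasure
triplicate_mean_with_tolerance <- function(values, tolerance = 0.10,
                                           anchor = c("median", "mean")) {
  anchor <- match.arg(anchor)
  if (length(values) != 3)
    .stop_typed("dxacv_invalid_replicates", "exactly three measurements required")
  if (any(values <= 0) || any(is.na(values)))
    .stop_typed("dxacv_invalid_replicates", "measurements must be positive")
  ref <- if (anchor == "median") stats::median(values) else mean(values)
  dev <- max(abs(values - ref))
  ok <- dev <= tolerance * ref
  list(accepted = ok, mean = if (ok) mean(values) else NA_real_,
       max_deviation = dev)
}

#' Technical error of measurement (TEM)
#'
#' Dahlberg's repeatability statistic for duplicate measurements:
#' `TEM = sqrt(sum(d^2) / (2 n))` over the n pair differences d, in the
#' measurement units, and `%TEM = 100 * TEM / grand mean`. Intra- vs
#' inter-rater TEM differ only in which pairs are supplied (two sessions of
#' one rater, or one session each of two raters).
#'
#' @param first,second Paired measurements, equal length n >= 2.
#' @return List with `tem` (units), `pct_tem` (% of grand mean), `n`.
#' @export
#' @examples
#' tem(c(10, 12, 9), c(11, 12, 10))
tem <- function(first, second) {
  if (length(first) != length(second))
    .stop_typed("dxacv_invalid_replicates", "pair vectors differ in length")
  if (length(first) < 2)
    .stop_typed("dxacv_invalid_replicates", "TEM needs at least 2 pairs")
  d <- first - second
  out <- sqrt(sum(d^2) / (2 * length(d)))
  list(tem = out, pct_tem = 100 * out / mean(c(first, second)),
       n = length(d))
}

#' Repeatability coefficient of variation
#'
#' Per-subject CV of repeated measurements, `CV_i = 100 * SD_i / mean_i`
#' (sample SD), and the (min, max, mean) summary across subjects.
#'
#' @param replicates A list of numeric vectors, one per subject, each with
#'   at least 2 replicates and positive mean.
#' @return List with `cv` (per-subject, %), and `summary` (`min`, `max`,
#'   `mean`).
#' @export
#' @examples
#' repeatability_cv(list(c(32.0, 32.4), c(28.1, 28.1)))
repeatability_cv <- function(replicates) {
  cv <- vapply(replicates, function(x) {
    if (length(x) < 2)
      .stop_typed("dxacv_invalid_replicates",
                  "each subject needs >= 2 replicates")
    mu <- mean(x)
    if (mu == 0)
      .stop_typed("dxacv_invalid_replicates", "zero-mean replicates")
    100 * stats::sd(x) / mu
  }, numeric(1))
  list(cv = cv,
       summary = c(min = min(cv), max = max(cv), mean = mean(cv)))
}

#' Least significant change (ISCD precision convention)
#'
#' From a precision study of m subjects scanned k >= 2 times each: the RMS
#' precision SD is `sqrt(mean(SD_i^2))` with per-subject sample SDs (k - 1
#' df), and the least significant change is `multiplier * rms_sd` with the
#' 95% two-sided multiplier 2.77. A measured change smaller than the LSC is
#' indistinguishable from instrument noise.
#'
#' @param replicates A list of numeric vectors, one per subject (>= 2
#'   replicates each).
#' @param multiplier LSC multiplier, default 2.77.
#' @return List with `rms_sd`, `lsc`, `n_subjects`.
#' @export
#' @examples
#' least_significant_change(replicate(15, rnorm(3, 32, 0.3), simplify = FALSE))
least_significant_change <- function(replicates, multiplier = 2.77) {
  sds <- vapply(replicates, function(x) {
    if (length(x) < 2)
      .stop_typed("dxacv_invalid_replicates",
                  "each subject needs >= 2 replicates")
    stats::sd(x)
  }, numeric(1))
  rms <- sqrt(mean(sds^2))
  list(rms_sd = rms, lsc = multiplier * rms, n_subjects = length(sds))
}
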