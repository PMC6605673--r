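#' dxacv: cross-validation of body composition prediction equations against DXA
#'
#' Tools to evaluate published anthropometry (skinfold) and bioelectrical
#' impedance (BIA) prediction equations for body fat (BF) and fat-free mass
#' (FFM) against dual-energy X-ray absorptiometry (DXA) as a reference method,
#' using the Bland-Altman agreement framework with a staged validity verdict.
#'
#' The package has five parts: an equation registry and evaluation engine
#' ([equation_registry()], [evaluate_equation()]), the agreement statistics
#' chain ([validity_verdict()]), a pipeline that orchestrates the full
#' cross-validation over a cohort ([run_crossvalidation()]), a synthetic
#' cohort generator with controllable bias structure ([generate_cohort()],
#' [inject_bias()]), and measurement-quality utilities ([tem()],
#' [least_significant_change()]).
#'
#' @keywords internal
"_PACKAGE"

# Symbols used inside equation formulas -> cohort column names.
# H is special-cased: height is stored in meters and converted to the
# unit each equation's source publication used.
.symbol_columns <- c(
  W   = "weight_kg",
  H   = "height_m",
  A   = "age_years",
  sex = "sex",
  TR  = "sf_triceps_mm",
  BC  = "sf_biceps_mm",
  SE  = "sf_subscapular_mm",
  SI  = "sf_suprailiac_mm",
  TH  = "sf_thigh_mm",
  AX  = "sf_midaxillary_mm",
  CA  = "sf_calf_mm",
  AB  = "sf_abdominal_mm",
  R   = "resistance_ohm",
  Xc  = "reactance_ohm"
)

.dxa_columns <- c("dxa_bf_pct", "dxa_bf_kg", "dxa_ffm_pct", "dxa_ffm_kg")

#' Cohort column dictionary
#'
#' Column names of the per-subject cohort table used throughout the package.
#' All measurements are SI: weight in kg, height in meters, skinfolds in mm,
#' resistance and reactance in ohms, DXA compartments in percent of body mass
#' and in kg. `sex` is coded `"female"` or `"male"`. Missing values are `NA`
#' (empty cells in CSV).
#'
#' @return Named character vector mapping column names to short descriptions.
#' @export
#' @examples
#' cohort_columns()
cohort_columns <- function() {
  c(subject_id        = "opaque subject identifier",
    age_years         = "age in completed years",
    sex               = "female | male",
    weight_kg         = "body mass, kg",
    height_m          = "stature, m",
    sf_triceps_mm     = "triceps skinfold (TR), mm",
    sf_biceps_mm      = "biceps skinfold (BC), mm",
    sf_subscapular_mm = "subscapular skinfold (SE), mm",
    sf_suprailiac_mm  = "suprailiac skinfold (SI), mm",
    sf_thigh_mm       = "thigh skinfold (TH), mm",
    sf_midaxillary_mm = "mid-axillary skinfold (AX), mm",
    sf_calf_mm        = "medial calf skinfold (CA), mm",
    sf_abdominal_mm   = "abdominal skinfold (AB), mm",
    resistance_ohm    = "BIA resistance (R), ohm",
    reactance_ohm     = "BIA reactance (Xc), ohm",
    dxa_bf_pct        = "DXA body fat, % of body mass",
    dxa_bf_kg         = "DXA body fat, kg",
    dxa_ffm_pct       = "DXA fat-free mass, % of body mass",
    dxa_ffm_kg        = "DXA fat-free mass, kg")
}

.stop_typed <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "dxacv_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a cohort table
#'
#' Checks the per-subject invariants: positive weight, height in (0.5, 2.5) m,
#' positive skinfolds where present, resistance > 0, reactance >= 0, and
#' DXA body fat percentage in \[0, 100\]. When all four DXA fields are present,
#' the mass bookkeeping `dxa_bf_kg + dxa_ffm_kg` is allowed to deviate from
#' `weight` by at most `bone_slack_kg` (DXA fat-free mass may or may not fold
#' in bone mineral content, depending on vendor reporting).
#'
#' @param cohort A data frame with columns from [cohort_columns()].
#' @param bone_slack_kg Tolerated absolute gap, in kg, between weight and the
#'   sum of the DXA compartments. Default 3 kg.
#' @return The cohort, invisibly, if valid; otherwise an error of class
#'   `dxacv_invalid_cohort`.
#' @export
validate_cohort <- function(cohort, bone_slack_kg = 3) {
  need <- c("subject_id", "age_years", "sex", "weight_kg", "height_m")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    .stop_typed("dxacv_invalid_cohort",
                paste0("cohort is missing required columns: ",
                       paste(miss, collapse = ", ")))
  if (nrow(cohort) == 0)
    .stop_typed("dxacv_invalid_cohort", "cohort has no rows")
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      .stop_typed("dxacv_invalid_cohort",
                  paste0(what, " (rows ",
                         paste(utils::head(which(cond), 5), collapse = ", "),
                         ")"))
  }
  bad(cohort$weight_kg <= 0, "non-positive weight")
  bad(cohort$height_m <= 0.5 | cohort$height_m >= 2.5,
      "height outside (0.5, 2.5) m")
  bad(!(cohort$sex %in% c("female", "male")) & !is.na(cohort$sex),
      "sex must be coded 'female' or 'male'")
  for (col in grep("^sf_", names(cohort), value = TRUE))
    bad(cohort[[col]] <= 0, paste0("non-positive skinfold in ", col))
  if ("resistance_ohm" %in% names(cohort))
    bad(cohort$resistance_ohm <= 0, "non-positive resistance")
  if ("reactance_ohm" %in% names(cohort))
    bad(cohort$reactance_ohm < 0, "negative reactance")
  if ("dxa_bf_pct" %in% names(cohort))
    bad(cohort$dxa_bf_pct < 0 | cohort$dxa_bf_pct > 100,
        "DXA BF% outside [0, 100]")
  if (all(.dxa_columns %in% names(cohort))) {
    gap <- abs(cohort$dxa_bf_kg + cohort$dxa_ffm_kg - cohort$weight_kg)
    bad(gap > bone_slack_kg,
        paste0("DXA compartments deviate from weight by more than ",
               bone_slack_kg, " kg"))
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a UTF-8 CSV with a header row following the [cohort_columns()]
#' dictionary; empty cells become `NA`. The table is validated with
#' [validate_cohort()] before it is returned.
#'
#' @param path Path to the CSV file.
#' @param ... Passed to [validate_cohort()].
#' @return A tibble, one row per subject.
#' @export
read_cohort <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  df$subject_id <- as.character(df$subject_id)
  num <- setdiff(intersect(names(df), names(cohort_columns())),
                 c("subject_id", "sex"))
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  cohort <- tibble::as_tibble(df)
  validate_cohort(cohort, ...)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort Cohort table.
#' @param path Output path; missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize a cohort
#'
#' Computes, for every numeric cohort variable plus BMI (weight/height^2,
#' kg/m^2), both the mean (SD) and the median (Q1-Q3). Which presentation a
#' report uses is the caller's choice; this function always returns both.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param cohort Cohort table (non-empty).
#' @return A tibble with columns `variable`, `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, and `degenerate` (`TRUE` when fewer than 2 non-missing values,
#'   in which case `sd` is reported as 0-variance, i.e. `NA`).
#' @export
#' @examples
#' cohort <- generate_cohort(scenario_config(n = 25, seed = 7))
#' summarize_cohort(cohort)
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0)
    .stop_typed("dxacv_invalid_cohort", "cannot summarize an empty cohort")
  vars <- setdiff(intersect(names(cohort_columns()), names(cohort)),
                  c("subject_id", "sex"))
  work <- cohort[vars]
  work$bmi_kg_m2 <- cohort$weight_kg / cohort$height_m^2
  rows <- lapply(names(work), function(v) {
    x <- work[[v]]
    x <- x[!is.na(x)]
    n <- length(x)
    q <- if (n > 0) stats::quantile(x, c(.25, .5, .75), names = FALSE, type = 7)
         else rep(NA_real_, 3)
    tibble::tibble(variable = v, n = n,
                   mean = if (n > 0) mean(x) else NA_real_,
                   sd = if (n > 1) stats::sd(x) else NA_real_,
                   median = q[2], q1 = q[1], q3 = q[3],
                   degenerate = n < 2)
  })
  do.call(rbind, rows)
}
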