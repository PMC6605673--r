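# Eligibility, evaluation and scale standardization for registry equations.

# Build the symbol frame an evaluator consumes, converting height to the
# unit the source publication used.
.equation_inputs <- function(cohort, spec) {
  get_col <- function(col) {
    if (col %in% names(cohort)) cohort[[col]] else rep(NA_real_, nrow(cohort))
  }
  h <- get_col("height_m")
  if (identical(spec$height_unit, "cm")) h <- h * 100
  sex_chr <- if ("sex" %in% names(cohort)) cohort$sex else rep(NA_character_, nrow(cohort))
  data.frame(
    W = get_col("weight_kg"), H = h, A = get_col("age_years"),
    TR = get_col("sf_triceps_mm"), BC = get_col("sf_biceps_mm"),
    SE = get_col("sf_subscapular_mm"), SI = get_col("sf_suprailiac_mm"),
    TH = get_col("sf_thigh_mm"), AX = get_col("sf_midaxillary_mm"),
    CA = get_col("sf_calf_mm"), AB = get_col("sf_abdominal_mm"),
    R = get_col("resistance_ohm"), Xc = get_col("reactance_ohm"),
    sex = ifelse(sex_chr == "male", 1, 0)
  )
}

#' Eligibility of subjects for an equation
#'
#' A subject is eligible for an equation when their age (completed years) lies
#' inside the equation's closed development age range and every required input
#' is present (non-missing). Each equation is applied only to subjects within
#' the age range its source publication proposed.
#'
#' @param cohort Cohort table (one or more rows).
#' @param spec An `equation_spec` from [equation_registry()].
#' @return Logical vector, one element per subject.
#' @export
#' @examples
#' reg <- equation_registry()
#' cohort <- generate_cohort(scenario_config(n = 10, seed = 1))
#' is_eligible(cohort, reg$durnin_womersley_1974)
is_eligible <- function(cohort, spec) {
  if (!("age_years" %in% names(cohort)) || any(is.na(cohort$age_years)))
    .stop_typed("dxacv_unusable_record",
                "missing age: record unusable for eligibility")
  inputs <- .equation_inputs(cohort, spec)
  ok <- rep(TRUE, nrow(cohort))
  if (!is.na(spec$age_min))
    ok <- ok & cohort$age_years >= spec$age_min & cohort$age_years <= spec$age_max
  for (sym in spec$required_inputs)
    ok <- ok & !is.na(inputs[[sym]])
  ok
}

#' Evaluate an equation's closed form
#'
#' Evaluates the registered closed form for the eligible subjects, with
#' height converted internally to the unit the equation uses. The raw result
#' is on the spec's `output_kind` scale: body density (g/ml), BF (%), or
#' FFM (kg). No rounding is applied.
#'
#' @inheritParams is_eligible
#' @param check_eligibility Error if any subject is ineligible (default).
#' @return Numeric vector of raw predictions, one per subject row.
#' @export
#' @examples
#' reg <- equation_registry()
#' s <- tibble::tibble(subject_id = "a", age_years = 20, sex = "female",
#'   weight_kg = 51.44, height_m = 1.60, sf_triceps_mm = 15, sf_biceps_mm = 9.4,
#'   sf_subscapular_mm = 11.72, sf_suprailiac_mm = 15)
#' evaluate_equation(s, reg$durnin_womersley_1974)
evaluate_equation <- function(cohort, spec, check_eligibility = TRUE) {
  if (spec$external_only)
    .stop_typed("dxacv_external_equation",
                paste0(spec$equation_id, " has no printed formula; ",
                       "supply predictions via external_pred"))
  if (check_eligibility && !all(is_eligible(cohort, spec)))
    .stop_typed("dxacv_ineligible",
                paste0("cohort contains subjects ineligible for ",
                       spec$equation_id))
  spec$evaluator(.equation_inputs(cohort, spec))
}

#' Siri two-compartment conversion from body density to percent body fat
#'
#' `BF% = 495 / BD - 450`, with body density in g/ml. The fixed point is
#' BD = 1.1 g/ml, which maps to 0% fat.
#'
#' @param bd Body density, g/ml; must be positive.
#' @return Percent body fat.
#' @export
#' @examples
#' siri_bd_to_bf_pct(1.1)   # 0
#' siri_bd_to_bf_pct(0.99)  # 50
siri_bd_to_bf_pct <- function(bd) {
  if (any(bd <= 0, na.rm = TRUE))
    .stop_typed("dxacv_domain_error", "body density must be positive")
  495 / bd - 450
}

#' Body fat mass from fat-free mass
#'
#' `BF kg = weight - FFM kg`. Predictions outside physiology (FFM negative or
#' exceeding weight) are returned, not dropped: the result carries an
#' `implausible` attribute flagging such elements so they remain reportable.
#'
#' @param weight_kg Body mass, kg.
#' @param ffm_kg Fat-free mass, kg.
#' @return Numeric vector of fat mass in kg with logical attribute
#'   `implausible`.
#' @export
#' @examples
#' bf_kg_from_ffm(50, 39.5)  # 10.5
bf_kg_from_ffm <- function(weight_kg, ffm_kg) {
  out <- weight_kg - ffm_kg
  attr(out, "implausible") <- (ffm_kg > weight_kg) | (ffm_kg < 0)
  out
}

#' Scale on which an equation is compared to DXA
#'
#' Anthropometry equations are compared on BF% and BIA equations on FFM%,
#' mirroring how the two families are reported.
#'
#' @param spec An `equation_spec`.
#' @return `"bf_percent"` or `"ffm_percent"`.
#' @export
prediction_scale <- function(spec) {
  if (spec$modality == "anthropometry") "bf_percent" else "ffm_percent"
}

#' Standardize a raw prediction onto the comparison scale
#'
#' Anthropometry predictions are brought to BF%: body density via the Siri
#' conversion, FFM (kg) via `100 * (W - FFM) / W` (the fat mass left after
#' subtracting predicted FFM from body mass), BF% unchanged. BIA predictions
#' are brought to FFM% via `100 * FFM / W`.
#'
#' @param spec An `equation_spec`.
#' @param raw Raw predictions from [evaluate_equation()].
#' @param cohort The cohort rows the predictions belong to (weight is needed
#'   for the kg-to-percent conversions).
#' @return Numeric vector on the [prediction_scale()] of the spec.
#' @export
standardize_prediction <- function(spec, raw, cohort) {
  w <- cohort$weight_kg
  if (spec$modality == "anthropometry") {
    switch(spec$output_kind,
      body_density = siri_bd_to_bf_pct(raw),
      bf_percent   = raw,
      ffm_kg       = 100 * as.numeric(bf_kg_from_ffm(w, raw)) / w,
      .stop_typed("dxacv_registry_error",
                  paste0("unknown output_kind ", spec$output_kind)))
  } else {
    100 * raw / w
  }
}

#' Predict on the comparison scale for the eligible subset
#'
#' Applies eligibility, evaluates the equation on the eligible subjects and
#' standardizes to the comparison scale (BF% for anthropometry, FFM% for BIA).
#'
#' @inheritParams is_eligible
#' @return A `prediction_series`: list with `equation_id`, `scale`, `values`,
#'   `eligible_ids`, and `n`.
#' @export
predict_equation <- function(cohort, spec) {
  elig <- is_eligible(cohort, spec)
  sub <- cohort[elig, , drop = FALSE]
  values <- if (nrow(sub) > 0)
    standardize_prediction(spec, evaluate_equation(sub, spec), sub)
  else numeric(0)
  structure(
    list(equation_id = spec$equation_id,
         scale = prediction_scale(spec),
         values = values,
         eligible_ids = sub$subject_id,
         n = nrow(sub)),
    class = "prediction_series")
}

#' @export
print.prediction_series <- function(x, ...) {
  cat(sprintf("<prediction_series> %s on %s, n = %d\n",
              x$equation_id, x$scale, x$n))
  if (x$n > 0)
    cat(sprintf("  mean %.2f, sd %.2f\n", mean(x$values),
                if (x$n > 1) stats::sd(x$values) else 0))
  invisible(x)
}
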