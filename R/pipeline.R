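# Orchestration: cohort -> per-equation eligibility, prediction,
# agreement chain, report tables and plot data.

#' Run configuration
#'
#' Bundles the tunable analysis settings: significance level, limit-of-
#' agreement multiplier, box-plot outlier multiplier and quantile algorithm,
#' and report rounding.
#'
#' @param alpha Significance level for all three stages, default 0.05.
#' @param loa_multiplier Limits-of-agreement multiplier, default 1.96.
#' @param outlier_k Box-length multiplier for extreme outliers, default 3.
#' @param quartile_type Quantile algorithm for the outlier rule, default 7
#'   (linear interpolation between order statistics).
#' @param digits_mean,digits_r Rounding used by [report_table()] for
#'   means/SDs (2) and correlations (3).
#' @param p_floor p-values below this are printed as `"<floor"` in formatted
#'   reports, default 0.0005.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, loa_multiplier = 1.96, outlier_k = 3,
                       quartile_type = 7, digits_mean = 2, digits_r = 3,
                       p_floor = 0.0005) {
  structure(list(alpha = alpha, loa_multiplier = loa_multiplier,
                 outlier_k = outlier_k, quartile_type = quartile_type,
                 digits_mean = digits_mean, digits_r = digits_r,
                 p_floor = p_floor),
            class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (comments with `#`) overriding
#' [run_config()] defaults. Recognized keys: `alpha`, `loa_multiplier`,
#' `outlier_k`, `quartile_type`, `digits_mean`, `digits_r`, `p_floor`.
#'
#' @param path Path to the configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- run_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      .stop_typed("dxacv_config_error", paste0("cannot parse line: ", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg))
      .stop_typed("dxacv_config_error", paste0("unknown config key: ", key))
    cfg[[key]] <- as.numeric(val)
  }
  cfg
}

# DXA reference column for a comparison scale.
.reference_column <- function(scale)
  switch(scale, bf_percent = "dxa_bf_pct", ffm_percent = "dxa_ffm_pct",
         .stop_typed("dxacv_config_error", paste0("unknown scale ", scale)))

#' Difference series of one equation against DXA
#'
#' Predicts on the equation's eligible subset, standardizes to the comparison
#' scale and pairs the predictions with the matching DXA reference column
#' (`dxa_bf_pct` for anthropometry, `dxa_ffm_pct` for BIA). Subjects missing
#' the reference value are excluded listwise for this equation only.
#'
#' @inheritParams is_eligible
#' @param external_values Optional numeric vector (one per cohort row) of
#'   user-supplied predictions on the comparison scale, required for
#'   `external_only` specs.
#' @return A `difference_series`, possibly with `n = 0`.
#' @export
equation_series <- function(cohort, spec, external_values = NULL) {
  scale <- prediction_scale(spec)
  ref_col <- .reference_column(scale)
  if (!ref_col %in% names(cohort))
    .stop_typed("dxacv_config_error",
                paste0("cohort lacks reference column ", ref_col))
  if (spec$external_only) {
    if (is.null(external_values))
      .stop_typed("dxacv_external_equation",
                  paste0(spec$equation_id,
                         " requires a user-supplied prediction column"))
    return(difference_series(external_values, cohort[[ref_col]],
                             equation_id = spec$equation_id, scale = scale,
                             subject_ids = cohort$subject_id))
  }
  pred <- predict_equation(cohort, spec)
  sub <- cohort[match(pred$eligible_ids, cohort$subject_id), , drop = FALSE]
  difference_series(pred$values, sub[[ref_col]],
                    equation_id = spec$equation_id, scale = scale,
                    subject_ids = pred$eligible_ids)
}

#' Cross-validate every registry equation against DXA
#'
#' For each evaluable equation: restrict the cohort to the equation's
#' eligible subset (age range plus required inputs, listwise per equation),
#' predict, standardize to the comparison scale, pair with the matching DXA
#' reference, and run the staged validity chain. Equations whose eligible
#' subset is too small (n < 3) are reported with verdict `not_evaluable`
#' rather than dropped; external-only equations are included only when a
#' prediction column is supplied.
#'
#' @param cohort Cohort table with the DXA reference columns.
#' @param registry An `equation_registry`, default [equation_registry()].
#' @param config A [run_config()].
#' @param external_pred Named character vector mapping `equation_id` to a
#'   cohort column holding user-supplied predictions on the comparison scale,
#'   e.g. `c(rjl_manufacturer = "rjl_ffm_pct")`.
#' @return A `dxacv_run`: `results` (one tibble row per equation with raw
#'   precision statistics), `series` and `verdicts` (named lists), `config`,
#'   and `n_cohort`.
#' @export
#' @examples
#' cohort <- generate_cohort(scenario_config(n = 40, seed = 2))
#' run <- run_crossvalidation(cohort)
#' run$results[, c("equation_id", "n", "r", "verdict")]
run_crossvalidation <- function(cohort, registry = equation_registry(),
                                config = run_config(), external_pred = NULL) {
  validate_cohort(cohort)
  series <- list(); verdicts <- list(); rows <- list()
  for (spec in registry) {
    id <- spec$equation_id
    ext <- NULL
    if (spec$external_only) {
      if (is.null(external_pred) || !id %in% names(external_pred)) next
      col <- external_pred[[id]]
      if (!col %in% names(cohort))
        .stop_typed("dxacv_config_error",
                    paste0("external prediction column ", col, " not found"))
      ext <- cohort[[col]]
    }
    ds <- equation_series(cohort, spec, external_values = ext)
    series[[id]] <- ds
    verdict <- if (ds$n >= 3) validity_verdict(ds, alpha = config$alpha,
                                               loa_multiplier = config$loa_multiplier)
               else NULL
    verdicts[[id]] <- verdict
    ba <- if (ds$n >= 2) bland_altman(ds, multiplier = config$loa_multiplier)
          else NULL
    reg <- if (!is.null(verdict) && !is.null(verdict$stage3))
             verdict$stage3$regression else NULL
    rows[[id]] <- tibble::tibble(
      equation_id = id,
      citation = spec$citation_label,
      modality = spec$modality,
      scale = ds$scale,
      n = ds$n,
      eq_mean = if (ds$n > 0) mean(ds$equation) else NA_real_,
      eq_sd = if (ds$n > 1) stats::sd(ds$equation) else NA_real_,
      dxa_mean = if (ds$n > 0) mean(ds$dxa) else NA_real_,
      dxa_sd = if (ds$n > 1) stats::sd(ds$dxa) else NA_real_,
      r = if (!is.null(verdict) && !is.null(verdict$stage1))
            verdict$stage1$r else NA_real_,
      r_p = if (!is.null(verdict) && !is.null(verdict$stage1))
              verdict$stage1$p else NA_real_,
      t = if (!is.null(verdict) && !is.null(verdict$stage2))
            verdict$stage2$t else NA_real_,
      t_p = if (!is.null(verdict) && !is.null(verdict$stage2))
              verdict$stage2$p else NA_real_,
      mean_diff = if (!is.null(ba)) ba$mean_diff else NA_real_,
      sd_diff = if (!is.null(ba)) ba$sd_diff else NA_real_,
      loa_low = if (!is.null(ba)) ba$loa_low else NA_real_,
      loa_high = if (!is.null(ba)) ba$loa_high else NA_real_,
      beta = if (!is.null(reg)) reg$beta else NA_real_,
      adj_r2 = if (!is.null(reg)) reg$adj_r2 else NA_real_,
      see = if (!is.null(reg)) reg$see else NA_real_,
      reg_p = if (!is.null(reg)) reg$p_value else NA_real_,
      verdict = if (is.null(verdict)) "not_evaluable" else verdict$verdict
    )
  }
  structure(list(results = do.call(rbind, rows), series = series,
                 verdicts = verdicts, config = config,
                 n_cohort = nrow(cohort)),
            class = "dxacv_run")
}

#' @export
print.dxacv_run <- function(x, ...) {
  cat(sprintf("<dxacv_run> %d equations over %d subjects\n",
              nrow(x$results), x$n_cohort))
  print(x$results[, c("equation_id", "modality", "n", "r", "r_p", "t_p",
                      "verdict")])
  invisible(x)
}

.format_p <- function(p, floor = 0.0005) {
  ifelse(is.na(p), "", ifelse(p < floor, paste0("<", format(floor)),
                              formatC(p, digits = 3, format = "f")))
}

#' Formatted report table
#'
#' Renders the machine-precision results in the style of the published
#' comparison tables: one row per equation with n, equation mean (SD), DXA
#' mean (SD) on the comparison scale, r, and the correlation p-value printed
#' as `<0.0005` below the floor. Raw precision stays available in
#' `run$results`.
#'
#' @param run A `dxacv_run`.
#' @return A tibble of formatted character columns plus the verdict.
#' @export
report_table <- function(run) {
  cfg <- run$config
  res <- run$results
  msd <- function(m, s)
    ifelse(is.na(m), "",
           paste0(formatC(m, digits = cfg$digits_mean, format = "f"), " (",
                  formatC(s, digits = cfg$digits_mean, format = "f"), ")"))
  tibble::tibble(
    equation = res$citation,
    scale = ifelse(res$scale == "bf_percent", "BF (%)", "FFM (%)"),
    n = res$n,
    equation_mean_sd = msd(res$eq_mean, res$eq_sd),
    dxa_mean_sd = msd(res$dxa_mean, res$dxa_sd),
    r = ifelse(is.na(res$r), "",
               formatC(res$r, digits = cfg$digits_r, format = "f")),
    p = .format_p(res$r_p, cfg$p_floor),
    verdict = res$verdict)
}

#' Per-equation mean-difference plot data
#'
#' One row per evaluated equation with the mean equation-minus-DXA
#' difference on its comparison scale and the half-width of the +/- 1.96 SD
#' error bar, the structure of a mean-difference (agreement overview) figure.
#'
#' @param run A `dxacv_run`.
#' @return Tibble with `equation_id`, `scale`, `n`, `mean_diff`,
#'   `half_width`.
#' @export
difference_plot_data <- function(run) {
  res <- run$results
  tibble::tibble(equation_id = res$equation_id, scale = res$scale, n = res$n,
                 mean_diff = res$mean_diff,
                 half_width = run$config$loa_multiplier * res$sd_diff)
}

#' Bland-Altman plot data for one equation
#'
#' The (mean, difference) scatter with the bias line, limits of agreement,
#' and the proportional-bias regression line with its pointwise 95%
#' confidence band, evaluated over the observed range of means.
#'
#' @param run A `dxacv_run`.
#' @param equation_id Which equation's series to extract.
#' @return List with `points` (tibble), `mean_diff`, `loa_low`, `loa_high`,
#'   and `regression` (tibble of `mean`, `fit`, `lwr`, `upr`, or `NULL` when
#'   the regression stage was not reached).
#' @export
bland_altman_plot_data <- function(run, equation_id) {
  ds <- run$series[[equation_id]]
  if (is.null(ds) || ds$n < 2)
    .stop_typed("dxacv_insufficient_data",
                paste0("no plottable series for ", equation_id))
  ba <- bland_altman(ds, multiplier = run$config$loa_multiplier)
  verdict <- run$verdicts[[equation_id]]
  reg_band <- NULL
  if (!is.null(verdict) && !is.null(verdict$stage3) &&
      !verdict$stage3$regression$degenerate) {
    fit <- verdict$stage3$regression$fit
    grid <- data.frame(m = seq(min(ds$m), max(ds$m), length.out = 50))
    ci <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = 0.95)
    reg_band <- tibble::tibble(mean = grid$m, fit = ci[, "fit"],
                               lwr = ci[, "lwr"], upr = ci[, "upr"])
  }
  list(points = ba$points, mean_diff = ba$mean_diff,
       loa_low = ba$loa_low, loa_high = ba$loa_high, regression = reg_band)
}

#' Export a cross-validation run to CSV files
#'
#' Writes `report.csv` (raw-precision per-equation statistics),
#' `verdicts.csv`, one `bland_altman/<equation_id>.csv` of (mean,
#' difference) pairs per evaluated equation, and `run.log` (configuration
#' echo and per-equation eligibility counts).
#'
#' @param run A `dxacv_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(run$results), file.path(dir, "report.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(
    data.frame(equation_id = run$results$equation_id,
               n = run$results$n, verdict = run$results$verdict),
    file.path(dir, "verdicts.csv"), row.names = FALSE)
  badir <- file.path(dir, "bland_altman")
  dir.create(badir, showWarnings = FALSE)
  for (id in names(run$series)) {
    ds <- run$series[[id]]
    if (ds$n < 2) next
    ba <- bland_altman(ds, multiplier = run$config$loa_multiplier)
    pts <- ba$points
    pts$loa_low <- ba$loa_low; pts$loa_high <- ba$loa_high
    pts$mean_diff <- ba$mean_diff
    utils::write.csv(as.data.frame(pts),
                     file.path(badir, paste0(id, ".csv")), row.names = FALSE)
  }
  cfg <- run$config
  log_lines <- c(
    sprintf("dxacv run over %d subjects", run$n_cohort),
    sprintf("alpha = %g, loa_multiplier = %g, outlier_k = %g, quartile_type = %g",
            cfg$alpha, cfg$loa_multiplier, cfg$outlier_k, cfg$quartile_type),
    sprintf("%-24s eligible n = %3d  excluded = %3d  verdict = %s",
            run$results$equation_id, run$results$n,
            run$n_cohort - run$results$n, run$results$verdict))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
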