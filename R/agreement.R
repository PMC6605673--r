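# Agreement statistics: Pearson screen, one-sample t, Bland-Altman,
# proportional-bias regression, outlier flags and the staged verdict.

#' Paired equation/reference series for agreement analysis
#'
#' Bundles the per-subject (equation, DXA) pairs on a common scale with the
#' derived differences `d = equation - DXA` and means `m = (equation + DXA)/2`
#' that the Bland-Altman analysis works on.
#'
#' @param equation Numeric vector of equation predictions.
#' @param dxa Numeric vector of reference values on the same scale.
#' @param equation_id Identifier carried through to reports.
#' @param scale `"bf_percent"` or `"ffm_percent"`.
#' @param subject_ids Optional subject identifiers.
#' @return A `difference_series` with fields `equation`, `dxa`, `d`, `m`,
#'   `n`, `equation_id`, `scale`, `subject_ids`.
#' @export
#' @examples
#' ds <- difference_series(c(30, 32, 28), c(29, 33, 26))
#' ds$d
difference_series <- function(equation, dxa, equation_id = "equation",
                              scale = "bf_percent", subject_ids = NULL) {
  if (length(equation) != length(dxa))
    .stop_typed("dxacv_invalid_series", "equation and dxa differ in length")
  keep <- !is.na(equation) & !is.na(dxa)
  equation <- equation[keep]; dxa <- dxa[keep]
  if (!is.null(subject_ids)) subject_ids <- subject_ids[keep]
  structure(
    list(equation_id = equation_id, scale = scale,
         equation = equation, dxa = dxa,
         d = equation - dxa, m = (equation + dxa) / 2,
         n = length(equation), subject_ids = subject_ids),
    class = "difference_series")
}

#' Pearson correlation screen
#'
#' Two-sided Pearson correlation between equation and reference values, the
#' first stage of the validity chain. The p-value comes from the t transform
#' of r with n - 2 degrees of freedom (`stats::cor.test`).
#'
#' @param pairs A `difference_series` with `n >= 3` and both series
#'   non-constant.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
pearson_screen <- function(pairs) {
  if (pairs$n < 3)
    .stop_typed("dxacv_insufficient_data", "Pearson screen needs n >= 3")
  if (stats::var(pairs$equation) == 0 || stats::var(pairs$dxa) == 0)
    .stop_typed("dxacv_degenerate_input",
                "constant series: correlation undefined")
  ct <- stats::cor.test(pairs$equation, pairs$dxa, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = pairs$n)
}

#' One-sample t-test of the mean difference against zero
#'
#' Tests whether the mean equation-minus-reference difference departs from
#' zero (two-sided). In the validity chain a *non*-significant result
#' (p > alpha) signals agreement. Degenerate zero-variance input yields
#' t = 0, p = 1 when the mean is exactly zero and p = 0 (flagged) otherwise.
#'
#' @param differences Numeric vector of differences (n >= 2), or a
#'   `difference_series`.
#' @return List with `t`, `df`, `p`, `mean`, `sd`, `degenerate`.
#' @export
#' @examples
#' one_sample_t_zero(c(1, -1, 2))
one_sample_t_zero <- function(differences) {
  d <- if (inherits(differences, "difference_series")) differences$d
       else differences
  if (length(d) < 2)
    .stop_typed("dxacv_insufficient_data", "t-test needs n >= 2")
  n <- length(d); mu <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (mu == 0) return(list(t = 0, df = n - 1, p = 1, mean = mu, sd = 0,
                             degenerate = FALSE))
    return(list(t = sign(mu) * Inf, df = n - 1, p = 0, mean = mu, sd = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mu, sd = s, degenerate = FALSE)
}

#' Bland-Altman agreement statistics
#'
#' Mean difference (bias), sample SD of the differences (n - 1 denominator)
#' and limits of agreement at mean +/- `multiplier` * SD, with the
#' conventional multiplier 1.96. Also carries the plot-ready (mean,
#' difference) pairs: the x-axis is the per-subject mean of equation and
#' reference, the y-axis their difference.
#'
#' @param pairs A `difference_series` (n >= 2).
#' @param multiplier Limit multiplier, default 1.96.
#' @return A `bland_altman` object: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `multiplier`, and `points` (tibble of mean/difference).
#' @export
#' @examples
#' bland_altman(difference_series(c(30, 32, 28), c(29, 33, 26)))
bland_altman <- function(pairs, multiplier = 1.96) {
  if (pairs$n < 2)
    .stop_typed("dxacv_insufficient_data", "Bland-Altman needs n >= 2")
  mu <- mean(pairs$d)
  s <- stats::sd(pairs$d)
  structure(
    list(mean_diff = mu, sd_diff = s,
         loa_low = mu - multiplier * s, loa_high = mu + multiplier * s,
         n = pairs$n, multiplier = multiplier,
         points = tibble::tibble(mean = pairs$m, difference = pairs$d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d\n", x$n))
  cat(sprintf("  mean difference %.3f (SD %.3f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement [%.3f, %.3f] (+/- %.2f SD)\n",
              x$loa_low, x$loa_high, x$multiplier))
  invisible(x)
}

#' Proportional-bias regression
#'
#' Ordinary least squares of the differences (dependent) on the per-subject
#' means (independent). A significant slope (p < alpha, two-sided) indicates
#' proportional bias: the disagreement grows or shrinks with the magnitude
#' of the measurement. Reports the slope (beta, whose sign gives the bias
#' direction), intercept, adjusted R^2 (which can be negative), the standard
#' error of estimate SEE = sqrt(SSE / (n - 2)), and the slope p-value.
#'
#' Constant differences (zero variance) give slope 0, p = 1, flagged
#' degenerate; constant means are a degenerate-input error.
#'
#' @param pairs A `difference_series` (n >= 3, non-constant means).
#' @return A `regression_result`: `beta`, `intercept`, `adj_r2`, `see`,
#'   `p_value`, `n`, `degenerate`, and `fit` (the `lm` object or `NULL`).
#' @export
proportional_bias_fit <- function(pairs) {
  if (pairs$n < 3)
    .stop_typed("dxacv_insufficient_data",
                "proportional-bias regression needs n >= 3")
  if (stats::var(pairs$m) == 0)
    .stop_typed("dxacv_degenerate_input",
                "constant means: regression undefined")
  if (stats::var(pairs$d) == 0) {
    return(structure(
      list(beta = 0, intercept = pairs$d[1], adj_r2 = NA_real_, see = 0,
           p_value = 1, n = pairs$n, degenerate = TRUE, fit = NULL),
      class = "regression_result"))
  }
  df <- data.frame(d = pairs$d, m = pairs$m)
  fit <- stats::lm(d ~ m, data = df)
  # exact affine inputs are legitimate here (SEE = 0 by design); muffle
  # summary.lm's perfect-fit warning for that case only
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(
    list(beta = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         adj_r2 = sm$adj.r.squared,
         see = sm$sigma,
         p_value = sm$coefficients["m", "Pr(>|t|)"],
         n = pairs$n, degenerate = FALSE, fit = fit),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d\n", x$n))
  cat(sprintf("  beta %.4f, intercept %.4f, adj R2 %.3f, SEE %.3f, p %.4g\n",
              x$beta, x$intercept, x$adj_r2, x$see, x$p_value))
  invisible(x)
}

#' Extreme-outlier flags by the box-plot rule
#'
#' Flags values lying more than `k` box lengths (interquartile ranges) beyond
#' the box edges: `value > Q3 + k * IQR` or `value < Q1 - k * IQR`, with
#' k = 3 for extreme outliers. Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7 by default).
#'
#' @param values Numeric vector, n >= 4.
#' @param k Box-length multiplier, default 3.
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Logical vector of flags.
#' @export
#' @examples
#' outlier_flags(c(10, 11, 12, 13, 14, 27))
outlier_flags <- function(values, k = 3, type = 7) {
  if (length(values) < 4)
    .stop_typed("dxacv_insufficient_data", "outlier rule needs n >= 4")
  q <- stats::quantile(values, c(.25, .75), names = FALSE, type = type,
                       na.rm = TRUE)
  iqr <- q[2] - q[1]
  values > q[2] + k * iqr | values < q[1] - k * iqr
}

#' Staged validity verdict for one equation
#'
#' Applies the three-stage chain used to cross-validate a prediction equation
#' against the reference method:
#'
#' 1. *Correlation screen* - Pearson r must be significant (p < alpha).
#' 2. *Agreement* - the one-sample t-test of the differences against zero
#'    must be non-significant (p > alpha).
#' 3. *Proportional bias* - run only when stages 1 and 2 pass; the
#'    difference-on-mean regression slope must be non-significant
#'    (p >= alpha; bias is assumed when p < alpha).
#'
#' The verdict is `valid` only when every stage reached passes; otherwise it
#' names the first failing stage. Degenerate inputs at stage 1 (constant
#' series) yield `invalid_stage1` with a degeneracy note rather than an error.
#'
#' @param pairs A `difference_series` (n >= 3).
#' @param alpha Significance level, default 0.05.
#' @param loa_multiplier Limit-of-agreement multiplier for the attached
#'   Bland-Altman statistics, default 1.96.
#' @return A `validity_verdict`: `stage1`, `stage2`, `stage3` (NULL unless
#'   reached), `bland_altman` (NULL unless stage 3 reached), `verdict`,
#'   `degenerate_note`.
#' @export
#' @examples
#' set.seed(1)
#' dxa <- rnorm(30, 28, 7)
#' eq <- dxa + rnorm(30, 0, 2)
#' validity_verdict(difference_series(eq, dxa))
validity_verdict <- function(pairs, alpha = 0.05, loa_multiplier = 1.96) {
  if (pairs$n < 3)
    .stop_typed("dxacv_insufficient_data", "verdict needs n >= 3")
  out <- list(stage1 = NULL, stage2 = NULL, stage3 = NULL,
              bland_altman = NULL, verdict = NA_character_,
              alpha = alpha, degenerate_note = NA_character_)
  class(out) <- "validity_verdict"

  s1 <- tryCatch(pearson_screen(pairs), dxacv_degenerate_input = identity)
  if (inherits(s1, "condition")) {
    out$verdict <- "invalid_stage1"
    out$degenerate_note <- conditionMessage(s1)
    return(out)
  }
  s1$pass <- s1$p < alpha
  out$stage1 <- s1
  if (!s1$pass) { out$verdict <- "invalid_stage1"; return(out) }

  s2 <- one_sample_t_zero(pairs)
  s2$pass <- s2$p > alpha
  out$stage2 <- s2
  if (s2$degenerate) out$degenerate_note <- "zero-variance differences"
  if (!s2$pass) { out$verdict <- "invalid_stage2"; return(out) }

  out$bland_altman <- bland_altman(pairs, multiplier = loa_multiplier)
  s3 <- list(regression = proportional_bias_fit(pairs))
  s3$pass <- s3$regression$p_value >= alpha
  out$stage3 <- s3
  out$verdict <- if (s3$pass) "valid" else "invalid_stage3"
  out
}

#' @export
print.validity_verdict <- function(x, ...) {
  cat(sprintf("<validity_verdict> %s (alpha = %g)\n", x$verdict, x$alpha))
  if (!is.null(x$stage1))
    cat(sprintf("  stage 1 correlation: r = %.3f, p = %.4g [%s]\n",
                x$stage1$r, x$stage1$p, if (x$stage1$pass) "pass" else "fail"))
  if (!is.null(x$stage2))
    cat(sprintf("  stage 2 agreement:   t = %.3f, df = %d, p = %.4g [%s]\n",
                x$stage2$t, x$stage2$df, x$stage2$p,
                if (x$stage2$pass) "pass" else "fail"))
  if (!is.null(x$stage3))
    cat(sprintf("  stage 3 prop. bias:  beta = %.4f, p = %.4g [%s]\n",
                x$stage3$regression$beta, x$stage3$regression$p_value,
                if (x$stage3$pass) "pass" else "fail"))
  if (!is.na(x$degenerate_note))
    cat(sprintf("  note: %s\n", x$degenerate_note))
  invisible(x)
}
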