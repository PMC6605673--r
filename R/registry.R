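# Registry of published prediction equations for female subjects.
#
# Height-unit conventions follow each source publication: the H^2/R
# (resistance-index) terms and Yannakoulia's bare-H terms take height in cm;
# Deurenberg's equations take meters (the 10^4 factor on H^2/R restores the
# cm^2 scale). Sex is coded female = 0, male = 1 where a sex term appears.

.safe_log10 <- function(x) {
  if (any(x <= 0, na.rm = TRUE))
    .stop_typed("dxacv_domain_error",
                "log10 of a non-positive skinfold sum: corrupt input")
  log10(x)
}

# Closed-form evaluators, keyed by equation_id. Each takes a data frame of
# per-subject symbols (W kg, H in the spec's unit, A years, skinfolds mm,
# R/Xc ohm, sex 0/1) and returns the raw prediction vector.
.evaluators <- list(
  durnin_womersley_1974 = function(x)
    1.1567 - 0.0717 * .safe_log10(x$TR + x$BC + x$SE + x$SI),
  jackson_pollock_1980 = function(x) {
    s <- x$TR + x$TH + x$SI
    1.0994921 - 0.0009929 * s + 0.0000023 * s^2 - 0.0001392 * x$A
  },
  guedes_1985 = function(x)
    1.1665 - 0.0706 * .safe_log10(x$TH + x$SI + x$SE),
  petroski_1995 = function(x)
    1.19547130 - 0.07513507 * .safe_log10(x$AX + x$SI + x$TH + x$CA) -
      0.00041072 * x$A,
  sloan_1962 = function(x)
    1.0764 - 0.00081 * x$SI - 0.00088 * x$TR,
  hergenroeder_1993 = function(x)
    0.73 * x$W + 3.0,
  jackson_pollock_1975 = function(x) {
    s <- x$TR + x$SI + x$TH + x$AB
    1.096095 - 0.0006952 * s + 0.0000011 * s^2 - 0.0000714 * x$A
  },
  slaughter_1988 = function(x) {
    s <- x$TR + x$SE  # sum of the two female sites; -2.5 is the female constant
    1.33 * s - 0.013 * s^2 - 2.5
  },
  chumlea_2002 = function(x)
    -9.529 + 0.168 * x$W + 0.696 * x$H^2 / x$R + 0.016 * x$R,
  segal_1988 = function(x)
    5.091 + 0.6483 * x$H^2 / x$R + 0.1699 * x$W,
  gray_1989 = function(x)
    0.00151 * x$H^2 - 0.0344 * x$R + 0.140 * x$W - 0.158 * x$A + 20.387,
  lukaski_1986 = function(x)
    0.756 * x$H^2 / x$R + 0.110 * x$W + 0.107 * x$Xc - 5.463,
  deurenberg_child_1991 = function(x)  # H in meters; 10^4 factor printed
    0.406 * (1e4 * x$H^2 / x$R) + 0.360 * x$W + 5.58 * x$H + 0.56 * x$sex - 6.48,
  deurenberg_adult_1991 = function(x)  # H in meters; bare-H term 15.34*H
    0.340 * (1e4 * x$H^2 / x$R) + 15.34 * x$H + 0.273 * x$W - 0.127 * x$A +
      4.56 * x$sex - 12.44,
  houtkooper_1992 = function(x)
    0.61 * x$H^2 / x$R + 0.25 * x$W + 1.31,
  kyle_2001 = function(x)
    -4.104 + 0.518 * x$H^2 / x$R + 0.231 * x$W + 0.130 * x$Xc + 4.229 * x$sex,
  sun_2003 = function(x)
    -9.53 + 0.69 * x$H^2 / x$R + 0.17 * x$W + 0.02 * x$R,
  yannakoulia_a_2000 = function(x)
    0.247 * x$W + 0.214 * x$H^2 / x$R + 0.191 * x$H - 14.96,
  yannakoulia_b_2000 = function(x)
    0.391 * x$W + 0.168 * x$H - 0.253 * x$TR + 0.144 * x$H^2 / x$R - 9.49
)

.registry_table <- function() {
  tibble::tribble(
    ~equation_id, ~citation_label, ~modality, ~output_kind, ~age_min, ~age_max,
      ~required_inputs, ~height_unit, ~external_only, ~formula,
    "durnin_womersley_1974", "Durnin and Womersley, 1974", "anthropometry",
      "body_density", 16, 68, "TR;BC;SE;SI", NA,
      FALSE, "BD = 1.1567 - 0.0717*log10(TR+BC+SE+SI)",
    "jackson_pollock_1980", "Jackson and Pollock, 1980", "anthropometry",
      "body_density", 18, 55, "TR;TH;SI;A", NA,
      FALSE, "BD = 1.0994921 - 0.0009929*S + 0.0000023*S^2 - 0.0001392*A; S = TR+TH+SI",
    "guedes_1985", "Guedes, 1985", "anthropometry",
      "body_density", 17, 27, "TH;SI;SE", NA,
      FALSE, "BD = 1.1665 - 0.0706*log10(TH+SI+SE)",
    "petroski_1995", "Petroski and Pires-Neto, 1995", "anthropometry",
      "body_density", 18, 51, "AX;SI;TH;CA;A", NA,
      FALSE, "BD = 1.19547130 - 0.07513507*log10(AX+SI+TH+CA) - 0.00041072*A",
    "sloan_1962", "Sloan, 1962", "anthropometry",
      "body_density", 17, 25, "SI;TR", NA,
      FALSE, "BD = 1.0764 - 0.00081*SI - 0.00088*TR",
    "hergenroeder_1993", "Hergenroeder, et al., 1993", "anthropometry",
      "ffm_kg", 11, 25, "W", NA,
      FALSE, "FFM = 0.73*W + 3.0",
    "jackson_pollock_1975", "Jackson and Pollock, 1975", "anthropometry",
      "body_density", 18, 29, "TR;SI;TH;AB;A", NA,
      FALSE, "BD = 1.096095 - 0.0006952*S + 0.0000011*S^2 - 0.0000714*A; S = TR+SI+TH+AB",
    "slaughter_1988", "Slaughter et al., 1988", "anthropometry",
      "bf_percent", 7, 18, "TR;SE", NA,
      FALSE, "BF% = 1.33*(TR+SE) - 0.013*(TR+SE)^2 - 2.5",
    "rjl_manufacturer", "Manufacturer Equation - RJL Systems", "bia",
      "ffm_kg", NA, NA, "W", NA,
      TRUE, "undisclosed; supply predictions via external_pred",
    "chumlea_2002", "Chumlea, et al., 2002", "bia",
      "ffm_kg", 12, 80, "W;H;R", "cm",
      FALSE, "FFM = -9.529 + 0.168*W + 0.696*H^2/R + 0.016*R",
    "segal_1988", "Segal, et al., 1988", "bia",
      "ffm_kg", 17, 62, "W;H;R", "cm",
      FALSE, "FFM = 5.091 + 0.6483*H^2/R + 0.1699*W",
    "gray_1989", "Gray, et al., 1989", "bia",
      "ffm_kg", 19, 74, "H;R;W;A", "cm",
      FALSE, "FFM = 0.00151*H^2 - 0.0344*R + 0.140*W - 0.158*A + 20.387",
    "lukaski_1986", "Lukaski, et al., 1986", "bia",
      "ffm_kg", 19, 50, "H;R;W;Xc", "cm",
      FALSE, "FFM = 0.756*H^2/R + 0.110*W + 0.107*Xc - 5.463",
    "deurenberg_child_1991", "Deurenberg, et al., 1991 (7-15 y)", "bia",
      "ffm_kg", 7, 15, "H;R;W;sex", "m",
      FALSE, "FFM = 0.406*(1e4*H^2/R) + 0.360*W + 5.58*H + 0.56*sex - 6.48",
    "deurenberg_adult_1991", "Deurenberg, et al., 1991 (16-83 y)", "bia",
      "ffm_kg", 16, 83, "H;R;W;A;sex", "m",
      FALSE, "FFM = 0.340*(1e4*H^2/R) + 15.34*H + 0.273*W - 0.127*A + 4.56*sex - 12.44",
    "houtkooper_1992", "Houtkooper, et al., 1992", "bia",
      "ffm_kg", 10, 19, "H;R;W", "cm",
      FALSE, "FFM = 0.61*H^2/R + 0.25*W + 1.31",
    "kyle_2001", "Kyle, et al., 2001", "bia",
      "ffm_kg", 20, 94, "H;R;W;Xc;sex", "cm",
      FALSE, "FFM = -4.104 + 0.518*H^2/R + 0.231*W + 0.130*Xc + 4.229*sex",
    "sun_2003", "Sun, et al., 2003", "bia",
      "ffm_kg", 12, 94, "H;R;W", "cm",
      FALSE, "FFM = -9.53 + 0.69*H^2/R + 0.17*W + 0.02*R",
    "yannakoulia_a_2000", "Yannakoulia, et al., 2000 (BIA only)", "bia",
      "ffm_kg", 18, 26, "W;H;R", "cm",
      FALSE, "FFM = 0.247*W + 0.214*H^2/R + 0.191*H - 14.96",
    "yannakoulia_b_2000", "Yannakoulia, et al., 2000 (BIA + triceps)", "bia",
      "ffm_kg", 18, 26, "W;H;R;TR", "cm",
      FALSE, "FFM = 0.391*W + 0.168*H - 0.253*TR + 0.144*H^2/R - 9.49"
  )
}

.row_to_spec <- function(row) {
  spec <- list(
    equation_id     = row$equation_id,
    citation_label  = row$citation_label,
    modality        = row$modality,
    output_kind     = row$output_kind,
    age_min         = row$age_min,
    age_max         = row$age_max,
    required_inputs = strsplit(row$required_inputs, ";", fixed = TRUE)[[1]],
    height_unit     = row$height_unit,
    external_only   = row$external_only,
    formula         = row$formula,
    evaluator       = if (isTRUE(row$external_only)) NULL
                      else .evaluators[[row$equation_id]]
  )
  class(spec) <- "equation_spec"
  spec
}

#' The equation registry
#'
#' Returns the registry of prediction equations for female subjects: 19
#' evaluable closed forms (8 anthropometry, 11 BIA) plus one non-evaluable
#' placeholder for the undisclosed RJL Systems manufacturer equation
#' (`external_only = TRUE`; the pipeline accepts user-supplied predictions
#' for it, see [run_crossvalidation()]).
#'
#' Each `equation_spec` carries the output kind (`body_density` in g/ml,
#' `bf_percent`, or `ffm_kg`), the closed age range in completed years within
#' which the source publication developed the equation, the required input
#' symbols, and the height unit the formula uses internally (`cm` or `m`;
#' cohort heights are always stored in meters and converted on evaluation).
#'
#' @param include_external Keep the non-evaluable placeholder specs
#'   (default `TRUE`).
#' @return A named list of `equation_spec` objects, class `equation_registry`.
#' @export
#' @examples
#' reg <- equation_registry()
#' length(reg)
#' reg$durnin_womersley_1974
equation_registry <- function(include_external = TRUE) {
  tab <- .registry_table()
  specs <- lapply(seq_len(nrow(tab)), function(i) .row_to_spec(tab[i, ]))
  names(specs) <- tab$equation_id
  if (!include_external)
    specs <- Filter(function(s) !s$external_only, specs)
  class(specs) <- "equation_registry"
  specs
}

#' List all equation specs
#'
#' Convenience accessor equivalent to [equation_registry()].
#' @inheritParams equation_registry
#' @return A named list of `equation_spec` objects.
#' @export
list_equations <- function(include_external = TRUE)
  equation_registry(include_external)

#' Write / read the registry as a flat CSV
#'
#' The registry metadata (id, citation, modality, output kind, age range,
#' required inputs, height unit, formula text) round-trips through a flat
#' CSV; evaluator closures are re-attached by `equation_id` on read. A copy
#' is shipped as `system.file("extdata", "equation_registry.csv",
#' package = "dxacv")`.
#'
#' @param path CSV path.
#' @return `write_registry` returns `path` invisibly; `read_registry` returns
#'   an `equation_registry`.
#' @export
write_registry <- function(path) {
  utils::write.csv(as.data.frame(.registry_table()), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  tab <- tibble::as_tibble(tab)
  known <- tab$equation_id %in% c(names(.evaluators), "rjl_manufacturer")
  if (!all(known))
    .stop_typed("dxacv_registry_error",
                paste0("no evaluator registered for: ",
                       paste(tab$equation_id[!known], collapse = ", ")))
  specs <- lapply(seq_len(nrow(tab)), function(i) .row_to_spec(tab[i, ]))
  names(specs) <- tab$equation_id
  class(specs) <- "equation_registry"
  specs
}

#' @export
print.equation_spec <- function(x, ...) {
  cat(sprintf("<equation_spec> %s [%s]\n", x$equation_id, x$citation_label))
  cat(sprintf("  modality: %s   output: %s   ages: %s-%s\n",
              x$modality, x$output_kind, x$age_min, x$age_max))
  cat(sprintf("  inputs: %s\n", paste(x$required_inputs, collapse = ", ")))
  if (x$external_only) cat("  external only (no printed formula)\n")
  else cat(sprintf("  %s\n", x$formula))
  invisible(x)
}

#' @export
print.equation_registry <- function(x, ...) {
  n_eval <- sum(vapply(x, function(s) !s$external_only, logical(1)))
  cat(sprintf("<equation_registry> %d specs (%d evaluable)\n",
              length(x), n_eval))
  for (s in x)
    cat(sprintf("  %-24s %-14s %s\n", s$equation_id, s$modality,
                if (s$external_only) "(external)" else s$output_kind))
  invisible(x)
}
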