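reg <- equation_registry()

one_subject <- function(age = 20, ...) {
  base <- tibble::tibble(
    subject_id = "a", age_years = age, sex = "female",
    weight_kg = 51.44, height_m = 1.60,
    sf_triceps_mm = 15.00, sf_biceps_mm = 9.40, sf_subscapular_mm = 11.72,
    sf_suprailiac_mm = 15.00, sf_thigh_mm = 25.87, sf_midaxillary_mm = 10.92,
    sf_calf_mm = 10.92, sf_abdominal_mm = 19.67,
    resistance_ohm = 672, reactance_ohm = 68)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("registry holds 19 evaluable equations plus the external placeholder", {
  expect_length(reg, 20)
  evaluable <- Filter(function(s) !s$external_only, reg)
  expect_length(evaluable, 19)
  expect_equal(sum(vapply(evaluable, function(s) s$modality == "anthropometry",
                          logical(1))), 8)
  expect_equal(sum(vapply(evaluable, function(s) s$modality == "bia",
                          logical(1))), 11)
  dw <- reg$durnin_womersley_1974
  expect_equal(dw$citation_label, "Durnin and Womersley, 1974")
  expect_equal(c(dw$age_min, dw$age_max), c(16, 68))
  expect_setequal(dw$required_inputs, c("TR", "BC", "SE", "SI"))
  expect_equal(dw$output_kind, "body_density")
  hg <- reg$hergenroeder_1993
  expect_equal(hg$output_kind, "ffm_kg")
  expect_equal(hg$required_inputs, "W")
  expect_true(reg$rjl_manufacturer$external_only)
  # Deurenberg and Yannakoulia each contribute two specs
  expect_equal(sum(grepl("^deurenberg", names(reg))), 2)
  expect_equal(sum(grepl("^yannakoulia", names(reg))), 2)
})

test_that("age eligibility uses closed intervals on completed years", {
  expect_false(is_eligible(one_subject(age = 15), reg$durnin_womersley_1974))
  expect_true(is_eligible(one_subject(age = 16), reg$durnin_womersley_1974))
  expect_true(is_eligible(one_subject(age = 68), reg$durnin_womersley_1974))
  expect_false(is_eligible(one_subject(age = 19), reg$slaughter_1988))
  expect_true(is_eligible(one_subject(age = 18), reg$slaughter_1988))
})

test_that("missing age or missing required inputs affect eligibility", {
  expect_error(is_eligible(one_subject(age = NA), reg$durnin_womersley_1974),
               class = "dxacv_unusable_record")
  s <- one_subject(); s$sf_biceps_mm <- NA_real_
  expect_false(is_eligible(s, reg$durnin_womersley_1974))
  expect_true(is_eligible(s, reg$guedes_1985))  # biceps not required there
  # eligibility partitions any cohort
  cohort <- generate_cohort(scenario_config(n = 60, seed = 5))
  for (spec in Filter(function(s) !s$external_only, reg)) {
    e <- is_eligible(cohort, spec)
    expect_length(e, 60)
    expect_false(any(is.na(e)))
  }
})

test_that("hand anchors: Durnin-Womersley and Lukaski reproduce oracle values", {
  s <- one_subject()
  bd <- evaluate_equation(s, reg$durnin_womersley_1974)
  # TR+BC+SE+SI = 51.12 mm
  expect_equal(bd, 1.034194036403, tolerance = 1e-10)
  expect_equal(siri_bd_to_bf_pct(bd), 28.633585745455, tolerance = 1e-10)
  # skinfold sum of 10 mm makes the log term exactly 1
  s10 <- one_subject(sf_triceps_mm = 4, sf_biceps_mm = 2,
                     sf_subscapular_mm = 2.5, sf_suprailiac_mm = 1.5)
  expect_equal(evaluate_equation(s10, reg$durnin_womersley_1974),
               1.1567 - 0.0717)
  ffm <- evaluate_equation(s, reg$lukaski_1986)
  expect_equal(ffm, 0.756 * (160^2 / 672) + 0.110 * 51.44 + 0.107 * 68 - 5.463)
  expect_equal(ffm, 36.2714, tolerance = 1e-4)
  expect_equal(standardize_prediction(reg$lukaski_1986, ffm, s),
               70.5121, tolerance = 1e-4)
})

test_that("Siri conversion has its fixed points and rejects bad density", {
  expect_equal(siri_bd_to_bf_pct(1.1), 0, tolerance = 1e-12)
  expect_equal(siri_bd_to_bf_pct(0.99), 50)
  expect_error(siri_bd_to_bf_pct(0), class = "dxacv_domain_error")
  expect_error(siri_bd_to_bf_pct(-1), class = "dxacv_domain_error")
})

test_that("fat mass bookkeeping subtracts FFM from weight and flags implausibles", {
  expect_equal(as.numeric(bf_kg_from_ffm(50, 39.5)), 10.5)
  expect_equal(as.numeric(bf_kg_from_ffm(51.44, 36.271)), 15.169)
  expect_equal(as.numeric(bf_kg_from_ffm(50, 50)), 0)
  flagged <- bf_kg_from_ffm(c(50, 50, 50), c(55, -1, 40))
  expect_equal(attr(flagged, "implausible"), c(TRUE, TRUE, FALSE))
  expect_equal(as.numeric(flagged), c(-5, 51, 10))
})

test_that("standardization maps every output kind to its comparison scale", {
  s <- one_subject(weight_kg = 50)
  expect_equal(standardize_prediction(reg$hergenroeder_1993,
                                      evaluate_equation(s, reg$hergenroeder_1993),
                                      s), 21.0)
  bd <- evaluate_equation(s, reg$durnin_womersley_1974)
  expect_equal(standardize_prediction(reg$durnin_womersley_1974, bd, s),
               siri_bd_to_bf_pct(bd))
  s18 <- one_subject(age = 18)
  raw <- evaluate_equation(s18, reg$slaughter_1988)
  expect_equal(standardize_prediction(reg$slaughter_1988, raw, s18), raw)
  expect_equal(prediction_scale(reg$durnin_womersley_1974), "bf_percent")
  expect_equal(prediction_scale(reg$lukaski_1986), "ffm_percent")
})

test_that("non-positive skinfold sums inside log10 raise a domain error", {
  s <- one_subject(sf_triceps_mm = 1, sf_biceps_mm = 1,
                   sf_subscapular_mm = 1, sf_suprailiac_mm = 1)
  s$sf_triceps_mm <- -5
  expect_error(evaluate_equation(s, reg$durnin_womersley_1974,
                                 check_eligibility = FALSE),
               class = "dxacv_domain_error")
})

test_that("evaluating an ineligible subject errors", {
  expect_error(evaluate_equation(one_subject(age = 10), reg$durnin_womersley_1974),
               class = "dxacv_ineligible")
  expect_error(evaluate_equation(one_subject(), reg$rjl_manufacturer),
               class = "dxacv_external_equation")
})

test_that("log-sum equations are monotone and Hergenroeder has its closed form", {
  sums <- seq(20, 120, by = 5)
  bd_dw <- 1.1567 - 0.0717 * log10(sums)
  expect_true(all(diff(bd_dw) < 0))
  for (id in c("durnin_womersley_1974", "guedes_1985", "petroski_1995")) {
    spec <- reg[[id]]
    lo <- one_subject(sf_triceps_mm = 8, sf_biceps_mm = 5, sf_subscapular_mm = 8,
                      sf_suprailiac_mm = 8, sf_thigh_mm = 12,
                      sf_midaxillary_mm = 6, sf_calf_mm = 6)
    hi <- one_subject(sf_triceps_mm = 20, sf_biceps_mm = 14,
                      sf_subscapular_mm = 18, sf_suprailiac_mm = 24,
                      sf_thigh_mm = 32, sf_midaxillary_mm = 18,
                      sf_calf_mm = 18)
    expect_lt(evaluate_equation(hi, spec), evaluate_equation(lo, spec))
  }
  w <- seq(30, 90, length.out = 200)
  bf <- vapply(w, function(wi) {
    s <- one_subject(weight_kg = wi)
    standardize_prediction(reg$hergenroeder_1993,
                           evaluate_equation(s, reg$hergenroeder_1993), s)
  }, numeric(1))
  expect_equal(bf, 27 - 300 / w, tolerance = 1e-14)
  expect_true(all(diff(bf) > 0))
})

test_that("BIA mass conservation: FFM% plus BF% from the bookkeeping is 100", {
  cohort <- generate_cohort(scenario_config(n = 40, seed = 8))
  for (spec in Filter(function(s) !s$external_only && s$modality == "bia", reg)) {
    pred <- predict_equation(cohort, spec)
    if (pred$n == 0) next
    sub <- cohort[match(pred$eligible_ids, cohort$subject_id), ]
    ffm_kg <- evaluate_equation(sub, spec)
    bf_pct <- 100 * as.numeric(bf_kg_from_ffm(sub$weight_kg, ffm_kg)) /
      sub$weight_kg
    expect_equal(pred$values + bf_pct, rep(100, pred$n), tolerance = 1e-12)
  }
})

test_that("every registered formula matches the independent oracle on the grid", {
  g <- oracle_grid(100)
  for (spec in Filter(function(s) !s$external_only, reg)) {
    age <- spec$age_min + g$u_age * (spec$age_max - spec$age_min)
    cohort <- grid_to_cohort(g, age)
    got <- evaluate_equation(cohort, spec)
    s <- list(W = g$W, Hm = g$Hm, A = age, TR = g$TR, BC = g$BC, SE = g$SE,
              SI = g$SI, TH = g$TH, AX = g$AX, CA = g$CA, AB = g$AB,
              R = g$R, Xc = g$Xc, sex = 0)
    want <- oracle_formulas[[spec$equation_id]](s)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), 1e-10,
              label = paste("relative error for", spec$equation_id))
    # standardized comparison-scale values agree too
    got_std <- standardize_prediction(spec, got, cohort)
    want_std <- oracle_standardize(spec$equation_id, want, s)
    expect_lt(max(abs(got_std - want_std) / pmax(abs(want_std), 1e-12)), 1e-10)
  }
})

test_that("registry round-trips through its flat CSV, including the shipped copy", {
  tmp <- tempfile(fileext = ".csv")
  write_registry(tmp)
  back <- read_registry(tmp)
  expect_equal(names(back), names(reg))
  for (id in names(reg)) {
    a <- reg[[id]]; b <- back[[id]]
    expect_equal(a[setdiff(names(a), "evaluator")],
                 b[setdiff(names(b), "evaluator")])
  }
  shipped <- system.file("extdata", "equation_registry.csv", package = "dxacv")
  expect_true(nzchar(shipped))
  from_pkg <- read_registry(shipped)
  expect_equal(names(from_pkg), names(reg))
  s <- one_subject()
  expect_equal(evaluate_equation(s, from_pkg$durnin_womersley_1974),
               evaluate_equation(s, reg$durnin_womersley_1974))
})
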