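# Independent brute-force oracles used to cross-check the package.
# These are written from the source formulas and textbook summation
# definitions, deliberately not calling any dxacv internals or the stats
# convenience wrappers the package itself uses.

# --- formula oracles: plain arithmetic, height passed in meters -------------

oracle_formulas <- list(
  durnin_womersley_1974 = function(s)
    1.1567 - 0.0717 * log10(s$TR + s$BC + s$SE + s$SI),
  jackson_pollock_1980 = function(s)
    1.0994921 - 0.0009929 * (s$TR + s$TH + s$SI) +
      0.0000023 * (s$TR + s$TH + s$SI)^2 - 0.0001392 * s$A,
  guedes_1985 = function(s)
    1.1665 - 0.0706 * log10(s$TH + s$SI + s$SE),
  petroski_1995 = function(s)
    1.19547130 - 0.07513507 * log10(s$AX + s$SI + s$TH + s$CA) -
      0.00041072 * s$A,
  sloan_1962 = function(s)
    1.0764 - 0.00081 * s$SI - 0.00088 * s$TR,
  hergenroeder_1993 = function(s)
    0.73 * s$W + 3.0,
  jackson_pollock_1975 = function(s)
    1.096095 - 0.0006952 * (s$TR + s$SI + s$TH + s$AB) +
      0.0000011 * (s$TR + s$SI + s$TH + s$AB)^2 - 0.0000714 * s$A,
  slaughter_1988 = function(s)
    1.33 * (s$TR + s$SE) - 0.013 * (s$TR + s$SE)^2 - 2.5,
  chumlea_2002 = function(s)
    -9.529 + 0.168 * s$W + 0.696 * (100 * s$Hm)^2 / s$R + 0.016 * s$R,
  segal_1988 = function(s)
    5.091 + 0.6483 * (100 * s$Hm)^2 / s$R + 0.1699 * s$W,
  gray_1989 = function(s)
    0.00151 * (100 * s$Hm)^2 - 0.0344 * s$R + 0.140 * s$W -
      0.158 * s$A + 20.387,
  lukaski_1986 = function(s)
    0.756 * (100 * s$Hm)^2 / s$R + 0.110 * s$W + 0.107 * s$Xc - 5.463,
  deurenberg_child_1991 = function(s)
    0.406 * (1e4 * s$Hm^2 / s$R) + 0.360 * s$W + 5.58 * s$Hm +
      0.56 * s$sex - 6.48,
  deurenberg_adult_1991 = function(s)
    0.340 * (1e4 * s$Hm^2 / s$R) + 15.34 * s$Hm + 0.273 * s$W -
      0.127 * s$A + 4.56 * s$sex - 12.44,
  houtkooper_1992 = function(s)
    0.61 * (100 * s$Hm)^2 / s$R + 0.25 * s$W + 1.31,
  kyle_2001 = function(s)
    -4.104 + 0.518 * (100 * s$Hm)^2 / s$R + 0.231 * s$W +
      0.130 * s$Xc + 4.229 * s$sex,
  sun_2003 = function(s)
    -9.53 + 0.69 * (100 * s$Hm)^2 / s$R + 0.17 * s$W + 0.02 * s$R,
  yannakoulia_a_2000 = function(s)
    0.247 * s$W + 0.214 * (100 * s$Hm)^2 / s$R + 0.191 * (100 * s$Hm) - 14.96,
  yannakoulia_b_2000 = function(s)
    0.391 * s$W + 0.168 * (100 * s$Hm) - 0.253 * s$TR +
      0.144 * (100 * s$Hm)^2 / s$R - 9.49
)

oracle_siri <- function(bd) 495 / bd - 450

# standardize a raw oracle prediction to the comparison scale
oracle_standardize <- function(id, raw, s) {
  anthropometry <- c("durnin_womersley_1974", "jackson_pollock_1980",
                     "guedes_1985", "petroski_1995", "sloan_1962",
                     "hergenroeder_1993", "jackson_pollock_1975",
                     "slaughter_1988")
  if (id %in% anthropometry) {
    if (id == "hergenroeder_1993") return(100 * (s$W - raw) / s$W)
    if (id == "slaughter_1988") return(raw)
    return(oracle_siri(raw))
  }
  100 * raw / s$W
}

# --- statistics oracles: explicit summation formulas ------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_ttest <- function(d) {
  n <- length(d)
  s <- sqrt(sum((d - mean(d))^2) / (n - 1))
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_ba <- function(eq, dxa, mult = 1.96) {
  d <- eq - dxa
  n <- length(d)
  s <- sqrt(sum((d - mean(d))^2) / (n - 1))
  list(mean_diff = mean(d), sd_diff = s,
       loa_low = mean(d) - mult * s, loa_high = mean(d) + mult * s)
}

oracle_ols <- function(d, m) {
  n <- length(d)
  Sxx <- sum((m - mean(m))^2)
  beta <- sum((m - mean(m)) * (d - mean(d))) / Sxx
  intercept <- mean(d) - beta * mean(m)
  res <- d - intercept - beta * m
  sse <- sum(res^2)
  see <- sqrt(sse / (n - 2))
  r2 <- 1 - sse / sum((d - mean(d))^2)
  tb <- beta / (see / sqrt(Sxx))
  list(beta = beta, intercept = intercept,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), see = see,
       p_value = 2 * stats::pt(-abs(tb), n - 2))
}

# --- fixtures ---------------------------------------------------------------

# Deterministic 100-point grid spanning plausible input ranges. Each variable
# walks the grid in a different coprime stride so variables decorrelate.
# Ages are mapped per-equation into that equation's development range.
oracle_grid <- function(n = 100) {
  u <- function(stride) (((seq_len(n) - 1) * stride) %% n) / (n - 1)
  span <- function(stride, lo, hi) lo + u(stride) * (hi - lo)
  data.frame(
    W = span(7, 40, 70), Hm = span(11, 1.45, 1.80),
    TR = span(13, 5, 30), BC = span(17, 3, 20), SE = span(19, 5, 28),
    SI = span(23, 5, 35), TH = span(29, 8, 40), AX = span(31, 4, 25),
    CA = span(37, 4, 25), AB = span(41, 6, 35),
    R = span(43, 500, 850), Xc = span(47, 40, 95),
    sex = 0, u_age = u(53)
  )
}

grid_to_cohort <- function(g, age) {
  tibble::tibble(
    subject_id = sprintf("G%03d", seq_len(nrow(g))),
    age_years = age, sex = "female",
    weight_kg = g$W, height_m = g$Hm,
    sf_triceps_mm = g$TR, sf_biceps_mm = g$BC, sf_subscapular_mm = g$SE,
    sf_suprailiac_mm = g$SI, sf_thigh_mm = g$TH, sf_midaxillary_mm = g$AX,
    sf_calf_mm = g$CA, sf_abdominal_mm = g$AB,
    resistance_ohm = g$R, reactance_ohm = g$Xc)
}

# Hand-built 5-subject cohort used for the end-to-end report comparison.
# Ages 20-24 so the adult equations apply and the child-range ones
# (Slaughter, Deurenberg 7-15, Houtkooper 10-19) have empty subsets.
fixture_cohort <- function() {
  tibble::tibble(
    subject_id = paste0("F", 1:5),
    age_years = c(20, 21, 22, 23, 24), sex = "female",
    weight_kg = c(48.0, 51.5, 55.0, 50.0, 58.5),
    height_m = c(1.55, 1.60, 1.63, 1.58, 1.68),
    sf_triceps_mm = c(12.0, 15.0, 18.5, 14.0, 21.0),
    sf_biceps_mm = c(7.0, 9.4, 11.0, 8.5, 13.0),
    sf_subscapular_mm = c(9.5, 11.7, 14.0, 10.8, 16.5),
    sf_suprailiac_mm = c(10.0, 15.0, 20.0, 13.0, 25.0),
    sf_thigh_mm = c(20.0, 25.9, 30.0, 24.0, 34.0),
    sf_midaxillary_mm = c(8.0, 10.9, 13.5, 9.8, 16.0),
    sf_calf_mm = c(8.5, 10.9, 13.0, 10.0, 15.5),
    sf_abdominal_mm = c(14.0, 19.7, 24.0, 17.5, 28.0),
    resistance_ohm = c(640, 672, 700, 655, 730),
    reactance_ohm = c(62, 68, 72, 65, 78),
    dxa_bf_pct = c(24.0, 28.4, 32.5, 26.8, 36.0),
    dxa_ffm_pct = c(76.0, 71.6, 67.5, 73.2, 64.0),
    dxa_bf_kg = c(24.0, 28.4, 32.5, 26.8, 36.0) * c(48.0, 51.5, 55.0, 50.0, 58.5) / 100,
    dxa_ffm_kg = c(76.0, 71.6, 67.5, 73.2, 64.0) * c(48.0, 51.5, 55.0, 50.0, 58.5) / 100)
}

# Independent spreadsheet-style report for the fixture cohort: eligibility,
# prediction, standardization and all agreement statistics recomputed from
# the oracles above.
oracle_fixture_report <- function(cohort = fixture_cohort()) {
  ages <- list(
    durnin_womersley_1974 = c(16, 68), jackson_pollock_1980 = c(18, 55),
    guedes_1985 = c(17, 27), petroski_1995 = c(18, 51),
    sloan_1962 = c(17, 25), hergenroeder_1993 = c(11, 25),
    jackson_pollock_1975 = c(18, 29), slaughter_1988 = c(7, 18),
    chumlea_2002 = c(12, 80), segal_1988 = c(17, 62), gray_1989 = c(19, 74),
    lukaski_1986 = c(19, 50), deurenberg_child_1991 = c(7, 15),
    deurenberg_adult_1991 = c(16, 83), houtkooper_1992 = c(10, 19),
    kyle_2001 = c(20, 94), sun_2003 = c(12, 94),
    yannakoulia_a_2000 = c(18, 26), yannakoulia_b_2000 = c(18, 26))
  anthropometry <- c("durnin_womersley_1974", "jackson_pollock_1980",
                     "guedes_1985", "petroski_1995", "sloan_1962",
                     "hergenroeder_1993", "jackson_pollock_1975",
                     "slaughter_1988")
  out <- list()
  for (id in names(ages)) {
    rng <- ages[[id]]
    keep <- cohort$age_years >= rng[1] & cohort$age_years <= rng[2]
    sub <- cohort[keep, , drop = FALSE]
    s <- list(W = sub$weight_kg, Hm = sub$height_m, A = sub$age_years,
              TR = sub$sf_triceps_mm, BC = sub$sf_biceps_mm,
              SE = sub$sf_subscapular_mm, SI = sub$sf_suprailiac_mm,
              TH = sub$sf_thigh_mm, AX = sub$sf_midaxillary_mm,
              CA = sub$sf_calf_mm, AB = sub$sf_abdominal_mm,
              R = sub$resistance_ohm, Xc = sub$reactance_ohm, sex = 0)
    n <- nrow(sub)
    if (n == 0) {
      out[[id]] <- list(n = 0)
      next
    }
    pred <- oracle_standardize(id, oracle_formulas[[id]](s), s)
    ref <- if (id %in% anthropometry) sub$dxa_bf_pct else sub$dxa_ffm_pct
    d <- pred - ref; m <- (pred + ref) / 2
    sd2 <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
    out[[id]] <- c(
      list(n = n, eq_mean = mean(pred), eq_sd = sd2(pred),
           dxa_mean = mean(ref), dxa_sd = sd2(ref)),
      oracle_pearson(pred, ref),
      stats::setNames(oracle_ttest(d), c("t", "t_df", "t_p")),
      oracle_ba(pred, ref),
      stats::setNames(oracle_ols(d, m),
                      c("beta", "intercept", "adj_r2", "see", "reg_p")))
  }
  out
}
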