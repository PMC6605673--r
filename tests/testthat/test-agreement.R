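test_that("Pearson screen matches the summation oracle and textbook anchors", {
  expect_equal(pearson_screen(difference_series(c(2, 4, 6), c(1, 2, 3)))$r, 1)
  expect_equal(pearson_screen(difference_series(c(3, 2, 1), c(1, 2, 3)))$r, -1)
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  got <- pearson_screen(difference_series(x, y))
  expect_equal(got$r, 0.8, tolerance = 1e-12)
  expect_equal(got$p, 0.104088038662, tolerance = 1e-9)
  expect_equal(got$df, 3)
  want <- oracle_pearson(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_error(pearson_screen(difference_series(c(1, 1, 1), c(1, 2, 3))),
               class = "dxacv_degenerate_input")
  expect_error(pearson_screen(difference_series(1:2, 2:3)),
               class = "dxacv_insufficient_data")
})

test_that("one-sample t against zero matches the oracle and handles degeneracy", {
  expect_equal(one_sample_t_zero(c(0, 0, 0, 0))[c("t", "p")], list(t = 0, p = 1))
  got <- one_sample_t_zero(c(1, -1, 2))
  expect_equal(got$t, 0.755928946018, tolerance = 1e-9)
  expect_equal(got$df, 2)
  expect_equal(got$p, 0.528595479209, tolerance = 1e-9)
  want <- oracle_ttest(c(1, -1, 2))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # symmetric pair has mean exactly zero
  for (c0 in c(0.5, 2, 17)) {
    sym <- one_sample_t_zero(c(-c0, c0))
    expect_equal(sym$t, 0)
    expect_equal(sym$p, 1)
  }
  degen <- one_sample_t_zero(c(2, 2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
})

test_that("Bland-Altman statistics match the oracle on the toy fixtures", {
  same <- bland_altman(difference_series(c(30, 32, 28), c(30, 32, 28)))
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  offset <- bland_altman(difference_series(c(30, 32, 28) + 2, c(30, 32, 28)))
  expect_equal(offset$mean_diff, 2)
  expect_equal(offset$sd_diff, 0)
  expect_equal(c(offset$loa_low, offset$loa_high), c(2, 2))
  got <- bland_altman(difference_series(c(30, 32, 28), c(29, 33, 26)))
  expect_equal(got$mean_diff, 0.666666666667, tolerance = 1e-10)
  expect_equal(got$sd_diff, 1.527525231652, tolerance = 1e-10)
  expect_equal(got$loa_low, -2.327282787371, tolerance = 1e-10)
  expect_equal(got$loa_high, 3.660616120704, tolerance = 1e-10)
  want <- oracle_ba(c(30, 32, 28), c(29, 33, 26))
  expect_equal(got[c("mean_diff", "sd_diff", "loa_low", "loa_high")], want)
  # plot-ready pairs are the raw means and differences
  expect_equal(got$points$mean, c(29.5, 32.5, 27))
  expect_equal(got$points$difference, c(1, -1, 2))
  expect_error(bland_altman(difference_series(1, 1)),
               class = "dxacv_insufficient_data")
})

test_that("proportional-bias regression matches OLS oracle, exact fits and degeneracy", {
  m <- c(28, 29, 30, 31, 32)
  # pairs built so that d = 0.1*m exactly while the pair mean stays m
  exact <- proportional_bias_fit(difference_series(m + 0.05 * m, m - 0.05 * m))
  expect_equal(exact$beta, 0.1, tolerance = 1e-10)
  expect_equal(exact$see, 0, tolerance = 1e-8)
  expect_equal(exact$adj_r2, 1, tolerance = 1e-10)
  # affine: d = 0.5*m - 2
  d <- 0.5 * m - 2
  aff <- proportional_bias_fit(difference_series(m + d / 2, m - d / 2))
  expect_equal(aff$beta, 0.5, tolerance = 1e-10)
  expect_equal(aff$intercept, -2, tolerance = 1e-9)
  # 5-point fixture against the summation oracle (frozen values)
  d5 <- c(1, -1, 2, 0, 1); m5 <- c(30, 31, 29, 32, 30)
  got <- proportional_bias_fit(difference_series(m5 + d5 / 2, m5 - d5 / 2))
  expect_equal(got$beta, -0.807692307692, tolerance = 1e-9)
  expect_equal(got$intercept, 25.153846153846, tolerance = 1e-9)
  expect_equal(got$see, 0.776250025806, tolerance = 1e-9)
  expect_equal(got$adj_r2, 0.536489151874, tolerance = 1e-9)
  expect_equal(got$p_value, 0.098262227884, tolerance = 1e-9)
  want <- oracle_ols(d5, m5)
  expect_equal(got$beta, want$beta, tolerance = 1e-12)
  expect_equal(got$see, want$see, tolerance = 1e-12)
  expect_equal(got$adj_r2, want$adj_r2, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  # constant means are degenerate input; constant differences a flagged zero
  expect_error(proportional_bias_fit(difference_series(c(10, 11, 12),
                                                       c(10, 9, 8))),
               class = "dxacv_degenerate_input")
  const_d <- proportional_bias_fit(difference_series(c(31, 32, 33),
                                                     c(29, 30, 31)))
  expect_true(const_d$degenerate)
  expect_equal(const_d$beta, 0)
  expect_equal(const_d$p_value, 1)
  expect_equal(const_d$see, 0)
})

test_that("box-plot rule flags only values beyond k box-lengths", {
  v <- c(9, 10, 12, 14, 15, 40)
  q <- stats::quantile(v, c(.25, .75), names = FALSE, type = 7)
  flags <- outlier_flags(v)
  expect_equal(flags, v > q[2] + 3 * (q[2] - q[1]) | v < q[1] - 3 * (q[2] - q[1]))
  expect_true(flags[6])
  # within three box lengths of the box: not flagged
  expect_false(any(outlier_flags(c(9, 10, 12, 14, 15, 25))))
  expect_false(any(outlier_flags(rep(7, 6))))   # zero IQR flags nothing
  low <- outlier_flags(c(-40, 10, 11, 12, 13, 14))
  expect_true(low[1])
  expect_error(outlier_flags(1:3), class = "dxacv_insufficient_data")
})

test_that("verdict staging mirrors the screen-agreement-bias chain", {
  set.seed(404)
  dxa <- rnorm(40, 28, 7)
  agree <- validity_verdict(difference_series(dxa + rnorm(40, 0, 1.5), dxa))
  expect_equal(agree$verdict, "valid")
  expect_false(is.null(agree$stage3))
  expect_false(is.null(agree$bland_altman))

  uncorrelated <- validity_verdict(difference_series(rnorm(40, 28, 4), dxa))
  expect_equal(uncorrelated$verdict, "invalid_stage1")
  expect_null(uncorrelated$stage2)
  expect_null(uncorrelated$stage3)

  biased <- validity_verdict(difference_series(dxa + 6 + rnorm(40, 0, 1), dxa))
  expect_equal(biased$verdict, "invalid_stage2")
  expect_null(biased$stage3)

  # proportional bias with centered differences: stages 1-2 pass, 3 fails
  prop <- validity_verdict(
    difference_series(dxa + 0.4 * (dxa - mean(dxa)) + rnorm(40, 0, 0.5), dxa))
  expect_equal(prop$verdict, "invalid_stage3")
  expect_false(prop$stage3$pass)

  degen <- validity_verdict(difference_series(rep(30, 5), dxa[1:5]))
  expect_equal(degen$verdict, "invalid_stage1")
  expect_false(is.na(degen$degenerate_note))
})

test_that("stage 3 exists iff stages 1 and 2 passed, over generated cohorts", {
  for (i in 1:20) {
    cfg <- scenario_config(n = 25, seed = 700 + i, scenario = "constant_bias",
                           bias_const = (i %% 4) * 2, noise_sd = 2)
    cohort <- inject_bias(generate_cohort(cfg), cfg)
    run <- run_crossvalidation(cohort)
    for (v in run$verdicts) {
      if (is.null(v)) next
      reached3 <- !is.null(v$stage3)
      passed12 <- !is.null(v$stage1) && v$stage1$pass &&
        !is.null(v$stage2) && v$stage2$pass
      expect_equal(reached3, passed12)
    }
  }
})
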