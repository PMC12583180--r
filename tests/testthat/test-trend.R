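# Theil-Sen / Mann-Kendall engines, typologies, CV, lagged correlation.

test_that("Theil-Sen slope matches pairwise enumeration", {
  expect_equal(theil_sen_slope(c(1, 2, 4)), 1.5)   # slopes {1, 1.5, 2}
  expect_equal(theil_sen_slope(rep(3.3, 7)), 0)
  expect_equal(theil_sen_slope(0.002 * (1:22)), 0.002)
  expect_error(theil_sen_slope(c(1, 2)), "at least 3")

  set.seed(101)
  for (rep_i in 1:200) {
    n <- sample(3:15, 1)
    x <- rnorm(n)
    expect_equal(theil_sen_slope(x), oracle_theil_sen(x), tolerance = 1e-12)
  }
})

test_that("Mann-Kendall statistics match enumeration and the stated formulas", {
  r <- suppressWarnings(mann_kendall(1:4))
  expect_identical(r$S, 6L)
  expect_equal(r$VarS, 4 * 3 * 13 / 18)
  expect_equal(r$Z, 5 / sqrt(4 * 3 * 13 / 18))

  dec <- mann_kendall(seq(10, 1))
  expect_identical(dec$S, -45L)           # -n(n-1)/2
  expect_lt(dec$Z, 0)
  con <- mann_kendall(rep(2, 10))
  expect_identical(con$S, 0L)
  expect_equal(con$Z, 0)

  set.seed(55)
  for (rep_i in 1:200) {
    n <- sample(4:15, 1)
    x <- round(rnorm(n), 1)               # provoke ties
    expect_equal(suppressWarnings(mann_kendall(x))$S, oracle_mk_s(x))
  }

  # tie correction subtracts sum t(t-1)(2t+5)/18 over tie groups
  x <- c(1, 2, 2, 3, 3, 3, 4, 5)
  vt <- suppressWarnings(mann_kendall(x, tie_correction = TRUE))$VarS
  v0 <- suppressWarnings(mann_kendall(x, tie_correction = FALSE))$VarS
  expect_equal(v0 - vt, (2 * 1 * 9 + 3 * 2 * 11) / 18)
})

test_that("trend statistics are shift-invariant and antisymmetric", {
  set.seed(77)
  x <- rnorm(12)
  expect_equal(theil_sen_slope(x + 100), theil_sen_slope(x), tolerance = 1e-12)
  expect_identical(mann_kendall(x + 100)$S, mann_kendall(x)$S)
  expect_identical(mann_kendall(rev(x))$S, -mann_kendall(x)$S)
})

test_that("five-class trend typology follows the slope/Z rule", {
  lv <- trend_classes()
  expect_equal(lv[classify_trend(0.001, 2.5)], "significant_improvement")
  expect_equal(lv[classify_trend(0.001, 1.0)], "insignificant_improvement")
  expect_equal(lv[classify_trend(0.0001, 0.3)], "stabilization")
  expect_equal(lv[classify_trend(-0.002, -1.0)], "insignificant_degradation")
  expect_equal(lv[classify_trend(-0.002, -2.2)], "significant_degradation")
  # residual cell: small slope, large Z -> stabilization
  expect_equal(lv[classify_trend(0.0001, 3.0)], "stabilization")
  # thresholds are inclusive on the slope side
  expect_equal(lv[classify_trend(0.0005, 0)], "insignificant_improvement")
  expect_equal(lv[classify_trend(-0.0005, -2)], "significant_degradation")
})

test_that("coefficient of variation and its typology", {
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3)
  expect_equal(coefficient_of_variation(rep(5, 6)), 0)
  set.seed(3); x <- runif(10, 1, 2)
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x))
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))   # mean ~ 0

  lv <- cv_classes()
  expect_equal(lv[classify_cv(0.05)], "stabilisation")
  expect_equal(lv[classify_cv(0.07)], "slight_fluctuation")  # lower-inclusive
  expect_equal(lv[classify_cv(0.25)], "moderate_fluctuation")
  expect_equal(lv[classify_cv(0.40)], "high_fluctuation")
  expect_equal(lv[classify_cv(0.90)], "wild_fluctuation")
})

test_that("raster trend analysis agrees with the per-series functions", {
  set.seed(42)
  arr <- array(rnorm(4 * 5 * 10, mean = 0.5, sd = 0.1), c(4, 5, 10))
  stk <- mk_annual_stack(arr, 2001:2010)
  tr <- trend_analysis(stk)
  for (r in 1:4) for (c_ in 1:5) {
    v <- arr[r, c_, ]
    expect_equal(tr$slope$values[r, c_], theil_sen_slope(v, 2001:2010),
                 tolerance = 1e-12)
    mk <- mann_kendall(v)
    expect_equal(tr$s_stat$values[r, c_], mk$S)
    expect_equal(tr$z$values[r, c_], mk$Z, tolerance = 1e-12)
  }
  big_s <- abs(tr$s_stat$values) > 1   # |S| = 1 maps to Z = 0 (continuity)
  expect_true(all(sign(tr$z$values[big_s]) == sign(tr$s_stat$values[big_s])))

  # masked short series are excluded and counted
  msk <- array(FALSE, dim(arr)); msk[1, 1, 1:8] <- TRUE
  stk2 <- grid_stack(arr, years = 2001:2010, transform = stk$transform,
                     mask = msk)
  tr2 <- trend_analysis(stk2)
  expect_true(tr2$slope$mask[1, 1])
  expect_equal(tr2$n_masked, 1)
})

test_that("stability analysis reproduces the per-series CV", {
  set.seed(43)
  arr <- array(runif(3 * 3 * 8, 0.2, 0.8), c(3, 3, 8))
  st <- stability_analysis(mk_annual_stack(arr, 2001:2008))
  for (r in 1:3) for (c_ in 1:3)
    expect_equal(st$cv$values[r, c_], coefficient_of_variation(arr[r, c_, ]),
                 tolerance = 1e-12)
  expect_true(all(st$cv$values >= 0))
})

test_that("lagged correlation: self-correlation, null calibration, lag recovery", {
  set.seed(9)
  arr <- array(rnorm(10 * 10 * 22), c(10, 10, 22))
  stk <- mk_annual_stack(arr, 2001:2022)
  self <- lagged_correlation(stk, stk, 0)
  expect_true(all(abs(self$r$values - 1) < 1e-12))

  # independent white noise: ~5% of pixels significant at alpha = 0.05
  set.seed(10)
  a <- mk_annual_stack(array(rnorm(25 * 40 * 22), c(25, 40, 22)), 2001:2022)
  b <- mk_annual_stack(array(rnorm(25 * 40 * 22), c(25, 40, 22)), 2001:2022)
  null_lc <- lagged_correlation(a, b, 0)
  expect_lt(abs(mean(null_lc$p$values < 0.05) - 0.05), 0.02)

  # response built from the lag-1 driver: lag-1 beats lag-0 almost everywhere
  set.seed(11)
  drv <- array(rnorm(10 * 10 * 23), c(10, 10, 23))
  resp <- drv[, , 1:22] + array(rnorm(10 * 10 * 22, sd = 0.3), c(10, 10, 22))
  ds <- mk_annual_stack(drv, 2000:2022)
  rs <- mk_annual_stack(resp, 2001:2022)
  r0 <- lagged_correlation(rs, ds, 0)$r$values
  r1 <- lagged_correlation(rs, ds, 1)$r$values
  expect_gte(mean(r1 > r0), 0.95)
  expect_error(lagged_correlation(rs, ds, 21), "overlap")
})
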