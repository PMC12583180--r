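# FVC chain: compositing, annualisation, endmembers, dimidiate model, grading.

test_that("maximum-value compositing keeps the per-pixel maximum and the mask rule", {
  tr <- list(x0 = 0, y0 = 1, dx = 1, dy = 1)
  arr <- array(c(0.3, 0.1, 0.2, 0.4,      # period 1
                 0.5, 0.05, 0.25, 0.35,   # period 2
                 0.6, 0.6, 0.6, 0.6),     # next month, single period
               c(2, 2, 3))
  msk <- array(FALSE, c(2, 2, 3))
  msk[1, 1, 1] <- TRUE                    # first period masked at one pixel
  stk <- grid_stack(arr, years = 2001, months = c(1, 1, 2), periods = c(1, 2, 1),
                    transform = tr, mask = msk)
  mo <- monthly_composite(stk)
  expect_equal(stack_size(mo), 2)
  expect_equal(mo$data[2, 2, 1], 0.4)              # max(0.4, 0.35)
  expect_equal(mo$data[1, 1, 1], 0.5)              # masked period dropped
  expect_false(mo$mask[1, 1, 1])
  expect_equal(mo$data[, , 2], matrix(0.6, 2, 2))  # identity for single period

  # masked in all periods stays masked
  msk2 <- msk; msk2[1, 1, 2] <- TRUE
  stk2 <- grid_stack(arr, years = 2001, months = c(1, 1, 2),
                     periods = c(1, 2, 1), transform = tr, mask = msk2)
  expect_true(monthly_composite(stk2)$mask[1, 1, 1])
})

test_that("annual mean averages available months and honours the mask", {
  tr <- list(x0 = 0, y0 = 0, dx = 1, dy = 1)
  arr <- array(c(0.2, 0.2, 0.2, 0.2, 0.6, 0.6, 0.6, 0.6), c(2, 2, 2))
  msk <- array(FALSE, dim(arr)); msk[1, 1, 2] <- TRUE
  stk <- grid_stack(arr, years = 2001, months = 1:2, transform = tr, mask = msk)
  m <- annual_mean_evi(stk, 2001)
  expect_equal(m$values[2, 2], 0.4)
  expect_equal(m$values[1, 1], 0.2)      # one month masked -> mean of the rest
  expect_error(annual_mean_evi(stk, 1999), "no months")
})

test_that("composite-then-average is invariant to duplicating a period", {
  set.seed(21)
  tr <- list(x0 = 0, y0 = 2, dx = 1, dy = 1)
  arr <- array(runif(3 * 3 * 6), c(3, 3, 6))
  base <- grid_stack(arr, years = 2001, months = rep(1:3, each = 2),
                     periods = rep(1:2, 3), transform = tr)
  dup <- grid_stack(arr[, , c(1, 2, 2, 3, 4, 5, 6)], years = 2001,
                    months = c(1, 1, 1, 2, 2, 3, 3),
                    periods = c(1, 2, 3, 1, 2, 1, 2), transform = tr)
  a <- annual_mean_evi(monthly_composite(base), 2001)
  b <- annual_mean_evi(monthly_composite(dup), 2001)
  expect_equal(a$values, b$values)
})

test_that("endmember percentiles match empirical quantiles", {
  set.seed(33)
  u <- mk_grid(matrix(runif(1000), 25, 40))
  em <- estimate_endmembers(u)
  expect_lt(abs(em$evi_soil - 0.005), 0.01)
  expect_lt(abs(em$evi_veg - 0.995), 0.01)

  expect_error(estimate_endmembers(mk_grid(matrix(0.4, 30, 30))), "degenerate")

  skewed <- mk_grid(matrix(c(rep(0.1, 99), 0.9), 10, 10))
  suppressWarnings(em2 <- estimate_endmembers(skewed))
  expect_equal(em2$evi_soil, 0.1)
  expect_error(estimate_endmembers(u, soil_percentile = 99, veg_percentile = 1),
               "percentiles")
})

test_that("dimidiate pixel model is the clipped linear rescaling", {
  em <- structure(list(evi_soil = 0.1, evi_veg = 0.7,
                       soil_percentile = 0.5, veg_percentile = 99.5),
                  class = "fvc_endmembers")
  g <- mk_grid(matrix(c(0.1, 0.7, 0.4, 0.05, 0.9, 0.25), 2, 3))
  fvc <- estimate_fvc(g, em)
  expect_equal(fvc$values[1, 1], 0)      # at the soil endmember
  expect_equal(fvc$values[2, 1], 1)      # at the vegetation endmember
  expect_equal(fvc$values[1, 2], 0.5)    # midway
  expect_equal(fvc$values[2, 2], 0)      # clipped below
  expect_equal(fvc$values[1, 3], 1)      # clipped above
  expect_equal(fvc$values[2, 3], 0.25)

  # monotone non-decreasing in the index
  x <- sort(runif(50))
  fx <- estimate_fvc(mk_grid(matrix(x, 1)), em)$values
  expect_true(all(diff(as.vector(fx)) >= 0))
})

test_that("FVC grades use lower-inclusive bins with a closed top", {
  g <- mk_grid(matrix(c(0.10, 0.20, 1.00, 0.799, 0.80, 0.0), 2, 3))
  cls <- classify_fvc(g)
  expect_equal(cls$labels[cls$values[1, 1]], "low")
  expect_equal(cls$labels[cls$values[2, 1]], "medium_low")   # boundary 0.20
  expect_equal(cls$labels[cls$values[1, 2]], "high")         # top closure at 1
  expect_equal(cls$labels[cls$values[2, 2]], "medium_high")
  expect_equal(cls$labels[cls$values[1, 3]], "high")         # boundary 0.80
  expect_equal(cls$labels[cls$values[2, 3]], "low")
  expect_error(classify_fvc(mk_grid(matrix(c(0.5, 1.2), 1)))  , "outside")
})

test_that("fvc_series chains MVC, annualisation and per-year endmembers", {
  cfg <- scene_config(shape = c(25, 25), years = 2001:2005, seed = 17,
                      sixteen_day = TRUE)
  sc <- generate_scene(cfg)
  fs <- fvc_series(sc$evi_monthly)
  expect_equal(stack_size(fs$fvc), 5)
  expect_equal(fs$endmembers$year, 2001:2005)
  expect_true(all(fs$fvc$data >= 0 & fs$fvc$data <= 1))
  # pooled endmembers give one shared pair
  fp <- fvc_series(sc$evi_monthly, endmember_scope = "pooled")
  expect_equal(length(unique(fp$endmembers$evi_soil)), 1)
  # grade map is constant where the generating baseline is constant (noise 0)
  cfg0 <- scene_config(shape = c(12, 12), years = 2001:2004, seed = 3,
                       evi_params = list(noise_sd = 0, spatial_sd = 0,
                                         landuse_effect = 0, temp_coef = 0,
                                         precip_coef = 0,
                                         trend = list(type = "none")))
  sc0 <- generate_scene(cfg0)
  ann0 <- annual_mean_evi(sc0$evi_monthly, 2002)
  expect_lt(diff(range(ann0$values)), 1e-12)
})
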