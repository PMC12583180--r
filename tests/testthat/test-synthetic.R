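# Scene generator: determinism, stated physical structure, recoverability.

small_cfg <- function(...) scene_config(shape = c(30, 30), years = 2001:2006,
                                        seed = 7, ...)

test_that("generation is deterministic under the seed and varies across seeds", {
  s1 <- generate_scene(small_cfg())
  s2 <- generate_scene(small_cfg())
  expect_identical(s1$dem$values, s2$dem$values)
  expect_identical(s1$evi_monthly$data, s2$evi_monthly$data)
  expect_identical(s1$landuse$values, s2$landuse$values)
  s3 <- generate_scene(scene_config(shape = c(30, 30), years = 2001:2006,
                                    seed = 8))
  expect_gt(max(abs(s1$evi_monthly$data - s3$evi_monthly$data)), 0)
})

test_that("DEM honours the elevation clip range and the zero-relief ramp", {
  d <- generate_dem(small_cfg())
  expect_gte(min(d$values), 3173)
  expect_lte(max(d$values), 5279)
  ramp <- generate_dem(small_cfg(dem_params = list(relief_amp = 0)))
  # pure directional ramp: strictly non-increasing west->east and north->south
  expect_true(all(diff(t(ramp$values)[, 1]) <= 0))
  expect_true(all(apply(ramp$values, 2, function(col) all(diff(col) <= 0))))
  # high corner is the northwest one
  expect_gt(ramp$values[1, 1], ramp$values[30, 30])
})

test_that("climate obeys lapse rate and precipitation floor", {
  cfg <- small_cfg(climate_params = list(noise_sd_t = 0, noise_sd_p = 0,
                                         interannual_sd_t = 0,
                                         interannual_sd_p = 0))
  dem <- generate_dem(cfg)
  cl <- generate_climate(dem, cfg)
  # noiseless: temperature is an exact linear function of elevation
  tdiff <- cl$temperature$data[, , 1] + 0.006 * dem$values
  expect_lt(diff(range(tdiff)), 1e-9)
  expect_gte(min(cl$precipitation$data), 0)

  # noisy: the highest-lowest cell contrast shows -lapse * elevation gap,
  # with error shrinking as 1/sqrt(years)
  cfg2 <- scene_config(shape = c(40, 40), years = 2001:2022, seed = 2)
  dem2 <- generate_dem(cfg2)
  cl2 <- generate_climate(dem2, cfg2)
  hi <- which(dem2$values == max(dem2$values), arr.ind = TRUE)[1, ]
  lo <- which(dem2$values == min(dem2$values), arr.ind = TRUE)[1, ]
  dT <- mean(cl2$temperature$data[hi[1], hi[2], ] -
             cl2$temperature$data[lo[1], lo[2], ])
  dE <- dem2$values[hi[1], hi[2]] - dem2$values[lo[1], lo[2]]
  expect_lt(abs(dT + 0.006 * dE), 0.5)
})

test_that("EVI series: degenerate constancy and exact planted linear trend", {
  base_cfg <- function(trend) small_cfg(
    evi_params = list(noise_sd = 0, temp_coef = 0, precip_coef = 0,
                      trend = trend, spatial_sd = 0.04))
  flat <- generate_scene(base_cfg(list(type = "none")))
  ann <- sapply(flat$config$years, function(y)
    annual_mean_evi(flat$evi_monthly, y)$values[5, 5])
  expect_lt(diff(range(ann)), 1e-12)

  blk <- generate_scene(base_cfg(list(type = "block", value = 0.002)))
  stopifnot(blk$truth$trend_mask[2, 2], !blk$truth$trend_mask[29, 29])
  ann_in <- sapply(blk$config$years, function(y)
    annual_mean_evi(blk$evi_monthly, y)$values[2, 2])
  expect_equal(theil_sen_slope(ann_in, blk$config$years), 0.002,
               tolerance = 1e-12)
  ann_out <- sapply(blk$config$years, function(y)
    annual_mean_evi(blk$evi_monthly, y)$values[29, 29])
  expect_equal(theil_sen_slope(ann_out, blk$config$years), 0,
               tolerance = 1e-12)
})

test_that("planted trends are recovered through noise (Monte-Carlo)", {
  cfg <- scene_config(shape = c(20, 20), years = 2001:2022, seed = 31,
                      evi_params = list(trend = list(type = "constant",
                                                     value = 0.002),
                                        noise_sd = 0.02))
  sc <- generate_scene(cfg)
  ann <- grid_stack(lapply(cfg$years, function(y)
    annual_mean_evi(sc$evi_monthly, y)), years = cfg$years)
  tr <- trend_analysis(ann)
  expect_gte(sum(!tr$slope$mask), 100)
  expect_lt(abs(mean(tr$slope$values) - 0.002), 5e-4)
})

test_that("categorical layers are complete, deterministic and balanced", {
  cfg <- scene_config(shape = c(100, 100), years = 2001:2004, seed = 3)
  cg <- generate_categorical(cfg, 2, seed_offset = 5)
  expect_setequal(unique(as.vector(cg$values)), c(1, 2))
  cg2 <- generate_categorical(cfg, 2, seed_offset = 5)
  expect_identical(cg$values, cg2$values)
  cg5 <- generate_categorical(cfg, 5, seed_offset = 6)
  shares <- tabulate(cg5$values, 5) / 1e4
  expect_true(all(abs(shares - 0.2) < 0.05))
  expect_error(generate_categorical(cfg, 1), "at least 2")
})

test_that("scene bundle is co-registered with a complete truth record", {
  sc <- generate_scene(small_cfg())
  for (nm in c("slope", "aspect", "landuse", "soil_type", "soc", "grazing",
               "popdensity"))
    expect_true(same_geometry(sc$dem, sc[[nm]]), label = nm)
  expect_named(sc$truth, c("tau", "trend_mask", "temp_coef", "precip_coef",
                           "baseline", "landuse_means", "seasonal_amp"))
  expect_identical(dim(sc$truth$tau), dim(sc$dem$values))
})

test_that("16-day mode produces two periods per month and survives MVC", {
  cfg <- scene_config(shape = c(10, 10), years = 2001:2004, seed = 5,
                      sixteen_day = TRUE)
  sc <- generate_scene(cfg)
  expect_equal(stack_size(sc$evi_monthly), 4 * 12 * 2)
  mo <- monthly_composite(sc$evi_monthly)
  expect_equal(stack_size(mo), 4 * 12)
  # composite is the pairwise max
  expect_equal(mo$data[, , 1],
               pmax(sc$evi_monthly$data[, , 1], sc$evi_monthly$data[, , 2]))
})

test_that("scene directories round-trip through write_scene/read_scene", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_config(shape = c(8, 8), years = 2001:2004,
                                    seed = 13))
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_equal(back$dem$values, sc$dem$values, tolerance = 1e-6)
  expect_equal(back$evi_monthly$times, sc$evi_monthly$times)
  expect_equal(back$evi_monthly$data, sc$evi_monthly$data, tolerance = 1e-6)
  expect_equal(back$landuse$labels, sc$landuse$labels)
  expect_equal(matrix(back$truth$tau, 8, 8), sc$truth$tau, tolerance = 1e-9)
})
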