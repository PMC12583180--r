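# Raster substrate: CSV-dialect I/O, resampling, IDW, DEM derivatives.

test_that("grid CSV dialect round-trips values, mask and transform", {
  set.seed(11)
  g <- new_grid(matrix(runif(100), 10, 10),
                list(x0 = 1000, y0 = 5000, dx = 250, dy = 250))
  g$mask[3, 7] <- TRUE
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_lt(max(abs(g$values[!g$mask] - g2$values[!g2$mask])), 1e-6)
  expect_identical(g$transform, g2$transform)
  expect_identical(g$mask, g2$mask)

  # explicit tiny fixture: masked nodata cell and exact integer values
  lines <- c("#fvcdyn_grid v1", "#shape 2 2", "#transform 0 1 1 1",
             "#nodata -9999", "#units EVI", "#crs local",
             "1,2", "3,-9999")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, p2)
  g3 <- read_grid(p2)
  expect_equal(g3$values[1, ], c(1, 2))
  expect_equal(g3$values[2, 1], 3)
  expect_true(g3$mask[2, 2])
  expect_identical(g3$units, "EVI")
})

test_that("grid reader rejects missing files and malformed headers", {
  expect_error(read_grid(file.path(tempdir(), "does_not_exist.csv")),
               "not found")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#fvcdyn_grid v1", "#shape 2 2", "1,2", "3,4"), p)
  expect_error(read_grid(p), "geotransform")
  writeLines(c("not a grid", "1,2"), p)
  expect_error(read_grid(p), "header")
})

test_that("resampling: identity, convexity and the bilinear midpoint", {
  set.seed(5)
  g <- mk_grid(matrix(runif(36), 6, 6))
  same <- align_resample(g, g, "bilinear")
  expect_equal(same$values, g$values)

  const <- mk_grid(matrix(4.2, 5, 5))
  tgt <- grid_geometry(nrows = 3, ncols = 3, x0 = 0.3, y0 = 3.1,
                       dx = 1.3, dy = 1.2)
  expect_true(all(abs(align_resample(const, tgt, "bilinear")$values - 4.2) < 1e-12))

  # two-row source 0 / 10; sampling midway between the row centers gives 5
  src <- mk_grid(rbind(c(0, 0), c(10, 10)))
  mid <- grid_geometry(nrows = 1, ncols = 1, x0 = 0, y0 = 0.5, dx = 1, dy = 1)
  expect_equal(align_resample(src, mid, "bilinear")$values[1, 1], 5)

  # convexity on random geometry
  rnd <- mk_grid(matrix(rnorm(64), 8, 8))
  tg2 <- grid_geometry(nrows = 5, ncols = 5, x0 = 0.7, y0 = 6.2,
                       dx = 1.1, dy = 1.3)
  out <- align_resample(rnd, tg2, "bilinear")
  expect_gte(min(out$values), min(rnd$values))
  expect_lte(max(out$values), max(rnd$values))
})

test_that("resampling respects categorical layers and spatial overlap", {
  cg <- new_classified_grid(matrix(c(1, 1, 2, 2), 2, 2), c("a", "b"),
                            list(x0 = 0, y0 = 1, dx = 1, dy = 1))
  expect_error(align_resample(cg, cg, "bilinear"), "categorical")
  near <- align_resample(cg, grid_geometry(nrows = 4, ncols = 4, x0 = -0.4,
                                           y0 = 1.4, dx = 0.5, dy = 0.5),
                         "nearest")
  expect_true(all(near$values[!near$mask] %in% c(1, 2)))
  far <- grid_geometry(nrows = 2, ncols = 2, x0 = 100, y0 = 100, dx = 1, dy = 1)
  expect_error(align_resample(cg, far, "nearest"), "overlap")
})

test_that("IDW: degenerate, symmetric and hand-computed weights", {
  tgt <- grid_geometry(nrows = 1, ncols = 1, x0 = 0, y0 = 0, dx = 1, dy = 1)
  one <- idw_interpolate(data.frame(x = 3, y = 4, value = 7), tgt)
  expect_equal(one$values[1, 1], 7)

  two <- idw_interpolate(data.frame(x = c(-2, 2), y = 0, value = c(0, 10)), tgt)
  expect_equal(two$values[1, 1], 5)

  # weights 1 and 1/9 at distances 1 and 3, power 2 -> (0 + 10/9)/(10/9 + ... )
  duo <- idw_interpolate(data.frame(x = c(1, 3), y = 0, value = c(0, 10)),
                         tgt, power = 2)
  expect_equal(duo$values[1, 1], (0 * 1 + 10 * (1 / 9)) / (1 + 1 / 9))

  expect_error(idw_interpolate(data.frame(x = numeric(0), y = numeric(0),
                                          value = numeric(0)), tgt),
               "at least one sample")
})

test_that("IDW reproduces sample values exactly at sample locations", {
  set.seed(9)
  samples <- data.frame(x = runif(8, 0, 4), y = runif(8, 0, 4),
                        value = rnorm(8))
  for (p in c(0.5, 2, 4)) {
    tgt <- grid_geometry(nrows = 1, ncols = 1, x0 = samples$x[3],
                         y0 = samples$y[3], dx = 1, dy = 1)
    out <- idw_interpolate(samples, tgt, power = p)
    expect_equal(out$values[1, 1], samples$value[3])
  }
})

test_that("slope/aspect: flat surface, analytic planes, Horn interior", {
  flat <- slope_aspect(mk_grid(matrix(100, 5, 5)))
  inner <- flat$slope$values[2:4, 2:4]
  expect_true(all(inner == 0))
  expect_true(all(flat$aspect$values[2:4, 2:4] == -1))

  # plane z = x (rising east, 1 m cells): 45 degrees, faces west (270)
  xs <- matrix(rep(0:5, each = 6), 6, 6)   # z = column index - 1
  east_up <- slope_aspect(mk_grid(xs))
  expect_true(all(abs(east_up$slope$values[2:5, 2:5] - 45) < 1e-9))
  expect_true(all(abs(east_up$aspect$values[2:5, 2:5] - 270) < 1e-9))

  # plane rising due south faces north: aspect 0
  zs <- matrix(rep(0:5, times = 6), 6, 6)   # row index grows southward
  south_up <- slope_aspect(mk_grid(zs))
  expect_true(all(abs(south_up$aspect$values[2:5, 2:5] - 0) < 1e-9))

  # any plane: spatially constant interior slope/aspect
  pl <- mk_grid(outer(5:1, 1:6, function(r, c) 2.5 * c - 1.3 * r))
  ps <- slope_aspect(pl)
  expect_lt(diff(range(ps$slope$values[2:4, 2:5])), 1e-6)
  expect_lt(diff(range(ps$aspect$values[2:4, 2:5])), 1e-6)

  expect_error(slope_aspect(mk_grid(matrix(1, 2, 2))), "3 x 3")
})

test_that("stack construction enforces co-registration and time order", {
  g1 <- mk_grid(matrix(1, 3, 3)); g2 <- mk_grid(matrix(2, 3, 3))
  s <- grid_stack(list(g1, g2), years = c(2001, 2002))
  expect_equal(stack_size(s), 2)
  expect_equal(stack_layer(s, 2)$values, g2$values)
  expect_error(grid_stack(list(g1, mk_grid(matrix(1, 2, 2))),
                          years = c(2001, 2002)), "share shape")
  expect_error(grid_stack(list(g1, g2), years = c(2002, 2001)),
               "strictly increasing")
})
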