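# Synthetic closed-basin scenes with known ground truth.
#
# The generator states a world resembling a high, closed mountain basin:
# elevation falling NW -> SE, temperature decreasing with elevation by a lapse
# rate, precipitation increasing with elevation, a monthly vegetation-index
# (EVI) signal with a summer-peaked seasonal harmonic, a per-pixel linear
# trend, driver-dependent baselines and white noise. Every downstream stage is
# tested by recovering these planted quantities.

# stable child-seed derivation so stages are reproducible in isolation;
# kept below 2^31 - 1
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# running mean along each column, window ~L cells, edge-normalised
runmean_col <- function(m, L) {
  h <- max(1L, as.integer(floor(L / 2)))
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# smooth standard-normal random field: white noise blurred by a separable
# moving average (two passes), then re-standardised
smooth_field <- function(nr, nc, L, passes = 2) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  for (p in seq_len(passes)) {
    f <- runmean_col(f, L)
    f <- t(runmean_col(t(f), L))
  }
  (f - mean(f)) / sd(as.vector(f))
}

#' Configuration of a synthetic basin scene
#'
#' Bundles every tunable of the scene generator with field-realistic defaults:
#' a 100 x 100 grid of 250 m cells over 22 years (monthly vegetation-index
#' steps), an elevation range matching a high closed basin (3173-5279 m), a
#' 0.006 degC/m lapse rate, elevation-increasing precipitation, and an EVI
#' signal of baseline + seasonal harmonic + planted linear trend + climate
#' anomalies + noise (sd 0.02).
#'
#' @param shape Integer `(rows, cols)` of the scene grid.
#' @param cell_size Cell size in metres (also the nominal area base).
#' @param years Inclusive vector of years (span must be at least 3).
#' @param seed Integer master seed; fixed seed implies byte-identical scenes.
#' @param dem_params List: `relief_amp` (m, amplitude of the smooth random
#'   relief), `smooth` (smoothing length, cells), `clip` (elevation range, m).
#' @param climate_params List: `t_sea_level` (degC), `lapse` (degC/m),
#'   `precip_base` (mm), `precip_elev_coef` (mm/m), `precip_elev_quad`
#'   (mm/m^2, optional mid-elevation optimum), `interannual_sd_t`/`_p`
#'   (year-effect sd), `noise_sd_t`/`_p` (per-cell sd).
#' @param evi_params List: `baseline`, `seasonal_amp`, `trend` (list with
#'   `type` in none/constant/block/elevation_low/matrix, `value` in EVI units
#'   per year), `temp_coef`, `precip_coef` (per standardised anomaly),
#'   `noise_sd`, `landuse_effect` (half-spread of land-use class means),
#'   `spatial_sd` (sd of the smooth baseline field).
#' @param categorical_params List: `n_landuse`, `n_soil`, `patch_smooth`
#'   (patch smoothing length, cells).
#' @param sixteen_day If `TRUE`, each month carries two compositing periods
#'   with independent noise so maximum-value compositing is exercised.
#' @return A list of class `fvc_scene_config`.
#' @export
scene_config <- function(shape = c(100, 100), cell_size = 250,
                         years = 2001:2022, seed = 1,
                         dem_params = list(), climate_params = list(),
                         evi_params = list(), categorical_params = list(),
                         sixteen_day = FALSE) {
  merge_defaults <- function(user, def) { def[names(user)] <- user; def }
  cfg <- list(
    shape = as.integer(shape), cell_size = cell_size,
    years = as.integer(years), seed = as.integer(seed),
    sixteen_day = isTRUE(sixteen_day),
    dem_params = merge_defaults(dem_params, list(
      relief_amp = 300, smooth = 12, clip = c(3173, 5279))),
    climate_params = merge_defaults(climate_params, list(
      t_sea_level = 20, lapse = 0.006,
      precip_base = 100, precip_elev_coef = 0.08, precip_elev_quad = 0,
      interannual_sd_t = 0.5, interannual_sd_p = 25,
      noise_sd_t = 0.3, noise_sd_p = 15)),
    evi_params = merge_defaults(evi_params, list(
      baseline = 0.45, seasonal_amp = 0.15,
      trend = list(type = "block", value = 0.002),
      temp_coef = 0.02, precip_coef = 0.03, noise_sd = 0.02,
      landuse_effect = 0.15, spatial_sd = 0.04)),
    categorical_params = merge_defaults(categorical_params, list(
      n_landuse = 5, n_soil = 4, patch_smooth = 10)))
  if (length(cfg$years) < 3) stop("year span must be at least 3")
  sds <- c(cfg$climate_params$interannual_sd_t, cfg$climate_params$interannual_sd_p,
           cfg$climate_params$noise_sd_t, cfg$climate_params$noise_sd_p,
           cfg$evi_params$noise_sd, cfg$evi_params$spatial_sd)
  if (any(sds < 0)) stop("all standard deviations must be non-negative")
  class(cfg) <- "fvc_scene_config"
  cfg
}

scene_transform <- function(config) {
  list(x0 = 0, y0 = (config$shape[1] - 1) * config$cell_size,
       dx = config$cell_size, dy = config$cell_size)
}

#' Generate the scene DEM
#'
#' Smooth random relief plus a directional ramp (high in the northwest, low in
#' the southeast), rescaled and clipped to the configured elevation range.
#' Deterministic under the config seed.
#'
#' @param config A [scene_config()].
#' @return Elevation `fvc_grid` in metres.
#' @export
generate_dem <- function(config) {
  nr <- config$shape[1]; nc <- config$shape[2]
  p <- config$dem_params
  set.seed(derive_seed(config$seed, "dem"))
  ramp <- outer(seq(nr, 1), seq(nc, 1), "+")       # large in NW corner
  ramp01 <- (ramp - min(ramp)) / (max(ramp) - min(ramp))
  lo <- p$clip[1]; hi <- p$clip[2]
  base <- lo + (hi - lo) * (0.1 + 0.8 * ramp01)
  relief <- if (p$relief_amp > 0) p$relief_amp * smooth_field(nr, nc, p$smooth) else 0
  dem <- pmin(pmax(base + relief, lo), hi)
  new_grid(dem, scene_transform(config), units = "m")
}

#' Generate per-year temperature and precipitation stacks
#'
#' Temperature: sea-level temperature minus lapse x elevation, plus a yearly
#' basin-wide effect and cell noise. Precipitation: base plus a (possibly
#' signed, optionally quadratic) elevation term, yearly effect and noise,
#' floored at zero.
#'
#' @param dem Elevation grid from [generate_dem()].
#' @param config A [scene_config()].
#' @return List with `temperature` and `precipitation` annual `fvc_gridstack`s.
#' @export
generate_climate <- function(dem, config) {
  p <- config$climate_params
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  ny <- length(config$years)
  set.seed(derive_seed(config$seed, "climate"))
  eff_t <- rnorm(ny, 0, p$interannual_sd_t)
  eff_p <- rnorm(ny, 0, p$interannual_sd_p)
  Tarr <- array(NA_real_, c(nr, nc, ny))
  Parr <- array(NA_real_, c(nr, nc, ny))
  e <- dem$values
  for (y in seq_len(ny)) {
    Tarr[, , y] <- p$t_sea_level - p$lapse * e + eff_t[y] +
      if (p$noise_sd_t > 0) matrix(rnorm(nr * nc, 0, p$noise_sd_t), nr, nc) else 0
    pr <- p$precip_base + p$precip_elev_coef * e + p$precip_elev_quad * e^2 +
      eff_p[y] +
      if (p$noise_sd_p > 0) matrix(rnorm(nr * nc, 0, p$noise_sd_p), nr, nc) else 0
    Parr[, , y] <- pmax(pr, 0)
  }
  tr <- dem$transform
  list(temperature = grid_stack(Tarr, years = config$years, transform = tr,
                                units = "degC"),
       precipitation = grid_stack(Parr, years = config$years, transform = tr,
                                  units = "mm"))
}

#' Generate a spatially autocorrelated categorical layer
#'
#' Thresholds a smoothed random field at its empirical quantiles so the
#' `n_classes` labels occupy roughly equal, spatially contiguous shares.
#'
#' @param config A [scene_config()].
#' @param n_classes Number of classes (at least 2).
#' @param seed_offset Tag mixed into the child seed so multiple categorical
#'   layers of one scene differ.
#' @param labels Optional class labels.
#' @return An `fvc_classified` grid.
#' @export
generate_categorical <- function(config, n_classes, seed_offset = 0,
                                 labels = paste0("class_", seq_len(n_classes))) {
  if (n_classes < 2) stop("n_classes must be at least 2")
  nr <- config$shape[1]; nc <- config$shape[2]
  if (n_classes > nr * nc) stop("n_classes exceeds cell count")
  set.seed(derive_seed(config$seed, paste0("categorical", seed_offset)))
  f <- smooth_field(nr, nc, config$categorical_params$patch_smooth)
  qs <- quantile(as.vector(f), probs = seq_len(n_classes - 1) / n_classes,
                 type = 7)
  codes <- matrix(findInterval(f, qs) + 1L, nr, nc)
  # quantile thresholding guarantees every class non-empty for continuous fields
  new_classified_grid(codes, labels, scene_transform(config))
}

trend_field <- function(config, dem) {
  tp <- config$evi_params$trend
  nr <- config$shape[1]; nc <- config$shape[2]
  tau <- matrix(0, nr, nc)
  if (is.matrix(tp$type) || identical(tp$type, "matrix")) {
    tau <- if (is.matrix(tp$type)) tp$type else tp$value
  } else if (identical(tp$type, "constant")) {
    tau[] <- tp$value
  } else if (identical(tp$type, "block")) {
    tau[seq_len(floor(nr / 2)), seq_len(floor(nc / 2))] <- tp$value
  } else if (identical(tp$type, "elevation_low")) {
    tau[dem$values < 3500] <- tp$value
  } else if (!identical(tp$type, "none")) {
    stop("unknown trend field type: ", tp$type)
  }
  tau
}

#' Generate the monthly EVI series
#'
#' Per pixel, year and month:
#' `EVI = clip(b + a * seasonal(month) + tau * (year - year_1) +
#' c_T * Tanom + c_P * Panom + noise, 0, 1)`, where `b` is the driver-dependent
#' baseline (land-use class mean + smooth field), `tau` the planted trend
#' field, and the climate anomalies are standardised per pixel across years.
#' In 16-day mode each month carries two periods with independent noise.
#'
#' @param scene Partial scene list with `dem`, `temperature`, `precipitation`
#'   and `landuse` already generated.
#' @param config A [scene_config()].
#' @return List with `evi` (`fvc_gridstack`, monthly or 16-day) and `truth`
#'   (planted trend field, coefficients, baseline field, class means).
#' @export
generate_evi_series <- function(scene, config) {
  p <- config$evi_params
  nr <- config$shape[1]; nc <- config$shape[2]
  years <- config$years; ny <- length(years)
  set.seed(derive_seed(config$seed, "evi"))
  n_lu <- config$categorical_params$n_landuse
  lu_means <- seq(-p$landuse_effect, p$landuse_effect, length.out = n_lu)
  baseline <- p$baseline + lu_means[scene$landuse$values] +
    if (p$spatial_sd > 0) p$spatial_sd * smooth_field(nr, nc, 8) else 0
  baseline <- matrix(baseline, nr, nc)
  tau <- trend_field(config, scene$dem)

  # standardised, trend-free climate anomalies: the per-pixel linear-in-year
  # component is removed so the planted tau is, by construction, the series'
  # only linear trend (see the methods vignette)
  std_anom <- function(stk) {
    d <- stk$data
    nt <- dim(d)[3]
    M <- matrix(d, ncol = nt)
    m <- rowMeans(M)
    M <- M - m
    cy <- seq_len(nt) - mean(seq_len(nt))
    beta <- as.vector(M %*% cy) / sum(cy^2)
    M <- M - outer(beta, cy)
    s <- sqrt(rowSums(M^2) / (nt - 1))
    s[s == 0] <- 1
    array(M / s, dim = dim(d))
  }
  Ta <- std_anom(scene$temperature)
  Pa <- std_anom(scene$precipitation)

  months <- 1:12
  n_periods <- if (config$sixteen_day) 2L else 1L
  nt <- ny * 12L * n_periods
  data <- array(NA_real_, c(nr, nc, nt))
  yy <- integer(nt); mm <- integer(nt); pp <- integer(nt)
  k <- 0L
  for (y in seq_len(ny)) {
    for (mo in months) {
      seas <- p$seasonal_amp * cos(2 * pi * (mo - 7) / 12)
      mu <- baseline + seas + tau * (years[y] - years[1]) +
        p$temp_coef * Ta[, , y] + p$precip_coef * Pa[, , y]
      for (per in seq_len(n_periods)) {
        k <- k + 1L
        noise <- if (p$noise_sd > 0) matrix(rnorm(nr * nc, 0, p$noise_sd), nr, nc) else 0
        data[, , k] <- pmin(pmax(mu + noise, 0), 1)
        yy[k] <- years[y]; mm[k] <- mo; pp[k] <- per
      }
    }
  }
  evi <- grid_stack(data, years = yy, months = mm,
                    periods = if (config$sixteen_day) pp else NA,
                    transform = scene_transform(config), units = "EVI")
  list(evi = evi,
       truth = list(tau = tau, trend_mask = tau != 0,
                    temp_coef = p$temp_coef, precip_coef = p$precip_coef,
                    baseline = baseline, landuse_means = lu_means,
                    seasonal_amp = p$seasonal_amp))
}

#' Generate a complete synthetic scene
#'
#' Composes DEM, slope/aspect, climate stacks, land-use and soil-type
#' categorical layers, continuous soil-organic-carbon / grazing / population
#' layers, and the monthly EVI series, all co-registered, with a `truth`
#' record sufficient to score parameter recovery. Fully deterministic under
#' the config seed.
#'
#' @param config A [scene_config()].
#' @return A list of class `fvc_scene` with all layers and `truth`.
#' @export
generate_scene <- function(config = scene_config()) {
  dem <- generate_dem(config)
  sa <- slope_aspect(dem)
  climate <- generate_climate(dem, config)
  landuse <- generate_categorical(config, config$categorical_params$n_landuse,
                                  seed_offset = 1,
                                  labels = c("grassland", "meadow", "shrubland",
                                             "bare_land", "wetland")[
                                               seq_len(config$categorical_params$n_landuse)])
  soil <- generate_categorical(config, config$categorical_params$n_soil,
                               seed_offset = 2,
                               labels = paste0("soil_", seq_len(config$categorical_params$n_soil)))
  nr <- config$shape[1]; nc <- config$shape[2]
  tr <- scene_transform(config)
  set.seed(derive_seed(config$seed, "surfaces"))
  # SOC declines with elevation; grazing and population are smooth fields
  soc <- new_grid(60 - 0.008 * dem$values + 3 * smooth_field(nr, nc, 8),
                  tr, units = "g/kg")
  grazing <- new_grid(matrix(pmax(0, 1 + 0.5 * smooth_field(nr, nc, 12)),
                             nr, nc), tr, units = "sheep_units")
  popdensity <- new_grid(matrix(pmax(0, 5 + 3 * smooth_field(nr, nc, 15)),
                                nr, nc), tr, units = "persons/km2")
  scene <- list(dem = dem, slope = sa$slope, aspect = sa$aspect,
                temperature = climate$temperature,
                precipitation = climate$precipitation,
                landuse = landuse, soil_type = soil,
                soc = soc, grazing = grazing, popdensity = popdensity)
  ev <- generate_evi_series(scene, config)
  scene$evi_monthly <- ev$evi
  scene$truth <- ev$truth
  scene$config <- config
  class(scene) <- "fvc_scene"
  scene
}

#' Write scene layers as CSV-dialect fixtures
#'
#' Static layers, the per-year climate stacks, the EVI series (one file per
#' time step) and the planted-trend truth table, all in the plain-text grid
#' dialect so a scene can round-trip through [read_scene()].
#'
#' @param scene A scene from [generate_scene()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("dem", "slope", "aspect", "soc", "grazing", "popdensity",
               "landuse", "soil_type"))
    write_grid(scene[[nm]], file.path(dir, paste0(nm, ".csv")))
  writeLines(scene$landuse$labels, file.path(dir, "landuse_labels.txt"))
  writeLines(scene$soil_type$labels, file.path(dir, "soil_type_labels.txt"))
  for (stk_nm in c("temperature", "precipitation")) {
    stk <- scene[[stk_nm]]
    for (i in seq_len(stack_size(stk)))
      write_grid(stack_layer(stk, i),
                 file.path(dir, sprintf("%s_%d.csv", stk_nm, stk$times$year[i])))
  }
  evi <- scene$evi_monthly
  for (i in seq_len(stack_size(evi))) {
    per <- evi$times$period[i]
    fn <- if (is.na(per))
      sprintf("evi_%d_%02d.csv", evi$times$year[i], evi$times$month[i])
    else sprintf("evi_%d_%02d_%d.csv", evi$times$year[i], evi$times$month[i], per)
    write_grid(stack_layer(evi, i), file.path(dir, fn))
  }
  truth <- data.frame(pixel = seq_along(scene$truth$tau),
                      tau = as.vector(scene$truth$tau))
  write.csv(truth, file.path(dir, "truth_trend.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir Scene directory.
#' @return A list of class `fvc_scene` (the `truth` record carries the
#'   planted trend field only).
#' @export
read_scene <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("scene layer missing: ", p)
    p
  }
  scene <- list()
  for (nm in c("dem", "slope", "aspect", "soc", "grazing", "popdensity"))
    scene[[nm]] <- read_grid(need(paste0(nm, ".csv")))
  for (nm in c("landuse", "soil_type")) {
    g <- read_grid(need(paste0(nm, ".csv")))
    labels <- readLines(need(paste0(nm, "_labels.txt")))
    scene[[nm]] <- new_classified_grid(g$values, labels, g$transform, g$mask)
  }
  read_stack <- function(pattern, parse) {
    files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    if (!length(files)) stop("no layers matching ", pattern, " in ", dir)
    meta <- do.call(rbind, lapply(basename(files), parse))
    ord <- do.call(order, as.data.frame(meta))
    grid_stack(lapply(files[ord], read_grid),
               years = meta[ord, 1], months = meta[ord, 2],
               periods = meta[ord, 3])
  }
  scene$temperature <- read_stack("^temperature_[0-9]+\\.csv$", function(f)
    c(as.integer(sub("temperature_([0-9]+)\\.csv", "\\1", f)), NA, NA))
  scene$precipitation <- read_stack("^precipitation_[0-9]+\\.csv$", function(f)
    c(as.integer(sub("precipitation_([0-9]+)\\.csv", "\\1", f)), NA, NA))
  scene$evi_monthly <- read_stack("^evi_[0-9_]+\\.csv$", function(f) {
    parts <- as.integer(strsplit(sub("^evi_", "", sub("\\.csv$", "", f)), "_")[[1]])
    c(parts[1], parts[2], if (length(parts) > 2) parts[3] else NA)
  })
  tpath <- file.path(dir, "truth_trend.csv")
  if (file.exists(tpath)) {
    tt <- read.csv(tpath)
    scene$truth <- list(tau = matrix(tt$tau, nrow(scene$dem$values)))
  }
  scene$config <- list(cell_size = scene$dem$transform$dx,
                       years = sort(unique(scene$evi_monthly$times$year)))
  class(scene) <- "fvc_scene"
  scene
}

# ---------------------------------------------------------------------------
# Synthetic indicator data for PLS path modelling
# ---------------------------------------------------------------------------

#' Simulate indicator data from a known PLS path model
#'
#' Latents are generated in topological order with unit variance (endogenous
#' disturbances scaled accordingly). Indicators carry the requested loadings;
#' in the default `"composite"` mode the block noise is constructed orthogonal
#' to the block's weight vector, so each block's composite equals the
#' structural latent exactly and the planted paths and loadings are the PLS
#' estimands (mode-A PLS is consistent in this world). In `"factor"` mode the
#' indicators follow the common-factor model
#' `loading * latent + sqrt(1 - loading^2) * noise`, for which composite-based
#' estimates show the well-known attenuation (see the methods vignette). The
#' default model is the 4-block chain A -> B (0.5), B -> C (-0.4),
#' C -> D (0.3) with two indicators per block loading 0.8.
#'
#' @param n Number of observations.
#' @param spec A [pls_model_spec()]; defaults to the 4-block chain.
#' @param loadings Named list (per latent) of indicator loadings, or a single
#'   number recycled everywhere. Composite mode requires equal loadings
#'   within a block.
#' @param path_values Named vector of true path coefficients, names
#'   `"source->target"`; or a single number recycled.
#' @param seed Integer seed.
#' @param sim_mode `"composite"` (PLS-consistent, default) or `"factor"`.
#' @return List with `data` (data frame of indicators), `spec`, and `truth`
#'   (loadings and path coefficients used).
#' @export
simulate_pls_data <- function(n = 2000, spec = NULL, loadings = 0.8,
                              path_values = NULL, seed = 1,
                              sim_mode = c("composite", "factor")) {
  sim_mode <- match.arg(sim_mode)
  if (is.null(spec)) {
    spec <- pls_model_spec(
      blocks = list(A = c("a1", "a2"), B = c("b1", "b2"),
                    C = c("c1", "c2"), D = c("d1", "d2")),
      paths = rbind(c("A", "B"), c("B", "C"), c("C", "D")))
    if (is.null(path_values)) path_values <- c("A->B" = 0.5, "B->C" = -0.4,
                                               "C->D" = 0.3)
  }
  lat <- names(spec$blocks)
  P <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  keys <- paste0(spec$paths[, 1], "->", spec$paths[, 2])
  if (is.null(path_values)) path_values <- stats::setNames(rep(0.4, length(keys)), keys)
  if (length(path_values) == 1 && is.null(names(path_values)))
    path_values <- stats::setNames(rep(path_values, length(keys)), keys)
  P[spec$paths] <- path_values[keys]
  set.seed(seed)
  ord <- topo_order(spec$paths, lat)
  scores <- matrix(NA_real_, n, length(lat), dimnames = list(NULL, lat))
  for (l in ord) {
    parents <- lat[P[, l] != 0]
    if (!length(parents)) {
      scores[, l] <- rnorm(n)
    } else {
      mu <- scores[, parents, drop = FALSE] %*% P[parents, l]
      vres <- 1 - stats::var(as.vector(mu)) * (n - 1) / n
      vres <- max(vres, 0.05)
      scores[, l] <- mu + rnorm(n, 0, sqrt(vres))
    }
    scores[, l] <- (scores[, l] - mean(scores[, l])) / sd(scores[, l])
  }
  cols <- list(); lam <- list()
  for (l in lat) {
    k <- length(spec$blocks[[l]])
    lds <- if (is.list(loadings)) loadings[[l]] else rep(loadings, k)
    lam[[l]] <- lds
    if (sim_mode == "composite") {
      if (k == 1) {
        lam[[l]] <- 1          # a single indicator is its own composite
        cols[[spec$blocks[[l]]]] <- scores[, l]
        next
      }
      if (diff(range(lds)) > 1e-12)
        stop("composite mode requires equal loadings within a block")
      lambda <- lds[1]
      # row-centred noise: the equal-weight composite of the block equals the
      # structural latent exactly, so planted paths are the PLS estimand
      E <- matrix(rnorm(n * k), n, k)
      E <- E - rowMeans(E)
      E <- E * sqrt((1 - lambda^2) / (1 - 1 / k))
      for (j in seq_len(k))
        cols[[spec$blocks[[l]][j]]] <- lambda * scores[, l] + E[, j]
    } else {
      for (j in seq_len(k))
        cols[[spec$blocks[[l]][j]]] <-
          lds[j] * scores[, l] + sqrt(1 - lds[j]^2) * rnorm(n)
    }
  }
  list(data = as.data.frame(cols), spec = spec,
       truth = list(loadings = lam, paths = P, scores = scores))
}
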