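# Terrain stratification and the terrain distribution (dominance) index:
# fixed elevation/slope/aspect class schemes, exact Jenks natural breaks, and
# K = (S_ie / S_e) / (S_i / S) per change type and stratum.

#' Jenks natural breaks (exact Fisher optimal classification)
#'
#' Exact dynamic-programming minimisation of the total within-class sum of
#' squared deviations over the sorted sample — the "natural breakpoint"
#' discretisation. Deterministic; the optimal objective is attached as the
#' `"objective"` attribute.
#'
#' @param values Numeric vector (NAs dropped).
#' @param n_classes Number of classes.
#' @return Numeric vector of the `n_classes - 1` interior break values (upper
#'   edge of each class but the last, as data values).
#' @export
jenks_breaks <- function(values, n_classes) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < n_classes)
    stop("need at least n_classes distinct values")
  .jenks_cpp(v, as.integer(n_classes))
}

# strata codes from interior break values: class k covers (b_{k-1}, b_k]
jenks_assign <- function(values, breaks) {
  findInterval(values, breaks, left.open = TRUE) + 1L
}

#' Terrain classification scheme
#'
#' The three fixed stratification schemes:
#' \describe{
#'   \item{elevation}{low (<3500 m), middle-low (3500-3800), middle
#'     (3800-4200), high (>4200); lower-edge-inclusive.}
#'   \item{slope}{flat (0-3 deg), gently sloping (3-7), sloping (7-12),
#'     steeply sloping (12-18), sharply sloping (>18).}
#'   \item{aspect}{flat (-1), shaded (\[0,67.5) and \[337.5,360)), semishaded
#'     (\[67.5,112.5) and \[292.5,337.5)), semipositive (\[112.5,157.5) and
#'     \[247.5,292.5)), sunny (\[157.5,247.5)); symmetric half-degree windows,
#'     lower-inclusive.}
#' }
#'
#' @param variable `"elevation"`, `"slope"` or `"aspect"`.
#' @param edges Optional replacement numeric edges (elevation/slope only),
#'   interior edges in increasing order.
#' @param labels Optional replacement labels (must match the class count).
#' @return List of class `fvc_terrain_scheme`.
#' @export
terrain_scheme <- function(variable = c("elevation", "slope", "aspect"),
                           edges = NULL, labels = NULL) {
  variable <- match.arg(variable)
  sch <- switch(variable,
    elevation = list(edges = c(3500, 3800, 4200),
                     labels = c("low_elevation", "middle_low_elevation",
                                "middle_elevation", "high_elevation")),
    slope = list(edges = c(3, 7, 12, 18),
                 labels = c("flat", "gently_sloping", "sloping",
                            "steeply_sloping", "sharply_sloping")),
    aspect = list(edges = NULL,
                  labels = c("flat", "shaded", "semishaded", "semipositive",
                             "sunny")))
  if (!is.null(edges)) {
    if (variable == "aspect") stop("aspect windows are fixed by convention")
    sch$edges <- sort(edges)
    if (is.null(labels)) sch$labels <- paste0(variable, "_class_",
                                              seq_len(length(sch$edges) + 1))
  }
  if (!is.null(labels)) {
    need <- if (variable == "aspect") 5 else length(sch$edges) + 1
    if (length(labels) != need) stop("label count does not match class count")
    sch$labels <- labels
  }
  structure(c(list(variable = variable), sch), class = "fvc_terrain_scheme")
}

aspect_class <- function(a) {
  cls <- rep(NA_integer_, length(a))
  cls[a == -1] <- 1L
  ok <- is.finite(a) & a >= 0 & a < 360
  cls[ok & ((a >= 0 & a < 67.5) | (a >= 337.5))] <- 2L
  cls[ok & ((a >= 67.5 & a < 112.5) | (a >= 292.5 & a < 337.5))] <- 3L
  cls[ok & ((a >= 112.5 & a < 157.5) | (a >= 247.5 & a < 292.5))] <- 4L
  cls[ok & (a >= 157.5 & a < 247.5)] <- 5L
  cls
}

#' Classify a terrain variable grid into strata
#'
#' @param grid Elevation (m), slope (deg) or aspect (deg, -1 = flat)
#'   `fvc_grid`.
#' @param scheme A [terrain_scheme()] matching the variable.
#' @return An `fvc_classified` grid.
#' @export
classify_terrain <- function(grid, scheme) {
  v <- grid$values
  if (scheme$variable == "aspect") {
    bad <- !grid$mask & is.finite(v) & !(v == -1 | (v >= 0 & v < 360))
    if (any(bad)) stop("aspect values outside [-1, 360)")
    codes <- matrix(aspect_class(v), nrow(v))
  } else {
    if (scheme$variable == "slope" &&
        any(!grid$mask & is.finite(v) & (v < 0 | v > 90)))
      stop("slope values outside [0, 90]")
    codes <- matrix(findInterval(v, scheme$edges) + 1L, nrow(v))
  }
  codes[grid$mask] <- NA_integer_
  new_classified_grid(codes, scheme$labels, grid$transform, grid$mask,
                      crs_tag = grid$crs_tag)
}

#' Terrain distribution (dominance) index table
#'
#' For every change type `i` and terrain stratum `e`,
#' `K = (S_ie / S_e) / (S_i / S)`: the change type's area share inside the
#' stratum relative to its basin-wide share. `K > 1` marks dominance of the
#' type in that stratum, `K = 1` an even distribution, `K < 1` under-
#' representation. Rows with `S_e = 0` or `S_i = 0` carry `K = NA`.
#'
#' @param change An `fvc_classified` change-type grid.
#' @param terrain An `fvc_classified` terrain-stratum grid, co-registered.
#' @param cell_area_km2 Nominal cell area.
#' @return Data frame with `change_type`, `terrain_class`, `S_ie`, `S_e`,
#'   `S_i`, `S` (km^2) and `K`.
#' @export
terrain_distribution_index <- function(change, terrain,
                                       cell_area_km2 = 0.0625) {
  if (!identical(dim(change$values), dim(terrain$values)) ||
      !same_geometry(change, terrain))
    stop("change and terrain grids are not co-registered")
  keep <- !change$mask & !terrain$mask
  ci <- factor(change$values[keep], levels = seq_along(change$labels))
  te <- factor(terrain$values[keep], levels = seq_along(terrain$labels))
  tab <- unclass(table(ci, te)) * cell_area_km2
  S <- sum(tab)
  S_i <- rowSums(tab); S_e <- colSums(tab)
  out <- expand.grid(change_type = change$labels,
                     terrain_class = terrain$labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$S_ie <- as.vector(tab)
  out$S_e <- S_e[match(out$terrain_class, terrain$labels)]
  out$S_i <- S_i[match(out$change_type, change$labels)]
  out$S <- S
  out$K <- ifelse(out$S_e > 0 & out$S_i > 0,
                  (out$S_ie / out$S_e) / (out$S_i / out$S), NA_real_)
  out
}

#' Collapse the five trend classes to degraded / stable / improved
#'
#' The terrain dominance analysis uses three change types; this maps the
#' five-class trend typology onto them (both improvement classes to improved,
#' both degradation classes to degraded).
#'
#' @param trend_class An `fvc_classified` five-class trend map.
#' @return An `fvc_classified` grid with classes degraded / stable / improved.
#' @export
collapse_trend_classes <- function(trend_class) {
  map <- c(3L, 3L, 2L, 1L, 1L)   # sig/insig improvement -> improved, etc.
  v <- matrix(map[trend_class$values], nrow(trend_class$values))
  new_classified_grid(v, c("degraded", "stable", "improved"),
                      trend_class$transform, trend_class$mask,
                      crs_tag = trend_class$crs_tag)
}
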