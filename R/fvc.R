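# Fractional vegetation cover from a vegetation-index series:
# maximum-value compositing, annual aggregation, percentile endmembers and the
# dimidiate pixel model, then five-grade classification.

#' Maximum-value composite to monthly resolution
#'
#' Collapses multiple compositing periods per (year, month) to their per-pixel
#' maximum — the standard suppression of cloud/atmosphere artifacts in
#' vegetation-index series. A composited cell is masked only where every
#' contributing period is masked.
#'
#' @param evi_periods An `fvc_gridstack` with at least one period per
#'   (year, month).
#' @return A monthly `fvc_gridstack`.
#' @export
monthly_composite <- function(evi_periods) {
  if (stack_size(evi_periods) < 1) stop("empty stack")
  key <- paste(evi_periods$times$year, evi_periods$times$month, sep = "-")
  groups <- split(seq_len(stack_size(evi_periods)), factor(key, unique(key)))
  dims <- dim(evi_periods$data)
  out <- array(NA_real_, c(dims[1], dims[2], length(groups)))
  yy <- integer(length(groups)); mm <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    d <- evi_periods$data[, , idx, drop = FALSE]
    d[evi_periods$mask[, , idx, drop = FALSE]] <- NA_real_
    M <- matrix(d, dims[1] * dims[2], length(idx))
    mx <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE),
                 lapply(seq_len(ncol(M)), function(j) M[, j]))
    out[, , g] <- matrix(mx, dims[1], dims[2])
    yy[g] <- evi_periods$times$year[idx[1]]
    mm[g] <- evi_periods$times$month[idx[1]]
  }
  grid_stack(out, years = yy, months = mm, transform = evi_periods$transform,
             units = evi_periods$units, crs_tag = evi_periods$crs_tag)
}

#' Annual mean of a monthly stack
#'
#' Per-pixel arithmetic mean over the months available for `year`; a cell's
#' masked months are simply dropped from its mean.
#'
#' @param monthly A monthly `fvc_gridstack`.
#' @param year Year to aggregate.
#' @return An `fvc_grid`.
#' @export
annual_mean_evi <- function(monthly, year) {
  idx <- which(monthly$times$year == year)
  if (!length(idx)) stop("no months present for year ", year)
  d <- monthly$data[, , idx, drop = FALSE]
  d[monthly$mask[, , idx, drop = FALSE]] <- NA_real_
  nr <- dim(d)[1]; nc <- dim(d)[2]
  m <- rowMeans(matrix(d, nr * nc, length(idx)), na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  new_grid(matrix(m, nr, nc), monthly$transform, units = monthly$units,
           crs_tag = monthly$crs_tag)
}

#' Annual maximum of a monthly stack
#'
#' Alternative annualisation that takes the yearly per-pixel maximum instead
#' of the mean (see the methods vignette for when each is appropriate).
#'
#' @inheritParams annual_mean_evi
#' @return An `fvc_grid`.
#' @export
annual_max_evi <- function(monthly, year) {
  idx <- which(monthly$times$year == year)
  if (!length(idx)) stop("no months present for year ", year)
  d <- monthly$data[, , idx, drop = FALSE]
  d[monthly$mask[, , idx, drop = FALSE]] <- NA_real_
  nr <- dim(d)[1]; nc <- dim(d)[2]
  M <- matrix(d, nr * nc, length(idx))
  m <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE),
              lapply(seq_len(ncol(M)), function(j) M[, j]))
  new_grid(matrix(m, nr, nc), monthly$transform, units = monthly$units,
           crs_tag = monthly$crs_tag)
}

#' Estimate pure-soil and pure-vegetation endmembers
#'
#' The dimidiate pixel model needs the index values of a fully bare and a
#' fully vegetated pixel. Following the cumulative-frequency convention, they
#' are taken as the 0.5 % and 99.5 % empirical quantiles (linear interpolation
#' between order statistics) of the unmasked index values.
#'
#' @param evi An index `fvc_grid` (typically an annual mean).
#' @param soil_percentile,veg_percentile Cumulative percentages in (0, 100).
#' @return List of class `fvc_endmembers` with `evi_soil`, `evi_veg` and the
#'   percentiles used.
#' @export
estimate_endmembers <- function(evi, soil_percentile = 0.5,
                                veg_percentile = 99.5) {
  if (soil_percentile <= 0 || veg_percentile >= 100 ||
      soil_percentile >= veg_percentile)
    stop("percentiles must satisfy 0 < soil < veg < 100")
  v <- grid_values(evi)
  if (!length(v)) stop("all cells are masked")
  if (length(v) < 200)
    warning("fewer than 200 unmasked cells; endmember quantiles are unstable")
  qs <- quantile(v, probs = c(soil_percentile, veg_percentile) / 100,
                 type = 7, names = FALSE)
  if (qs[1] >= qs[2])
    stop("degenerate index distribution: soil and vegetation endmembers coincide")
  structure(list(evi_soil = qs[1], evi_veg = qs[2],
                 soil_percentile = soil_percentile,
                 veg_percentile = veg_percentile),
            class = "fvc_endmembers")
}

#' Fractional vegetation cover by the dimidiate pixel model
#'
#' `FVC = (EVI - EVI_soil) / (EVI_veg - EVI_soil)`, clipped to \[0, 1\]
#' (pixels beyond the percentile endmembers would otherwise fall outside the
#' physical range).
#'
#' @param evi An index `fvc_grid`.
#' @param endmembers An `fvc_endmembers` pair.
#' @return An FVC `fvc_grid` in \[0, 1\].
#' @export
estimate_fvc <- function(evi, endmembers) {
  fvc <- (evi$values - endmembers$evi_soil) /
    (endmembers$evi_veg - endmembers$evi_soil)
  fvc <- pmin(pmax(fvc, 0), 1)
  new_grid(fvc, evi$transform, evi$mask, units = "FVC", crs_tag = evi$crs_tag)
}

#' Five-grade FVC classification scheme
#'
#' @param edges Strictly increasing class edges covering \[0, 1\].
#' @param labels One label per bin.
#' @return List of class `fvc_grade_scheme`.
#' @export
fvc_grade_scheme <- function(edges = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                             labels = c("low", "medium_low", "medium",
                                        "medium_high", "high")) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (edges[1] != 0 || edges[length(edges)] != 1)
    stop("edges must cover [0, 1]")
  if (length(labels) != length(edges) - 1)
    stop("need one label per bin")
  structure(list(edges = edges, labels = labels), class = "fvc_grade_scheme")
}

#' Classify FVC into coverage grades
#'
#' Bins are lower-edge-inclusive (`[e_i, e_{i+1})`); the top bin is closed so
#' FVC = 1 lands in the highest grade.
#'
#' @param fvc An FVC `fvc_grid` with values in \[0, 1\].
#' @param scheme A [fvc_grade_scheme()].
#' @return An `fvc_classified` grade map.
#' @export
classify_fvc <- function(fvc, scheme = fvc_grade_scheme()) {
  v <- grid_values(fvc)
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("FVC values outside [0, 1]")
  k <- length(scheme$labels)
  codes <- matrix(findInterval(fvc$values, scheme$edges,
                               rightmost.closed = TRUE), nrow(fvc$values))
  codes[fvc$mask] <- NA_integer_
  codes[!fvc$mask & codes > k] <- k
  new_classified_grid(codes, scheme$labels, fvc$transform, fvc$mask,
                      crs_tag = fvc$crs_tag)
}

#' Annual FVC series from a (possibly multi-period) EVI stack
#'
#' Convenience chain: maximum-value composite to monthly, annualise (mean by
#' default, maximum optionally), estimate endmembers (per year, or pooled over
#' the whole record), and apply the dimidiate pixel model.
#'
#' @param evi_stack An `fvc_gridstack` of index values.
#' @param annualize `"mean"` or `"max"`.
#' @param endmember_scope `"per_year"` or `"pooled"`.
#' @param soil_percentile,veg_percentile Endmember percentiles.
#' @return List with `fvc` (annual `fvc_gridstack`), `endmembers` (data frame,
#'   one row per year) and `annual_evi` (annual index stack).
#' @export
fvc_series <- function(evi_stack, annualize = c("mean", "max"),
                       endmember_scope = c("per_year", "pooled"),
                       soil_percentile = 0.5, veg_percentile = 99.5) {
  annualize <- match.arg(annualize)
  endmember_scope <- match.arg(endmember_scope)
  monthly <- if (any(!is.na(evi_stack$times$period))) monthly_composite(evi_stack)
             else evi_stack
  years <- unique(monthly$times$year)
  agg <- if (annualize == "mean") annual_mean_evi else annual_max_evi
  annual <- lapply(years, function(y) agg(monthly, y))
  annual_stack <- grid_stack(annual, years = years)
  pooled_em <- NULL
  if (endmember_scope == "pooled") {
    all_v <- as.vector(annual_stack$data[!annual_stack$mask])
    g_all <- new_grid(matrix(all_v, nrow = 1), annual_stack$transform)
    pooled_em <- estimate_endmembers(g_all, soil_percentile, veg_percentile)
  }
  fvc_list <- vector("list", length(years))
  em_tab <- data.frame(year = years, evi_soil = NA_real_, evi_veg = NA_real_)
  for (i in seq_along(years)) {
    em <- if (is.null(pooled_em))
      estimate_endmembers(annual[[i]], soil_percentile, veg_percentile)
    else pooled_em
    em_tab$evi_soil[i] <- em$evi_soil
    em_tab$evi_veg[i] <- em$evi_veg
    fvc_list[[i]] <- estimate_fvc(annual[[i]], em)
  }
  list(fvc = grid_stack(fvc_list, years = years), endmembers = em_tab,
       annual_evi = annual_stack)
}
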