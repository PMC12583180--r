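# Per-pixel trend and stability analysis: Theil-Sen slope, Mann-Kendall
# significance, the five-class trend typology, coefficient of variation with
# five fluctuation classes, and lagged climate correlation maps.

#' Theil-Sen slope of a series
#'
#' Median of all pairwise slopes `(x_j - x_i) / (j - i)`, `i < j` — the robust
#' nonparametric trend estimator. Even pair counts take the mean of the two
#' central order statistics.
#'
#' @param series Numeric vector in time order (NAs dropped with their time
#'   index).
#' @param t Optional numeric time coordinates (defaults to `1..n`).
#' @return The slope in value units per time unit.
#' @export
theil_sen_slope <- function(series, t = seq_along(series)) {
  keep <- is.finite(series)
  x <- series[keep]; tt <- t[keep]
  n <- length(x)
  if (n < 3) stop("Theil-Sen slope needs at least 3 values")
  ij <- utils::combn(n, 2)
  median((x[ij[2, ]] - x[ij[1, ]]) / (tt[ij[2, ]] - tt[ij[1, ]]))
}

#' Mann-Kendall trend test statistics
#'
#' `S` counts concordant minus discordant later-vs-earlier pairs; the variance
#' is `n(n-1)(2n+5)/18`, optionally reduced by the tie correction
#' `sum t(t-1)(2t+5)/18` over tie groups; `Z` applies the +/-1 continuity
#' correction (`(S-1)/sqrt(Var)` for positive `S`, 0 at `S = 0`,
#' `(S+1)/sqrt(Var)` for negative `S`).
#'
#' @param series Numeric vector in time order.
#' @param tie_correction Apply the tie-group variance correction.
#' @return List with `S`, `VarS`, `Z`.
#' @export
mann_kendall <- function(series, tie_correction = FALSE) {
  x <- series[is.finite(series)]
  n <- length(x)
  if (n < 2) stop("Mann-Kendall test needs at least 2 values")
  if (n < 8) warning("Mann-Kendall normal approximation is weak below n = 8")
  ij <- utils::combn(n, 2)
  S <- sum(sign(x[ij[2, ]] - x[ij[1, ]]))
  VarS <- n * (n - 1) * (2 * n + 5) / 18
  if (tie_correction) {
    tg <- table(x)
    tg <- tg[tg > 1]
    if (length(tg)) VarS <- VarS - sum(tg * (tg - 1) * (2 * tg + 5)) / 18
  }
  Z <- if (S > 0) (S - 1) / sqrt(VarS) else if (S < 0) (S + 1) / sqrt(VarS) else 0
  if (VarS <= 0) Z <- 0
  list(S = as.integer(S), VarS = VarS, Z = Z)
}

#' Five-class trend typology
#'
#' Classifies a (slope, Z) pair into significant improvement
#' (`slope >= s0, |Z| >= z0`), insignificant improvement
#' (`slope >= s0, |Z| < z0`), stabilization (`|slope| < s0`), insignificant
#' degradation (`slope <= -s0, |Z| < z0`) or significant degradation
#' (`slope <= -s0, |Z| >= z0`). The residual cell (`|slope| < s0` with
#' `|Z| >= z0`) maps to stabilization.
#'
#' @param slope Theil-Sen slope(s), FVC units per year.
#' @param z Mann-Kendall Z statistic(s).
#' @param slope_threshold `s0`, default 0.0005 / a.
#' @param z_threshold `z0`, default 1.96 (two-sided 5 %).
#' @return Integer codes 1..5 with levels attribute `trend_classes()`.
#' @export
classify_trend <- function(slope, z, slope_threshold = 0.0005,
                           z_threshold = 1.96) {
  sig <- abs(z) >= z_threshold
  cls <- ifelse(slope >= slope_threshold, ifelse(sig, 1L, 2L),
         ifelse(slope <= -slope_threshold, ifelse(sig, 5L, 4L), 3L))
  cls[!is.finite(slope) | !is.finite(z)] <- NA_integer_
  structure(cls, levels = trend_classes())
}

#' Labels of the five trend classes, in code order
#' @return Character vector of length 5.
#' @export
trend_classes <- function() {
  c("significant_improvement", "insignificant_improvement", "stabilization",
    "insignificant_degradation", "significant_degradation")
}

#' Coefficient of variation of a series
#'
#' Sample standard deviation divided by the mean; undefined (NA) where the
#' mean does not exceed `eps`.
#'
#' @param series Numeric vector (NAs dropped).
#' @param eps Smallest admissible mean.
#' @return The dimensionless CV, or NA.
#' @export
coefficient_of_variation <- function(series, eps = 1e-12) {
  x <- series[is.finite(series)]
  if (length(x) < 2) stop("CV needs at least 2 values")
  m <- mean(x)
  if (m <= eps) return(NA_real_)
  sd(x) / m
}

#' Five-class fluctuation typology of the CV
#'
#' Stabilisation (CV < 0.07), slight (0.07-0.17), moderate (0.17-0.30), high
#' (0.30-0.50) and wild fluctuation (>= 0.50); bins lower-edge-inclusive.
#'
#' @param cv CV value(s), non-negative.
#' @return Integer codes 1..5 with levels attribute `cv_classes()`.
#' @export
classify_cv <- function(cv) {
  cls <- findInterval(cv, c(0.07, 0.17, 0.30, 0.50)) + 1L
  cls[!is.finite(cv)] <- NA_integer_
  structure(cls, levels = cv_classes())
}

#' Labels of the five fluctuation classes, in code order
#' @return Character vector of length 5.
#' @export
cv_classes <- function() {
  c("stabilisation", "slight_fluctuation", "moderate_fluctuation",
    "high_fluctuation", "wild_fluctuation")
}

# pairwise index pairs for an n-long series, cached per call site
pair_index <- function(n) utils::combn(n, 2)

#' Per-pixel trend analysis of an annual stack
#'
#' Vectorised Theil-Sen slope and Mann-Kendall test over every pixel of an
#' annual `fvc_gridstack`, plus the five-class typology. Pixels with fewer
#' than `min_n` unmasked years are masked (their count is reported).
#'
#' @param annual An annual `fvc_gridstack` (e.g. FVC per year).
#' @param slope_threshold,z_threshold Typology thresholds, see
#'   [classify_trend()].
#' @param tie_correction Use the tie-corrected Mann-Kendall variance.
#' @param min_n Minimum unmasked series length per pixel (>= 3).
#' @return List of class `fvc_trend_result`: grids `slope`, `s_stat`, `var_s`,
#'   `z`, classified grid `trend_class`, and `n_masked`.
#' @export
trend_analysis <- function(annual, slope_threshold = 0.0005,
                           z_threshold = 1.96, tie_correction = FALSE,
                           min_n = 3) {
  d <- annual$data
  d[annual$mask] <- NA_real_
  nr <- dim(d)[1]; nc <- dim(d)[2]; nt <- dim(d)[3]
  years <- annual$times$year
  X <- matrix(d, nr * nc, nt)            # pixels x years
  ok_n <- rowSums(is.finite(X))
  complete <- ok_n == nt
  slope <- rep(NA_real_, nr * nc)
  S <- rep(NA_real_, nr * nc)

  ij <- pair_index(nt)
  dt <- years[ij[2, ]] - years[ij[1, ]]
  if (any(complete)) {
    Xi <- X[complete, ij[1, ], drop = FALSE]
    Xj <- X[complete, ij[2, ], drop = FALSE]
    D <- sweep(Xj - Xi, 2, dt, "/")
    slope[complete] <- apply(D, 1, median)
    S[complete] <- rowSums(sign(Xj - Xi))
  }
  partial <- which(!complete & ok_n >= max(3, min_n))
  for (p in partial) {
    v <- X[p, ]
    slope[p] <- theil_sen_slope(v, years)
    keep <- is.finite(v)
    ijp <- utils::combn(sum(keep), 2)
    vv <- v[keep]
    S[p] <- sum(sign(vv[ijp[2, ]] - vv[ijp[1, ]]))
  }
  n_eff <- ifelse(complete, nt, ok_n)
  VarS <- n_eff * (n_eff - 1) * (2 * n_eff + 5) / 18
  if (tie_correction) {
    for (p in which(is.finite(S))) {
      tg <- table(X[p, ])
      tg <- tg[tg > 1]
      if (length(tg)) VarS[p] <- VarS[p] - sum(tg * (tg - 1) * (2 * tg + 5)) / 18
    }
  }
  Z <- ifelse(S > 0, (S - 1) / sqrt(VarS),
       ifelse(S < 0, (S + 1) / sqrt(VarS), 0))
  Z[!is.finite(slope)] <- NA_real_
  cls <- classify_trend(slope, Z, slope_threshold, z_threshold)

  tr <- annual$transform
  as_g <- function(v, units = "") new_grid(matrix(v, nr, nc), tr, units = units)
  res <- list(slope = as_g(slope, "FVC/a"),
              s_stat = as_g(S), var_s = as_g(VarS), z = as_g(Z),
              trend_class = new_classified_grid(matrix(unclass(cls), nr, nc),
                                                trend_classes(), tr),
              n_masked = sum(!is.finite(slope)))
  class(res) <- "fvc_trend_result"
  res
}

#' Per-pixel stability (CV) analysis of an annual stack
#'
#' @param annual An annual `fvc_gridstack`.
#' @param eps Smallest admissible pixel mean.
#' @return List of class `fvc_stability_result`: grid `cv` and classified
#'   grid `cv_class`.
#' @export
stability_analysis <- function(annual, eps = 1e-12) {
  d <- annual$data
  d[annual$mask] <- NA_real_
  nr <- dim(d)[1]; nc <- dim(d)[2]
  X <- matrix(d, nr * nc, dim(d)[3])
  n <- rowSums(is.finite(X))
  m <- rowMeans(X, na.rm = TRUE)
  s <- sqrt(pmax(rowSums((X - m)^2, na.rm = TRUE) / (n - 1), 0))
  cv <- ifelse(n >= 2 & is.finite(m) & m > eps, s / m, NA_real_)
  cls <- classify_cv(cv)
  tr <- annual$transform
  res <- list(cv = new_grid(matrix(cv, nr, nc), tr, units = "CV"),
              cv_class = new_classified_grid(matrix(unclass(cls), nr, nc),
                                             cv_classes(), tr))
  class(res) <- "fvc_stability_result"
  res
}

#' Per-pixel lagged Pearson correlation between two annual stacks
#'
#' Correlates `y(year)` with `driver(year - lag)` pixel-wise over the
#' overlapping years, with a two-sided t-test p-value (n - 2 df).
#'
#' @param fvc_annual Annual response `fvc_gridstack` (e.g. FVC).
#' @param driver_annual Annual driver `fvc_gridstack` (e.g. precipitation).
#' @param lag_years Lag in years (0, 1 or 2 in typical use).
#' @param min_pairs Minimum overlapping years required (default 5).
#' @return List with grids `r` and `p`, and `n_pairs`.
#' @export
lagged_correlation <- function(fvc_annual, driver_annual, lag_years = 0,
                               min_pairs = 5) {
  ya <- fvc_annual$times$year
  yb <- driver_annual$times$year + lag_years    # driver shifted forward
  common <- intersect(ya, yb)
  if (length(common) < min_pairs)
    stop("fewer than ", min_pairs, " overlapping year pairs at lag ", lag_years)
  ia <- match(common, ya); ib <- match(common, yb)
  A <- fvc_annual$data[, , ia, drop = FALSE]
  B <- driver_annual$data[, , ib, drop = FALSE]
  A[fvc_annual$mask[, , ia, drop = FALSE]] <- NA_real_
  B[driver_annual$mask[, , ib, drop = FALSE]] <- NA_real_
  nr <- dim(A)[1]; nc <- dim(A)[2]; nt <- dim(A)[3]
  MA <- matrix(A, nr * nc, nt); MB <- matrix(B, nr * nc, nt)
  ok <- is.finite(MA) & is.finite(MB)
  MA[!ok] <- NA_real_; MB[!ok] <- NA_real_
  n <- rowSums(ok)
  ma <- rowMeans(MA, na.rm = TRUE); mb <- rowMeans(MB, na.rm = TRUE)
  ca <- MA - ma; cb <- MB - mb
  num <- rowSums(ca * cb, na.rm = TRUE)
  den <- sqrt(rowSums(ca^2, na.rm = TRUE) * rowSums(cb^2, na.rm = TRUE))
  r <- ifelse(n >= min_pairs & den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.finite(r)] <- NA_real_
  tr <- fvc_annual$transform
  list(r = new_grid(matrix(r, nr, nc), tr, units = "r"),
       p = new_grid(matrix(p, nr, nc), tr, units = "p"),
       n_pairs = length(common))
}
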