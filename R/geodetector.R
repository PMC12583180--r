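# Spatial stratified-heterogeneity attribution (geodetector): continuous
# driver discretisation, the factor-detector q statistic with its
# noncentral-F significance test, and the interaction detector with the five
# categorical interaction types.

#' Stratify a driver for the geodetector
#'
#' Builds a stratified factor either from a native categorical vector
#' (`method = "categorical"`) or by discretising a continuous driver with
#' Jenks natural breaks, quantiles or equal intervals. Breaks are recorded in
#' the provenance.
#'
#' @param values Numeric or integer/factor vector of observations.
#' @param method `"jenks"`, `"quantile"`, `"equal_interval"` or
#'   `"categorical"`.
#' @param n_classes Number of strata for the continuous methods.
#' @param name Factor name used in result tables.
#' @return List of class `fvc_stratified_factor` with `name`, `strata`
#'   (integer codes, NA where the value was NA), `L`, `provenance`.
#' @export
discretize <- function(values, method = c("jenks", "quantile",
                                          "equal_interval", "categorical"),
                       n_classes = 5, name = deparse(substitute(values))) {
  method <- match.arg(method)
  if (method == "categorical") {
    f <- factor(values)
    strata <- as.integer(f)
    prov <- list(method = "categorical", levels = levels(f))
    L <- nlevels(f)
  } else {
    v <- as.numeric(values)
    ok <- is.finite(v)
    if (length(unique(v[ok])) < n_classes)
      stop("too few distinct values for ", n_classes, " classes")
    breaks <- switch(method,
      jenks = jenks_breaks(v[ok], n_classes),
      quantile = unique(quantile(v[ok], probs = seq_len(n_classes - 1) / n_classes,
                                 type = 7, names = FALSE)),
      equal_interval = min(v[ok]) +
        (max(v[ok]) - min(v[ok])) * seq_len(n_classes - 1) / n_classes)
    strata <- rep(NA_integer_, length(v))
    strata[ok] <- jenks_assign(v[ok], breaks)
    strata <- match(strata, sort(unique(strata[ok])))  # compact codes
    prov <- list(method = method, n_classes = n_classes, breaks = breaks)
    L <- length(unique(strata[ok]))
  }
  structure(list(name = name, strata = strata, L = L, provenance = prov),
            class = "fvc_stratified_factor")
}

#' Factor-detector q statistic
#'
#' `q = 1 - SSW / SST` where SSW is the pooled within-stratum sum of squared
#' deviations and SST the total sum of squared deviations — the share of the
#' response's spatial variance explained by the stratification, in \[0, 1\].
#' Significance uses the transformation
#' `F = (N - L) / (L - 1) * q / (1 - q)`, which is algebraically the one-way
#' ANOVA F ratio of the stratification: under the null it is central
#' F(L - 1, N - L), giving a calibrated test (the default). The noncentral
#' variant with the plug-in noncentrality
#' `lambda = (sum_h m_h^2 N_h - (sum_h sqrt(N_h) m_h)^2 / N) / sigma^2`
#' (stratum means centered, since q is translation-invariant) is provided for
#' parity with common geodetector software but is strongly conservative — see
#' the methods vignette. A seeded permutation test is used when any stratum
#' is smaller than `min_stratum_size`, or on request.
#'
#' @param y Numeric response vector (e.g. mean FVC per pixel).
#' @param factor_x An `fvc_stratified_factor`, or a vector to be treated as
#'   categorical.
#' @param test `"f"` (central F), `"ncf"` (plug-in noncentral F),
#'   `"permutation"`, or `"auto"` (central F unless tiny strata force the
#'   permutation fallback).
#' @param n_perm Permutations for the fallback test.
#' @param min_stratum_size Strata below this size are flagged and force the
#'   permutation test under `"auto"`.
#' @param seed Seed for the permutation test.
#' @return List of class `fvc_factor_result`: `name`, `q`, `F_stat`,
#'   `p_value`, `N`, `L`, `sst`, `ssw`, `small_strata`, `test`.
#' @export
factor_q <- function(y, factor_x, test = c("auto", "f", "ncf", "permutation"),
                     n_perm = 999, min_stratum_size = 2, seed = 1) {
  test <- match.arg(test)
  if (!inherits(factor_x, "fvc_stratified_factor"))
    factor_x <- discretize(factor_x, "categorical", name = "factor")
  ok <- is.finite(y) & !is.na(factor_x$strata)
  yy <- y[ok]; h <- factor_x$strata[ok]
  N <- length(yy)
  if (N < 3) stop("too few observations")
  sst <- sum((yy - mean(yy))^2)
  if (sst == 0) stop("constant response: q is undefined")
  Nh <- tapply(yy, h, length)
  mh <- tapply(yy, h, mean)
  ssw <- sum(tapply(yy, h, function(v) sum((v - mean(v))^2)))
  q <- 1 - ssw / sst
  L <- length(Nh)
  small <- sum(Nh < min_stratum_size)
  q_of <- function(yv) {
    1 - sum(tapply(yv, h, function(v) sum((v - mean(v))^2))) / sst
  }
  if (test == "auto") test <- if (small > 0 || L < 2) "permutation" else "f"
  if (test %in% c("f", "ncf") && L >= 2 && q < 1) {
    F_stat <- (N - L) / (L - 1) * q / (1 - q)
    if (test == "f") {
      p <- pf(F_stat, df1 = L - 1, df2 = N - L, lower.tail = FALSE)
    } else {
      sigma2 <- sst / N
      mc <- mh - mean(yy)
      lambda <- (sum(mc^2 * Nh) - (sum(sqrt(Nh) * mc))^2 / N) / sigma2
      p <- pf(F_stat, df1 = L - 1, df2 = N - L, ncp = lambda,
              lower.tail = FALSE)
    }
  } else {
    set.seed(seed)
    qs <- replicate(n_perm, q_of(sample(yy)))
    F_stat <- NA_real_
    p <- (1 + sum(qs >= q)) / (n_perm + 1)
    test <- "permutation"
  }
  structure(list(name = factor_x$name, q = q, F_stat = F_stat, p_value = p,
                 N = N, L = L, sst = sst, ssw = ssw,
                 small_strata = small, test = test),
            class = "fvc_factor_result")
}

#' Overlay (intersection) of two stratifications
#'
#' The Cartesian product of the two codings, compacted to the nonempty
#' combinations.
#'
#' @param factor_n,factor_m `fvc_stratified_factor`s of equal length.
#' @return An `fvc_stratified_factor`.
#' @export
overlay_factors <- function(factor_n, factor_m) {
  s <- interaction(factor_n$strata, factor_m$strata, drop = TRUE)
  structure(list(name = paste0(factor_n$name, ":", factor_m$name),
                 strata = as.integer(s), L = nlevels(s),
                 provenance = list(method = "overlay",
                                   parents = c(factor_n$name, factor_m$name))),
            class = "fvc_stratified_factor")
}

#' Interaction detector
#'
#' Computes `q` for both factors and for their overlay, then assigns one of
#' the five interaction types by comparing `q_nm` with `q_n`, `q_m` and their
#' sum: equality with the sum (relative tolerance `tol`) is independent;
#' above the sum, nonlinear enhanced; above the max, bivariable enhanced;
#' below the min, nonlinear weakened; otherwise uni-variable weakened
#' (boundary ties fall into this residual band).
#'
#' @inheritParams factor_q
#' @param factor_n,factor_m `fvc_stratified_factor`s.
#' @param tol Relative tie tolerance for the independence comparison.
#' @return List of class `fvc_interaction_result`: `pair`, `q_n`, `q_m`,
#'   `q_nm`, `interaction_type`, and the three factor results.
#' @export
interaction_q <- function(y, factor_n, factor_m,
                          test = c("auto", "f", "ncf", "permutation"),
                          tol = 1e-9, min_stratum_size = 2, seed = 1) {
  test <- match.arg(test)
  rn <- factor_q(y, factor_n, test = test, min_stratum_size = min_stratum_size,
                 seed = seed)
  rm_ <- factor_q(y, factor_m, test = test, min_stratum_size = min_stratum_size,
                  seed = seed)
  ov <- overlay_factors(factor_n, factor_m)
  ok <- is.finite(y) & !is.na(ov$strata)
  if (max(tabulate(ov$strata[ok])) <= 1)
    warning("overlay produces only singleton strata; q_nm = 1 is an artifact")
  rnm <- factor_q(y, ov, test = test, min_stratum_size = min_stratum_size,
                  seed = seed)
  type <- interaction_type(rn$q, rm_$q, rnm$q, tol = tol)
  structure(list(pair = c(factor_n$name, factor_m$name),
                 q_n = rn$q, q_m = rm_$q, q_nm = rnm$q,
                 interaction_type = type,
                 factor_n = rn, factor_m = rm_, overlay = rnm),
            class = "fvc_interaction_result")
}

#' Classify an interaction from its three q values
#'
#' @param q_n,q_m,q_nm The two single-factor q values and the overlay q.
#' @param tol Relative tolerance for the independence equality.
#' @return One of `"nonlinear_enhanced"`, `"independent"`,
#'   `"bivariable_enhanced"`, `"univariable_weakened"`,
#'   `"nonlinear_weakened"`.
#' @export
interaction_type <- function(q_n, q_m, q_nm, tol = 1e-9) {
  s <- q_n + q_m
  if (abs(q_nm - s) <= tol * max(1, abs(s))) return("independent")
  if (q_nm > s) return("nonlinear_enhanced")
  if (q_nm > max(q_n, q_m)) return("bivariable_enhanced")
  if (q_nm < min(q_n, q_m)) return("nonlinear_weakened")
  "univariable_weakened"
}

#' Rank factor results by explanatory power
#'
#' Descending by `q`; exact ties broken alphabetically by factor name.
#'
#' @param results List of `fvc_factor_result`.
#' @return Data frame with `name`, `q`, `F_stat`, `p_value`, `L`, `N`, sorted.
#' @export
rank_factors <- function(results) {
  if (!length(results)) stop("no factor results to rank")
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(name = r$name, q = r$q, F_stat = r$F_stat, p_value = r$p_value,
               L = r$L, N = r$N, row.names = NULL)))
  df[order(-df$q, df$name), , drop = FALSE]
}
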