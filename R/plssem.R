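# Partial least squares path modelling (PLS-SEM) from first principles:
# standardisation, VIF screening, the iterative Lohmoeller outer/inner
# estimation with centroid/factor/path inner weighting, OLS path coefficients,
# quality metrics (R2, communality, AVE, GOF), bootstrap significance and
# direct/indirect/total effect decomposition. All blocks are reflective
# (mode A).

topo_order <- function(paths, latents) {
  # Kahn's algorithm; errors on cycles
  indeg <- stats::setNames(rep(0L, length(latents)), latents)
  if (length(paths)) for (k in seq_len(nrow(paths)))
    indeg[paths[k, 2]] <- indeg[paths[k, 2]] + 1L
  ord <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    l <- ready[1]; ready <- ready[-1]
    ord <- c(ord, l)
    if (length(paths)) {
      ch <- paths[paths[, 1] == l, 2]
      for (c_ in ch) {
        indeg[c_] <- indeg[c_] - 1L
        if (indeg[c_] == 0L) ready <- c(ready, c_)
      }
    }
  }
  if (length(ord) != length(latents)) stop("inner path graph contains a cycle")
  ord
}

#' Specify a PLS path model
#'
#' @param blocks Named list: latent name -> character vector of its indicator
#'   (manifest variable) names. Every indicator belongs to exactly one block;
#'   all blocks are reflective.
#' @param paths Two-column character matrix of directed inner edges
#'   (source latent, target latent); the graph must be acyclic.
#' @param scheme Inner weighting scheme: `"centroid"` (default, the common
#'   package default), `"factor"` or `"path"`.
#' @return List of class `fvc_pls_spec`.
#' @export
pls_model_spec <- function(blocks, paths, scheme = c("centroid", "factor",
                                                     "path")) {
  scheme <- match.arg(scheme)
  paths <- matrix(as.character(paths), ncol = 2)
  lat <- names(blocks)
  if (is.null(lat) || any(!nzchar(lat))) stop("blocks must be named")
  if (!all(paths %in% lat)) stop("path endpoints must be latent names")
  inds <- unlist(blocks)
  if (anyDuplicated(inds)) stop("each indicator may appear in exactly one block")
  if (any(lengths(blocks) < 1)) stop("every latent needs at least one indicator")
  topo_order(paths, lat)   # validates acyclicity
  structure(list(blocks = blocks, paths = paths, scheme = scheme),
            class = "fvc_pls_spec")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing each listed variable on the
#' others — the standard multicollinearity screen run before a PLS-SEM fit.
#' Perfectly collinear variables report `Inf` with a warning.
#'
#' @param data Data frame of observations.
#' @param variables Column names to screen (default: all).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(data, variables = colnames(data)) {
  X <- as.matrix(data[, variables, drop = FALSE])
  if (nrow(X) < length(variables) + 2)
    stop("need at least length(variables) + 2 observations")
  if (any(apply(X, 2, sd) == 0)) stop("constant columns have no defined VIF")
  out <- stats::setNames(numeric(length(variables)), variables)
  for (j in seq_along(variables)) {
    yj <- X[, j]; Xo <- X[, -j, drop = FALSE]
    # lm warns about "essentially perfect fit" exactly when we are about to
    # report the collinearity ourselves
    r2 <- suppressWarnings(summary(lm(yj ~ Xo))$r.squared)
    if (r2 > 1 - 1e-12) {
      warning("variable '", variables[j], "' is perfectly collinear")
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2)
  }
  out
}

std_cols <- function(X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
}

#' Fit a PLS path model
#'
#' Lohmoeller's iterative algorithm with mode-A (reflective) outer updates:
#' indicators are standardised; latent scores are standardised weighted
#' composites; the inner approximation follows the chosen scheme (centroid:
#' sign of score correlations between adjacent latents; factor: the
#' correlations; path: regression weights for predecessors, correlations for
#' successors); outer weights are refreshed as correlations between each
#' indicator and its block's inner approximation, until the largest absolute
#' outer-weight change falls below `tol`. Afterwards, path coefficients are
#' ordinary least squares of each endogenous latent on its parents' scores,
#' loadings are indicator-score correlations, and each block's sign is fixed
#' so its dominant loading is positive.
#'
#' @param data Data frame containing every indicator; rows with missing
#'   indicator values are dropped (listwise) with the count recorded.
#' @param spec A [pls_model_spec()].
#' @param tol Convergence tolerance on outer weights.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#' @return List of class `fvc_pls_fit`: `outer_weights`, `loadings`,
#'   `communality`, `latent_scores`, `path_coefficients` (matrix
#'   source x target), `path_table`, `r_squared`, `convergence`, `n_used`,
#'   `n_dropped`, `spec`.
#' @export
fit_pls_sem <- function(data, spec, tol = 1e-6, max_iter = 300) {
  inds <- unlist(spec$blocks)
  missing_ind <- setdiff(inds, colnames(data))
  if (length(missing_ind))
    stop("indicators absent from data: ", paste(missing_ind, collapse = ", "))
  df <- data[, inds, drop = FALSE]
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (n <= length(inds)) stop("need more observations than indicators")
  X <- std_cols(df)
  lat <- names(spec$blocks)
  J <- length(lat)
  # adjacency (undirected for the inner approximation)
  A <- matrix(0, J, J, dimnames = list(lat, lat))
  if (nrow(spec$paths)) A[spec$paths] <- 1
  Au <- (A + t(A)) > 0

  w <- lapply(spec$blocks, function(b) rep(1, length(b)))
  score <- function(wts) {
    Y <- sapply(seq_along(lat), function(j)
      X[, spec$blocks[[j]], drop = FALSE] %*% wts[[j]])
    colnames(Y) <- lat
    apply(Y, 2, function(v) (v - mean(v)) / sd(v))
  }
  Y <- score(w)
  it <- 0; delta <- Inf
  while (it < max_iter && delta > tol) {
    it <- it + 1
    R <- cor(Y)
    E <- matrix(0, J, J, dimnames = list(lat, lat))
    for (j in seq_len(J)) {
      nb <- which(Au[j, ])
      if (!length(nb)) next
      if (spec$scheme == "centroid") {
        E[j, nb] <- sign(R[j, nb])
      } else if (spec$scheme == "factor") {
        E[j, nb] <- R[j, nb]
      } else {  # path scheme
        preds <- which(A[, j] > 0)
        succ <- setdiff(nb, preds)
        if (length(preds))
          E[j, preds] <- solve(R[preds, preds, drop = FALSE],
                               R[preds, j, drop = FALSE])
        if (length(succ)) E[j, succ] <- R[j, succ]
      }
    }
    Z <- Y %*% t(E)
    w_new <- w
    for (j in seq_len(J)) {
      if (all(Z[, j] == 0)) next   # isolated latent keeps its weights
      cw <- as.vector(cor(X[, spec$blocks[[j]], drop = FALSE], Z[, j]))
      w_new[[j]] <- cw
    }
    Y_new <- score(w_new)
    # normalise weights so the composite has unit variance, for comparability
    w_new <- lapply(seq_along(lat), function(j) {
      comp <- X[, spec$blocks[[j]], drop = FALSE] %*% w_new[[j]]
      w_new[[j]] / sd(comp)
    })
    names(w_new) <- lat
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    Y <- Y_new
  }
  converged <- delta <= tol

  # sign convention: dominant loading positive per block
  for (j in seq_len(J)) {
    ld <- as.vector(cor(X[, spec$blocks[[j]], drop = FALSE], Y[, j]))
    if (ld[which.max(abs(ld))] < 0) {
      Y[, j] <- -Y[, j]
      w[[j]] <- -w[[j]]
    }
  }
  loadings <- lapply(seq_len(J), function(j)
    stats::setNames(as.vector(cor(X[, spec$blocks[[j]], drop = FALSE], Y[, j])),
                    spec$blocks[[j]]))
  names(loadings) <- lat

  P <- matrix(0, J, J, dimnames = list(lat, lat))
  r2 <- stats::setNames(rep(NA_real_, J), lat)
  for (j in seq_len(J)) {
    parents <- lat[A[, j] > 0]
    if (!length(parents)) next
    fitj <- lm(Y[, j] ~ Y[, parents, drop = FALSE] - 1)
    P[parents, j] <- coef(fitj)
    r2[j] <- 1 - sum(stats::residuals(fitj)^2) / sum(Y[, j]^2)
  }
  path_table <- if (nrow(spec$paths)) data.frame(
    source = spec$paths[, 1], target = spec$paths[, 2],
    coefficient = P[spec$paths], row.names = NULL) else
    data.frame(source = character(0), target = character(0),
               coefficient = numeric(0))

  structure(list(outer_weights = w, loadings = loadings,
                 communality = lapply(loadings, function(l) l^2),
                 latent_scores = Y, path_coefficients = P,
                 path_table = path_table,
                 r_squared = r2[!is.na(r2)],
                 convergence = list(iterations = it, final_change = delta,
                                    converged = converged),
                 n_used = n, n_dropped = n_dropped, spec = spec),
            class = "fvc_pls_fit")
}

#' @export
print.fvc_pls_fit <- function(x, ...) {
  cat(sprintf("<fvc_pls_fit> %d latents, n = %d, %s after %d iterations\n",
              length(x$spec$blocks), x$n_used,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  print(x$path_table)
  invisible(x)
}

#' Quality metrics of a PLS fit
#'
#' R2 per endogenous latent (banded substantial > 0.67, moderate > 0.33,
#' weak > 0.19), communality per indicator (squared loading), AVE per block
#' (mean communality), and `GOF = sqrt(mean communality x mean R2)` (banded
#' strong > 0.36, medium > 0.25, weak > 0.1).
#'
#' @param fit An `fvc_pls_fit`.
#' @return List of class `fvc_pls_quality`: `r_squared` (data frame with
#'   band), `communality`, `ave`, `gof`, `gof_band`.
#' @export
model_quality <- function(fit) {
  r2 <- fit$r_squared
  r2_band <- vapply(r2, function(v)
    if (v > 0.67) "substantial" else if (v > 0.33) "moderate"
    else if (v > 0.19) "weak" else "below_weak", character(1))
  comm <- unlist(fit$communality)
  ave <- vapply(fit$communality, mean, numeric(1))
  gof <- sqrt(mean(comm) * mean(r2))
  gof_band <- if (gof > 0.36) "strong" else if (gof > 0.25) "medium"
              else if (gof > 0.1) "weak" else "below_weak"
  structure(list(r_squared = data.frame(latent = names(r2), r2 = unname(r2),
                                        band = unname(r2_band),
                                        row.names = NULL),
                 communality = comm, ave = ave, gof = gof,
                 gof_band = gof_band),
            class = "fvc_pls_quality")
}

#' Direct, indirect and total effects
#'
#' Direct effects are the path coefficients; total effects sum the products
#' of coefficients over every directed path (the geometric series of the path
#' matrix, finite because the graph is acyclic); indirect = total - direct,
#' so additivity holds exactly.
#'
#' @param fit An `fvc_pls_fit` (or a bare path-coefficient matrix).
#' @return Data frame with `source`, `target`, `direct`, `indirect`, `total`
#'   for every ordered latent pair connected by at least one path.
#' @export
effects_decomposition <- function(fit) {
  P <- if (inherits(fit, "fvc_pls_fit")) fit$path_coefficients else fit
  J <- nrow(P)
  total <- matrix(0, J, J, dimnames = dimnames(P))
  Pk <- diag(J)
  for (k in seq_len(J)) {            # paths longer than J - 1 are impossible
    Pk <- Pk %*% P
    if (all(Pk == 0)) break
    total <- total + Pk
  }
  lat <- rownames(P)
  rows <- which(total != 0 | P != 0, arr.ind = TRUE)
  if (!nrow(rows)) return(data.frame(source = character(0),
                                     target = character(0), direct = numeric(0),
                                     indirect = numeric(0), total = numeric(0)))
  out <- data.frame(source = lat[rows[, 1]], target = lat[rows[, 2]],
                    direct = P[rows], indirect = total[rows] - P[rows],
                    total = total[rows], row.names = NULL)
  out[order(out$target, out$source), , drop = FALSE]
}

#' Bootstrap significance of path coefficients
#'
#' Observation resampling with replacement; each resample is refit and
#' sign-aligned to the full-sample fit blockwise (a latent whose loadings
#' anticorrelate with the full-sample loadings is flipped, flipping its
#' incident paths). Reports the resample standard error, the normal-reference
#' p-value of the t-ratio (the common PLS software convention), the percentile
#' p-value and confidence interval. Fully reproducible under `seed`.
#'
#' @param data,spec As for [fit_pls_sem()].
#' @param n_boot Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return Data frame: `source`, `target`, `coefficient`, `se`, `p_value`
#'   (normal on the t-ratio), `p_percentile`, `ci_lower`, `ci_upper`,
#'   `n_boot_used`.
#' @export
bootstrap_significance <- function(data, spec, n_boot = 500, seed = 1,
                                   conf = 0.95) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  full <- fit_pls_sem(data, spec)
  keys <- paste0(full$path_table$source, "->", full$path_table$target)
  est <- full$path_table$coefficient
  lat <- names(spec$blocks)
  set.seed(seed)
  B <- matrix(NA_real_, n_boot, length(keys))
  failed <- 0
  n <- nrow(data)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_pls_sem(data[idx, , drop = FALSE], spec),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$convergence$converged) { failed <- failed + 1; next }
    flip <- vapply(lat, function(l)
      if (sum(fb$loadings[[l]] * full$loadings[[l]]) < 0) -1 else 1, numeric(1))
    Pb <- fb$path_coefficients * outer(flip, flip)
    B[b, ] <- Pb[spec$paths]
  }
  if (failed > 0.1 * n_boot)
    stop("more than 10% of bootstrap resamples failed to converge (",
         failed, "/", n_boot, ")")
  used <- colSums(is.finite(B))
  se <- apply(B, 2, sd, na.rm = TRUE)
  tratio <- est / se
  p_norm <- 2 * pnorm(abs(tratio), lower.tail = FALSE)
  alpha <- 1 - conf
  ci <- apply(B, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              na.rm = TRUE, type = 7)
  p_perc <- vapply(seq_along(keys), function(j) {
    bj <- B[is.finite(B[, j]), j]
    2 * min(mean(bj <= 0), mean(bj >= 0))
  }, numeric(1))
  data.frame(source = full$path_table$source, target = full$path_table$target,
             coefficient = est, se = se, p_value = p_norm,
             p_percentile = pmin(pmax(p_perc, 0), 1),
             ci_lower = ci[1, ], ci_upper = ci[2, ],
             n_boot_used = used, row.names = NULL)
}
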