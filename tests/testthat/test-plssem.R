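# PLS path modelling: VIF, the iterative estimator, quality metrics,
# effect decomposition, bootstrap.

test_that("VIF matches closed forms", {
  set.seed(111)
  n <- 200
  # exactly orthonormal columns via QR -> sample correlation exactly 0
  Z0 <- scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
  Z <- qr.Q(qr(Z0))   # centred orthonormal columns: exact zero correlation
  d0 <- as.data.frame(Z); names(d0) <- c("u", "v", "w")
  expect_true(all(abs(vif(d0) - 1) < 1e-10))

  # exact equicorrelation 0.5: VIF = 1.5 for all three
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  X <- Z %*% chol(S)
  d1 <- as.data.frame(X); names(d1) <- c("a", "b", "c")
  expect_true(all(abs(vif(d1) - 1.5) < 1e-8))

  d2 <- data.frame(x1 = rnorm(50))
  d2$x2 <- d2$x1
  # one warning per collinear variable, so two here
  expect_warning(expect_warning(v2 <- vif(d2), "collinear"), "collinear")
  expect_true(all(is.infinite(v2)))
})

test_that("degenerate models have closed-form fits", {
  set.seed(112)
  # single latent, single indicator, no paths
  d <- data.frame(x = rnorm(40))
  spec1 <- pls_model_spec(blocks = list(A = "x"),
                          paths = matrix(character(0), ncol = 2))
  f1 <- fit_pls_sem(d, spec1)
  expect_equal(unname(f1$loadings$A), 1)
  expect_equal(as.vector(f1$latent_scores[, "A"]),
               as.vector(scale(d$x)), tolerance = 1e-10)

  # two single-indicator latents: path coefficient == Pearson correlation
  d2 <- data.frame(xa = rnorm(120))
  d2$xb <- 0.6 * d2$xa + rnorm(120)
  spec2 <- pls_model_spec(blocks = list(A = "xa", B = "xb"),
                          paths = rbind(c("A", "B")))
  f2 <- fit_pls_sem(d2, spec2)
  expect_equal(f2$path_table$coefficient, cor(d2$xa, d2$xb),
               tolerance = 1e-10)
  expect_equal(unname(f2$r_squared["B"]), cor(d2$xa, d2$xb)^2,
               tolerance = 1e-10)
})

test_that("latent scores are standardised and signs follow the convention", {
  sim <- simulate_pls_data(n = 300, seed = 4)
  fit <- fit_pls_sem(sim$data, sim$spec)
  expect_true(fit$convergence$converged)
  expect_lt(max(abs(colMeans(fit$latent_scores))), 1e-10)
  expect_lt(max(abs(apply(fit$latent_scores, 2, sd) - 1)), 1e-10)
  for (l in names(sim$spec$blocks)) {
    ld <- fit$loadings[[l]]
    expect_gt(ld[which.max(abs(ld))], 0)
  }
})

test_that("known 4-block model is recovered (tight at n=2000, loose at n=200)", {
  sim <- simulate_pls_data(n = 2000, seed = 7)
  fit <- fit_pls_sem(sim$data, sim$spec)
  truth <- c("A->B" = 0.5, "B->C" = -0.4, "C->D" = 0.3)
  got <- fit$path_coefficients[sim$spec$paths]
  expect_lt(max(abs(got - truth)), 0.05)
  expect_lt(max(abs(unlist(fit$loadings) - 0.8)), 0.05)

  sim_s <- simulate_pls_data(n = 200, seed = 8)
  fit_s <- fit_pls_sem(sim_s$data, sim_s$spec)
  expect_lt(max(abs(fit_s$path_coefficients[sim_s$spec$paths] - truth)), 0.15)

  # all three inner schemes agree closely on a well-conditioned model
  for (sch in c("factor", "path")) {
    sp <- sim$spec; sp$scheme <- sch
    f_alt <- fit_pls_sem(sim$data, sp)
    expect_lt(max(abs(f_alt$path_coefficients[sp$paths] - got)), 0.02)
  }
})

test_that("quality metrics: AVE, communality, GOF and bands", {
  sim <- simulate_pls_data(n = 500, seed = 5)
  fit <- fit_pls_sem(sim$data, sim$spec)
  q <- model_quality(fit)
  expect_equal(unname(q$communality), unname(unlist(fit$loadings))^2,
               tolerance = 1e-12)
  expect_equal(unname(q$ave["A"]), mean(fit$loadings$A^2), tolerance = 1e-12)
  expect_equal(q$gof, sqrt(mean(q$communality) * mean(fit$r_squared)),
               tolerance = 1e-12)

  # closed-form GOF on a constructed fit record
  fake <- list(communality = list(x = 0.5, y = 0.7),
               r_squared = c(l1 = 0.6, l2 = 0.4))
  qf <- model_quality(fake)
  expect_equal(qf$gof, sqrt(0.6 * 0.5), tolerance = 1e-12)
  expect_equal(qf$r_squared$band, c("moderate", "moderate"))

  # single-indicator blocks load at 1 -> AVE and communality 1
  d <- data.frame(p = rnorm(50)); d$q <- d$p * 0.5 + rnorm(50)
  sp <- pls_model_spec(blocks = list(P = "p", Q = "q"),
                       paths = rbind(c("P", "Q")))
  expect_equal(unname(model_quality(fit_pls_sem(d, sp))$ave), c(1, 1),
               tolerance = 1e-12)
})

test_that("effect decomposition matches path enumeration and is additive", {
  lat <- c("A", "B", "C")
  P <- matrix(0, 3, 3, dimnames = list(lat, lat))
  P["A", "B"] <- 0.5; P["B", "C"] <- 0.4
  ef <- effects_decomposition(P)
  ac <- ef[ef$source == "A" & ef$target == "C", ]
  expect_equal(ac$direct, 0)
  expect_equal(ac$indirect, 0.2)
  expect_equal(ac$total, 0.2)
  expect_equal(nrow(ef[ef$source == "C", ]), 0)   # no C -> anything paths

  set.seed(113)
  for (rep_i in 1:20) {
    J <- sample(3:6, 1)
    lt <- LETTERS[1:J]
    M <- matrix(0, J, J, dimnames = list(lt, lt))
    for (i in 1:(J - 1)) for (j in (i + 1):J)
      if (runif(1) < 0.5) M[i, j] <- round(runif(1, -0.8, 0.8), 2)
    ef2 <- effects_decomposition(M)
    expect_equal(ef2$total, ef2$direct + ef2$indirect)   # exact additivity
    oracle <- oracle_total_effects(M)
    for (k in seq_len(nrow(ef2)))
      expect_equal(ef2$total[k], oracle[ef2$source[k], ef2$target[k]],
                   tolerance = 1e-12)
  }
})

test_that("bootstrap is reproducible and detects a strong path", {
  set.seed(114)
  n <- 300
  d <- data.frame(xa = rnorm(n))
  d$xb <- 0.6 * d$xa + 0.8 * rnorm(n)
  spec <- pls_model_spec(blocks = list(A = "xa", B = "xb"),
                         paths = rbind(c("A", "B")))
  b1 <- bootstrap_significance(d, spec, n_boot = 120, seed = 42)
  b2 <- bootstrap_significance(d, spec, n_boot = 120, seed = 42)
  expect_identical(b1, b2)
  expect_lt(b1$p_value, 0.001)
  expect_true(b1$ci_lower < b1$coefficient & b1$coefficient < b1$ci_upper)
  expect_error(bootstrap_significance(d, spec, n_boot = 10), "at least 100")
})

test_that("model spec validation catches structural errors", {
  expect_error(pls_model_spec(blocks = list(A = "x", B = "y"),
                              paths = rbind(c("A", "B"), c("B", "A"))),
               "cycle")
  expect_error(pls_model_spec(blocks = list(A = "x", B = "x"),
                              paths = rbind(c("A", "B"))),
               "exactly one block")
  expect_error(pls_model_spec(blocks = list(A = "x"),
                              paths = rbind(c("A", "Z"))),
               "latent names")
  sim <- simulate_pls_data(n = 50, seed = 1)
  expect_error(fit_pls_sem(sim$data[, -1], sim$spec), "absent")
})
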