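test_that("partial_correlation matches the closed form and SEM structure", {
  # constructed data with exact sample correlations (r_uv, r_uw, r_vw)
  target <- matrix(c(1, 0.6, 0.5,
                     0.6, 1, 0.5,
                     0.5, 0.5, 1), 3, 3)
  d <- exact_corr_data(400, target, seed = 1)
  got <- partial_correlation(d[, 1], d[, 2], d[, 3])
  expect_equal(got, (0.6 - 0.25) / sqrt(0.75 * 0.75), tolerance = 1e-10)

  # residual-based definition agrees with the formula
  res_u <- lm.fit(cbind(1, d[, 3]), d[, 1])$residuals
  res_v <- lm.fit(cbind(1, d[, 3]), d[, 2])$residuals
  expect_equal(got, cor(res_u, res_v), tolerance = 1e-10)

  # data from the perfect-mediation structural model: partial correlation
  # of cause and outcome given the mediator is zero
  set.seed(2)
  n <- 1e5
  alpha <- 0.5; beta <- 0.5
  x <- rnorm(n)
  m <- alpha * x + sqrt(1 - alpha^2) * rnorm(n)
  y <- beta * m + sqrt(1 - beta^2) * rnorm(n)
  expect_lt(abs(partial_correlation(x, y, m)), 0.01)

  # conditioning on an independent variable leaves plain correlation
  w <- rnorm(n)
  expect_equal(partial_correlation(x, m, w), cor(x, m), tolerance = 0.01)
  expect_error(partial_correlation(x, m, x), "degenerate")
})

test_that("path_coefficient is the product of the structural parameters", {
  expect_equal(path_coefficient(0.43, 0.79), 0.3397)
  expect_equal(path_coefficient(0, 0.9), 0)
  expect_equal(path_coefficient(-0.3, 0.5), -0.15)
})

test_that("run_hdma returns self-consistent, sign-fixed results", {
  pop <- small_population(n = 150, seed = 4)
  fit <- run_hdma(pop$G_K, pop$T_K, pop$P_K)
  expect_true(fit$converged)
  expect_gte(fit$alpha, 0)
  expect_gte(fit$beta, 0)
  expect_equal(fit$path_coefficient, fit$alpha * fit$beta)
  # recomputing the structural parameters from the returned scores
  expect_equal(cor(fit$scores$G_C, fit$scores$T_C), fit$alpha,
               tolerance = 1e-8)
  expect_equal(cor(fit$scores$T_C, fit$scores$P_C), fit$beta,
               tolerance = 1e-8)
  for (s in fit$scores) {
    expect_lt(abs(mean(s)), 1e-8)
    expect_equal(var(s), 1, tolerance = 1e-8)
  }
  # anchor orientation: P_C correlates positively with the anchor trait
  fit2 <- run_hdma(pop$G_K, pop$T_K, pop$P_K,
                   anchor = unclass(pop$phenome)[, 1])
  expect_gte(cor(fit2$scores$P_C, unclass(pop$phenome)[, 1]), 0)
})

test_that("scores are invariant to positive kernel rescaling", {
  pop <- small_population(n = 80, seed = 5)
  f1 <- run_hdma(pop$G_K, pop$T_K, pop$P_K)
  Tk2 <- hdma_kernel(unclass(pop$T_K) * 7.3)
  f2 <- run_hdma(pop$G_K, Tk2, pop$P_K)
  expect_equal(f1$scores$T_C, f2$scores$T_C, tolerance = 1e-8)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-8)
})

test_that("relabeling individuals permutes scores and preserves parameters", {
  pop <- small_population(n = 60, seed = 6)
  f1 <- run_hdma(pop$G_K, pop$T_K, pop$P_K)
  p <- sample(60)
  perm <- function(K) {
    m <- unclass(K)[p, p]
    hdma_kernel(m, block_role = attr(K, "block_role"))
  }
  f2 <- run_hdma(perm(pop$G_K), perm(pop$T_K), perm(pop$P_K))
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  # scores are defined up to a joint sign flip
  s <- sign(cor(f2$scores$T_C, f1$scores$T_C[p]))
  expect_equal(unname(s * f2$scores$T_C), unname(f1$scores$T_C[p]),
               tolerance = 1e-5)
  expect_equal(unname(s * f2$scores$P_C), unname(f1$scores$P_C[p]),
               tolerance = 1e-5)
})

test_that("independent blocks show no mediation beyond their own null", {
  set.seed(7)
  n <- 120
  mk <- function() {
    gram_kernel(feature_block(matrix(rnorm(n * n), n, n,
                                     dimnames = list(sprintf("i%03d", 1:n),
                                                     NULL)),
                              block_role = "phenome"))
  }
  G <- mk(); Tk <- mk(); P <- mk()
  fit <- suppressWarnings(run_hdma(G, Tk, P))
  null <- suppressWarnings(permute_path_null(G, Tk, P, n_perm = 39,
                                             seed = 1))
  expect_gt(empirical_p(fit$path_coefficient, null$path_coefficients,
                        "greater"), 0.05)
  # the direct genome-phenome partial correlation is consistent with zero
  expect_lt(abs(fit$partials["gc_pc_given_tc"]), 0.3)
})

test_that("feature_loadings back-projection reproduces kernel scores", {
  pop <- small_population(n = 70, seed = 8)
  fit <- run_hdma(pop$G_K, pop$T_K, pop$P_K)
  b <- feature_loadings(fit$kernel_loadings$b, pop$expr)
  X <- scale(unclass(pop$expr))
  score <- drop(X %*% b)
  # X (X' b~) equals (X X') b~ up to the unit-variance standardization
  expect_equal(unname(score / sd(score)), unname(fit$scores$T_C) * sign(
    cor(score, fit$scores$T_C)), tolerance = 1e-8)

  # duplicated features receive identical loadings
  X2 <- cbind(unclass(pop$expr), dup = unclass(pop$expr)[, 1])
  colnames(X2)[1] <- "orig"
  b2 <- feature_loadings(fit$kernel_loadings$b,
                         feature_block(X2, "transcriptome"))
  expect_equal(unname(b2["dup"]), unname(b2["orig"]))
  expect_error(feature_loadings(fit$kernel_loadings$b[-1], pop$expr),
               "length")
})

test_that("mediation_summary computes trait variance capture", {
  pop <- small_population(n = 90, seed = 9)
  fit <- run_hdma(pop$G_K, pop$T_K, pop$P_K)

  # P_C equal to a single measured trait captures 100% of that phenome
  one <- feature_block(cbind(t1 = fit$scores$P_C), "phenome")
  expect_equal(mediation_summary(fit, one)$pct_phenome_variance, 100,
               tolerance = 1e-8)

  # two orthogonal traits, P_C equal to the first: 50%
  set.seed(10)
  t2 <- lm.fit(cbind(1, fit$scores$P_C), rnorm(90))$residuals
  two <- feature_block(cbind(t1 = fit$scores$P_C, t2 = t2), "phenome")
  expect_equal(mediation_summary(fit, two)$pct_phenome_variance, 50,
               tolerance = 1e-8)

  # independent phenome: near zero
  set.seed(11)
  ind <- feature_block(matrix(rnorm(90 * 4), 90, 4), "phenome")
  expect_lt(mediation_summary(fit, ind)$pct_phenome_variance, 10)
})

test_that("degenerate kernels are rejected", {
  pop <- small_population(n = 40, seed = 12)
  zero <- hdma_kernel(matrix(0, 40, 40,
                             dimnames = dimnames(unclass(pop$G_K))))
  expect_error(run_hdma(pop$G_K, zero, pop$P_K), "degenerate")
})
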