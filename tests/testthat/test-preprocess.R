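test_that("rank_normal matches Blom quantiles and handles ties", {
  # independent oracle: closed-form Blom quantile function
  blom <- function(x) qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
  expect_equal(rank_normal(c(5, 1, 9)), blom(c(5, 1, 9)), tolerance = 1e-12)
  expect_equal(round(rank_normal(c(5, 1, 9)), 4), c(0, -0.8694, 0.8694))

  x <- c(3.2, -1, 7, 0.5, 2.2, 9, -4)
  p <- sample(seq_along(x))
  expect_equal(rank_normal(x)[p], rank_normal(x[p]))

  # ties map to the tied average-rank quantile
  out <- rank_normal(c(1, 1, 5))
  expect_equal(out[1], out[2])
  expect_equal(out[1], qnorm((1.5 - 3 / 8) / 3.25))
  expect_lt(abs(mean(rank_normal(rnorm(101)))), 1e-8)
  expect_error(rank_normal(rep(2, 4)), "constant")
})

test_that("adjust_covariates residualizes on the covariate design", {
  set.seed(2)
  n <- 60
  c1 <- rnorm(n)
  covars <- feature_block(cbind(c1 = c1), "covariates",
                          individual_ids = sprintf("i%02d", 1:n))
  e <- lm.fit(cbind(1, c1), rnorm(n))$residuals
  y <- 2 * c1 + e
  block <- feature_block(cbind(a = c1, b = y), "phenome",
                         individual_ids = sprintf("i%02d", 1:n))
  adj <- adjust_covariates(block, covars)
  expect_lt(sqrt(sum(adj[, "a"]^2)), 1e-8)       # covariate column vanishes
  expect_equal(unname(adj[, "b"]), e, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(adj))), 1e-8)

  # intercept-only adjustment is column centering
  cent <- adjust_covariates(block, NULL)
  expect_equal(unclass(cent)[, ], scale(unclass(block), scale = FALSE)[, ])
})

test_that("gram_kernel equals the brute-force outer-product sum", {
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  X <- scale(X, scale = FALSE)
  b <- feature_block(X, "transcriptome")
  K <- gram_kernel(b, scale_features = FALSE)
  brute <- matrix(0, 6, 6)
  for (j in 1:3) brute <- brute + outer(X[, j], X[, j])
  expect_equal(unclass(K)[, ], brute, ignore_attr = TRUE, tolerance = 1e-12)

  # duplicated individuals give identical kernel rows/columns
  X2 <- rbind(X, X[1, ])
  K2 <- gram_kernel(feature_block(X2, "transcriptome"))
  expect_equal(unclass(K2)[7, ], unclass(K2)[1, ], ignore_attr = TRUE)

  # feature order invariance
  K3 <- gram_kernel(feature_block(X[, c(3, 1, 2)], "transcriptome"))
  K1 <- gram_kernel(feature_block(X, "transcriptome"))
  expect_equal(unclass(K3)[, ], unclass(K1)[, ], ignore_attr = TRUE)

  expect_error(gram_kernel(feature_block(X[, 0, drop = FALSE], "genome")),
               "no features")
})

test_that("nearest_marker picks minimal distance with lower-coordinate ties", {
  mm <- data.frame(marker_id = c("a", "b", "c"),
                   chromosome = c("1", "1", "2"),
                   position_bp = c(900000, 1200000, 500000))
  expect_equal(nearest_marker("1", 1000000, mm), "a")
  mm2 <- data.frame(marker_id = c("lo", "hi"), chromosome = "1",
                    position_bp = c(950000, 1050000))
  expect_equal(nearest_marker("1", 1000000, mm2), "lo")
  expect_error(nearest_marker("X", 1, mm), "X")
})

test_that("fit_local_model decomposes exactly and drops the reference founder", {
  set.seed(5)
  n <- 80
  D <- matrix(0, n, 4)
  D[cbind(1:n, sample(4, n, TRUE))] <- 2  # dosages sum to 2
  colnames(D) <- paste0("mk:", LETTERS[1:4])
  beta <- c(1, -2, 0.5, 0)
  y <- drop(D %*% beta) + rnorm(n, sd = 0.1)
  fit <- fit_local_model(y, D)
  expect_equal(fit$dropped_column, "mk:D")
  expect_equal(fit$fitted + fit$residual, y, tolerance = 1e-10)
  # residual orthogonal to every design column
  expect_lt(max(abs(crossprod(D, fit$residual))), 1e-8)

  # single column: coefficient recovered exactly
  c1 <- rnorm(n)
  f2 <- fit_local_model(3 * c1, cbind(c = c1))
  expect_equal(unname(f2$coefficients["c"]), 3, tolerance = 1e-10)
  expect_lt(sd(f2$residual), 1e-10)
})

test_that("local fit on pure noise explains about h/n of the variance", {
  set.seed(6)
  n <- 200
  ratios <- replicate(300, {
    D <- matrix(0, n, 8)
    D[cbind(1:n, sample(8, n, TRUE))] <- 2
    y <- rnorm(n)
    var(fit_local_model(y, D)$fitted) / var(y)
  })
  # OLS on h=7 effective columns (+ intercept) fits ~ 7/n of pure noise
  expect_equal(mean(ratios), 7 / n, tolerance = 0.3)
})

test_that("split_local_distal is an exact orthogonal decomposition", {
  pop <- small_population(n = 100, seed = 7)
  sp <- split_local_distal(pop$expr, pop$genomes, pop$marker_map)
  recon <- unclass(sp$local_block) + unclass(sp$distal_block)
  expect_equal(recon, unclass(pop$expr)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # residuals orthogonal to each transcript's local design
  for (j in c(1, 17, 44)) {
    fit <- sp$fits[[j]]
    D <- hdmediate:::marker_dosage_columns(pop$genomes, fit$marker_id)
    expect_lt(max(abs(crossprod(D, fit$residual))), 1e-6)
  }
  # fully locally determined transcript has near-zero distal variance
  set.seed(8)
  D <- hdmediate:::marker_dosage_columns(pop$genomes, "chr2_m01")
  lin <- drop(D %*% rnorm(8))
  f <- fit_local_model(lin, D)
  expect_lt(var(f$residual), 1e-16)
})

test_that("combine_tissue_kernels trace-normalizes and sums", {
  b1 <- tiny_block(8, 5, seed = 9)
  b2 <- tiny_block(8, 12, seed = 10)
  k1 <- gram_kernel(b1)
  k2 <- gram_kernel(b2)
  comb <- combine_tissue_kernels(list(k1, k2))
  expect_equal(sum(diag(comb)), 8, tolerance = 1e-10)
  # single kernel: returns it trace-normalized
  one <- combine_tissue_kernels(list(k1))
  expect_equal(unclass(one)[, ], unclass(k1)[, ] * 8 / sum(diag(k1)),
               tolerance = 1e-10)
  # two identical kernels: proportional to the input
  two <- combine_tissue_kernels(list(k1, k1))
  expect_equal(unclass(two)[, ] / unclass(one)[, ], matrix(1, 8, 8),
               tolerance = 1e-10, ignore_attr = TRUE)
  # PSD is preserved (validated inside hdma_kernel on construction)
  expect_s3_class(comb, "hdma_kernel")
  k3 <- gram_kernel(tiny_block(5, 2, seed = 11))
  expect_error(combine_tissue_kernels(list(k1, k3)), "identical")
})

test_that("kernel validation enforces symmetry and PSD", {
  m <- matrix(rnorm(16), 4, 4)
  expect_error(hdma_kernel(m), "symmetric")
  neg <- diag(c(1, 1, 1, -1))
  expect_error(hdma_kernel(neg), "positive semidefinite")
})
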