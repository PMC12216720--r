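test_that("kinship_matrix equals the brute-force marker average", {
  g <- simulate_genomes(12, n_chr = 2, markers_per_chr = 3, seed = 1)
  K <- kinship_matrix(g)
  D <- unclass(g)
  markers <- unique(sub(":[A-H]$", "", colnames(D)))
  brute <- matrix(0, 12, 12)
  for (mk in markers) {
    d <- D[, grep(paste0("^", mk, ":"), colnames(D)), drop = FALSE]
    brute <- brute + tcrossprod(d)
  }
  brute <- brute / length(markers)
  brute <- brute / mean(diag(brute))
  expect_equal(unclass(K)[, ], brute, ignore_attr = TRUE, tolerance = 1e-12)

  # identical genomes have K_ij = K_ii
  D2 <- rbind(D, D[1, ])
  rownames(D2)[13] <- "clone"
  K2 <- kinship_matrix(feature_block(D2, "genome"))
  expect_equal(K2["clone", rownames(D)[1]], K2["clone", "clone"])
})

test_that("estimate_h2 recovers simulated heritability", {
  set.seed(2)
  # structured kinship: families of 8 with within-family relatedness 0.6
  n <- 400
  fam <- kronecker(diag(n / 8), matrix(0.6, 8, 8))
  diag(fam) <- 1
  K <- hdma_kernel(fam, block_role = "genome")
  eig <- eigen(unclass(K), symmetric = TRUE)
  L <- with(eig, vectors %*% diag(sqrt(pmax(values, 0))))

  # pure genetic signal
  y_gen <- drop(L %*% rnorm(n))
  expect_gt(as.numeric(estimate_h2(y_gen, K, eig = eig)), 0.95)

  # white noise: near zero on average
  h0 <- replicate(30, as.numeric(estimate_h2(rnorm(n), K, eig = eig)))
  expect_lt(mean(h0), 0.06)

  # h2 = 0.5 recovered in the mean
  h5 <- replicate(50, {
    y <- sqrt(0.5) * scale(drop(L %*% rnorm(n))) +
      sqrt(0.5) * scale(rnorm(n))
    as.numeric(estimate_h2(drop(y), K, eig = eig))
  })
  expect_equal(mean(h5), 0.5, tolerance = 0.05)
})

test_that("estimate_h2 ignores covariate-spanned components", {
  set.seed(3)
  g <- simulate_genomes(150, seed = 3)
  K <- kinship_matrix(g)
  covar <- rnorm(150)
  y <- rnorm(150)
  h_plain <- as.numeric(estimate_h2(y, K, covars = cbind(covar)))
  h_shift <- as.numeric(estimate_h2(y + 5 * covar, K, covars = cbind(covar)))
  expect_equal(h_plain, h_shift, tolerance = 1e-6)
})

test_that("local_distal_decomposition separates the two sources", {
  set.seed(4)
  g <- simulate_genomes(300, seed = 4)
  K <- kinship_matrix(g)
  eig <- eigen(unclass(K), symmetric = TRUE)
  mm <- attr(g, "marker_map")
  D <- hdmediate:::marker_dosage_columns(g, "chr2_m02")

  # fully local transcript
  y_loc <- drop(scale(drop(D %*% rnorm(8))))
  r1 <- local_distal_decomposition(y_loc, D, K, eig = eig)
  expect_gt(r1$local_h2, 0.9)
  expect_lt(r1$distal_h2, 0.1)

  # polygenic signal away from the local design, high heritability
  ex <- simulate_transcriptome(g, n_transcripts = 1, module_size = 0,
                               local_fracs = 0, distal_fracs = 0.8,
                               n_distal_loci = 10, seed = 5)
  y_dist <- drop(scale(unclass(ex$expr)[, 1]))
  pos <- attr(ex$expr, "positions")
  Dd <- hdmediate:::marker_dosage_columns(
    g, nearest_marker(pos$chromosome[1], pos$position_bp[1], mm))
  r2 <- local_distal_decomposition(y_dist, Dd, K, eig = eig)
  expect_lt(r2$local_h2, 0.15)
  expect_gt(r2$distal_h2, 0.4)
  expect_lte(r2$local_h2 + r2$distal_h2, 1 + 1e-6)
})

test_that("trait_relevance takes the max absolute Spearman correlation", {
  set.seed(6)
  n <- 100
  tr <- rnorm(n)
  expr <- feature_block(cbind(mono = exp(tr), indep = rnorm(n)),
                        "transcriptome",
                        individual_ids = sprintf("i%03d", 1:n))
  traits <- feature_block(cbind(t1 = tr, t2 = rnorm(n)), "phenome",
                          individual_ids = sprintf("i%03d", 1:n))
  rel <- trait_relevance(expr, traits)
  expect_equal(unname(rel["mono"]), 1)  # monotone transform
  expect_lt(unname(rel["indep"]), 0.35)
  # constant trait skipped with warning
  traits2 <- feature_block(cbind(t1 = tr, flat = rep(1, n)), "phenome",
                           individual_ids = sprintf("i%03d", 1:n))
  expect_warning(trait_relevance(expr, traits2), "flat")
})

test_that("impute_expression applies training coefficients to new designs", {
  set.seed(7)
  D <- matrix(0, 50, 8)
  D[cbind(1:50, sample(8, 50, TRUE))] <- 2
  colnames(D) <- paste0("mk:", LETTERS[1:8])
  y <- drop(D %*% c(rnorm(7), 0)) + rnorm(50, sd = 0.2)
  fit <- fit_local_model(y, D)
  h <- length(fit$coefficients)
  # round trip on the training design reproduces the haplotype part
  imp <- impute_expression(D[, seq_len(h), drop = FALSE], fit$coefficients)
  expect_equal(imp + unname(fit$fitted[1] - imp[1]), unname(fit$fitted),
               tolerance = 1e-10)
  expect_equal(impute_expression(D[, seq_len(h)], rep(0, h)), rep(0, 50))
  expect_error(impute_expression(D[, 1:3], fit$coefficients), "mismatch")
})

test_that("f1_haplotype_average is the parental mean", {
  p1 <- c(A = 1, B = 0, C = 0)
  p2 <- c(A = 0, B = 1, C = 0)
  expect_equal(f1_haplotype_average(p1, p2), c(A = 0.5, B = 0.5, C = 0))
  expect_equal(f1_haplotype_average(p1, p1), p1)
  expect_equal(f1_haplotype_average(c(0.8, 0.2), c(0.2, 0.8)), c(0.5, 0.5))
  expect_error(f1_haplotype_average(p1, p2[1:2]), "shape")
})

test_that("twas flags only correlations beyond every permutation", {
  set.seed(8)
  n <- 80
  ids <- sprintf("i%03d", 1:n)
  tr <- rnorm(n)
  imputed <- feature_block(cbind(hit = tr, miss = rnorm(n)),
                           "transcriptome", individual_ids = ids)
  traits <- feature_block(cbind(t1 = tr + rnorm(n, sd = 0.01),
                                t2 = rnorm(n)), "phenome",
                          individual_ids = ids)
  res <- twas(imputed, traits, n_perm = 50, seed = 9)
  expect_true(res$significant[res$transcript_id == "hit" &
                                res$trait_id == "t1"])
  # null pairs essentially never flagged under the exceed-all criterion
  null_rows <- res[res$transcript_id == "miss", ]
  expect_true(all(!null_rows$significant))

  # an identity-only permutation can never be exceeded
  res1 <- twas(imputed, traits, n_perm = 200, seed = 10)
  expect_true(all(res1$max_null_abs_correlation <= 1))
})
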