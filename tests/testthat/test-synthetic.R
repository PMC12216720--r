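test_that("simulated dosages are valid founder mosaics", {
  g <- simulate_genomes(200, n_chr = 3, markers_per_chr = 4, seed = 1)
  D <- unclass(g)
  markers <- unique(sub(":[A-H]$", "", colnames(D)))
  for (mk in sample(markers, 4)) {
    d <- D[, grep(paste0("^", mk, ":"), colnames(D)), drop = FALSE]
    expect_true(all(rowSums(d) == 2))
    expect_true(all(d >= 0 & d <= 2))
  }
  # low switch probability keeps gametes nearly constant per chromosome:
  # adjacent markers share founders almost always
  g2 <- simulate_genomes(100, n_chr = 1, markers_per_chr = 10,
                         switch_prob = 0.01, seed = 2)
  D2 <- unclass(g2)
  m1 <- D2[, grep("^chr1_m01:", colnames(D2))]
  m10 <- D2[, grep("^chr1_m10:", colnames(D2))]
  expect_gt(mean(rowSums(abs(m1 - m10)) == 0), 0.7)
})

test_that("founder frequencies are uniform at large n", {
  g <- simulate_genomes(2000, n_chr = 1, markers_per_chr = 2, seed = 3)
  D <- unclass(g)
  freq <- colSums(D[, grep("^chr1_m01:", colnames(D))]) / (2 * 2000)
  expect_equal(unname(freq), rep(1 / 8, 8), tolerance = 0.04)
})

test_that("generators are pure functions of (config, seed)", {
  p1 <- simulate_mediation_population(n = 50, seed = 11)
  p2 <- simulate_mediation_population(n = 50, seed = 11)
  expect_identical(unclass(p1$expr)[, ], unclass(p2$expr)[, ])
  expect_identical(unclass(p1$phenome)[, ], unclass(p2$phenome)[, ])
  expect_identical(p1$truth$mediator_weights, p2$truth$mediator_weights)
  p3 <- simulate_mediation_population(n = 50, seed = 12)
  expect_false(identical(unclass(p1$expr)[, ], unclass(p3$expr)[, ]))
})

test_that("realized variance fractions match their targets", {
  g <- simulate_genomes(400, seed = 4)
  mm <- attr(g, "marker_map")
  ex <- simulate_transcriptome(g, n_transcripts = 100, module_size = 0,
                               local_fracs = 0.3, distal_fracs = 0.4,
                               seed = 5)
  pos <- attr(ex$expr, "positions")
  loc_var <- sapply(seq_len(100), function(j) {
    y <- drop(scale(unclass(ex$expr)[, j]))
    mk <- nearest_marker(pos$chromosome[j], pos$position_bp[j], mm)
    D <- hdmediate:::marker_dosage_columns(g, mk)
    var(fit_local_model(y, D)$fitted)
  })
  expect_equal(mean(loc_var), 0.3, tolerance = 0.05)
  gen_var <- colMeans(ex$truth$genetic_component^2)
  expect_equal(mean(gen_var), 0.7, tolerance = 0.05)
})

test_that("deterministic fraction limits hold", {
  g <- simulate_genomes(60, seed = 6)
  # (local, distal) = (1, 0): transcript is a function of the local marker
  ex <- simulate_transcriptome(g, n_transcripts = 2, module_size = 0,
                               local_fracs = 1, distal_fracs = 0, seed = 7)
  pos <- attr(ex$expr, "positions")
  mm <- attr(g, "marker_map")
  D <- hdmediate:::marker_dosage_columns(
    g, nearest_marker(pos$chromosome[1], pos$position_bp[1], mm))
  fit <- fit_local_model(unclass(ex$expr)[, 1], D)
  expect_lt(var(fit$residual), 1e-16)
  # (0, 0): independent of the genome
  ex0 <- simulate_transcriptome(g, n_transcripts = 2, module_size = 0,
                                local_fracs = 0, distal_fracs = 0, seed = 8)
  expect_equal(max(abs(ex0$truth$genetic_component)), 0)
})

test_that("the mediator calibration hits its target exactly in-sample", {
  pop <- simulate_mediation_population(n = 250, seed = 9, alpha_true = 0.55)
  expect_equal(pop$truth$alpha_realized, 0.55, tolerance = 1e-6)
  # unreachable target errors with the achievable range
  g <- simulate_genomes(150, seed = 10)
  expect_error(simulate_transcriptome(g, calibrate_alpha = 0.99, seed = 11),
               "achievable")
})

test_that("perfect mediation holds in the generated latents", {
  pop <- simulate_mediation_population(n = 800, seed = 12)
  tr <- pop$truth
  expect_lt(abs(partial_correlation(tr$g_latent, tr$y, tr$m)), 0.05)
  expect_equal(cor(tr$m, tr$y), tr$beta_true, tolerance = 0.02)
  # direct genome->phenome leakage breaks it
  pop2 <- simulate_mediation_population(n = 800, seed = 12,
                                        direct_effect = 0.5)
  expect_gt(abs(partial_correlation(pop2$truth$g_latent, pop2$truth$y,
                                    pop2$truth$m)), 0.2)
})

test_that("the null preset decouples traits from the transcriptome", {
  pop <- simulate_mediation_population(n = 400, preset = "null", seed = 13)
  expect_equal(pop$truth$beta_true, 0)
  cors <- cor(pop$truth$m, unclass(pop$phenome))
  expect_lt(max(abs(cors)), 0.15)
})

test_that("two populations share local but not distal regulation", {
  tp <- make_two_population_experiment(n_a = 150, n_b = 120, seed = 14)
  archA <- tp$pop_a$truth$architecture
  archB <- tp$pop_b$truth$architecture
  expect_identical(archA$tss_marker, archB$tss_marker)
  expect_identical(archA$founder_effects, archB$founder_effects)
  expect_identical(tp$pop_a$truth$mediator_weights,
                   tp$pop_b$truth$mediator_weights)
  # distal loci redrawn: shared factor loci differ with high probability
  expect_false(identical(unclass(tp$pop_a$expr)[1:5, 1:5],
                         unclass(tp$pop_b$expr)[1:5, 1:5]))

  # locally imputed expression in B correlates with measured expression
  # more strongly for high-local than for low-local transcripts
  spA <- split_local_distal(tp$pop_a$expr, tp$pop_a$genomes,
                            tp$pop_a$marker_map)
  r_by_local <- sapply(seq_along(spA$fits), function(j) {
    ft <- spA$fits[[j]]
    D <- hdmediate:::marker_dosage_columns(tp$pop_b$genomes, ft$marker_id)
    imp <- impute_expression(D[, seq_along(ft$coefficients), drop = FALSE],
                             ft$coefficients)
    if (sd(imp) < 1e-12) return(NA)
    cor(imp, unclass(tp$pop_b$expr)[, j])
  })
  # with shared local architecture the imputed-measured correlation is
  # positive on average
  expect_gt(mean(r_by_local, na.rm = TRUE), 0.05)
})
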