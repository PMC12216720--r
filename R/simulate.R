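#' Simulate founder-mosaic genomes
#'
#' Each individual carries two gametes per chromosome, each a first-order
#' Markov chain over the founder alphabet: the founder at the first marker
#' is uniform, and at every subsequent marker the gamete switches to a
#' uniformly chosen other founder with probability `switch_prob`
#' (emulating recombination in a multiparent cross). The returned block
#' holds per-marker founder dosages (columns `marker:founder`, values in
#' \[0, 2\], summing to 2 at every marker).
#'
#' The default grid (4 chromosomes x 5 markers at 1 Mb spacing, long
#' founder blocks) is a deliberately sparse desk-scale panel: one marker
#' per founder block carries essentially all of the mosaic's information,
#' the way a dense real panel collapses to a modest effective dimension
#' through linkage disequilibrium.
#'
#' @param n Number of individuals.
#' @param n_chr Number of chromosomes.
#' @param markers_per_chr Markers per chromosome (spaced 1 Mb apart).
#' @param n_founders Number of founder haplotypes (8 for an 8-founder
#'   population).
#' @param switch_prob Per-marker-step recombination probability, in (0, 1).
#' @param seed Integer seed.
#' @return A genome [feature_block()] with attribute `marker_map`
#'   (`data.frame(marker_id, chromosome, position_bp)`) and `founders`.
#' @export
simulate_genomes <- function(n, n_chr = 4L, markers_per_chr = 5L,
                             n_founders = 8L, switch_prob = 0.02,
                             seed = 1L) {
  if (switch_prob <= 0 || switch_prob >= 1) stop("switch_prob must be in (0, 1)")
  set.seed(seed)
  founders <- LETTERS[seq_len(n_founders)]
  marker_map <- do.call(rbind, lapply(seq_len(n_chr), function(chr) {
    data.frame(marker_id = sprintf("chr%d_m%02d", chr, seq_len(markers_per_chr)),
               chromosome = as.character(chr),
               position_bp = seq_len(markers_per_chr) * 1000000L)
  }))
  m_total <- nrow(marker_map)
  dosage <- matrix(0, n, m_total * n_founders)
  colnames(dosage) <- as.vector(t(outer(marker_map$marker_id, founders,
                                        paste, sep = ":")))
  rownames(dosage) <- sprintf("ind%04d", seq_len(n))
  one_gamete <- function() {
    g <- matrix(0L, n, m_total)
    col <- 0L
    for (chr in seq_len(n_chr)) {
      state <- sample.int(n_founders, n, replace = TRUE)
      for (j in seq_len(markers_per_chr)) {
        if (j > 1L) {
          sw <- stats::runif(n) < switch_prob
          if (any(sw)) {
            # uniform over the other founders
            jump <- sample.int(n_founders - 1L, sum(sw), replace = TRUE)
            state[sw] <- ((state[sw] - 1L + jump) %% n_founders) + 1L
          }
        }
        col <- col + 1L
        g[, col] <- state
      }
    }
    g
  }
  for (g in list(one_gamete(), one_gamete())) {
    idx <- (rep(seq_len(m_total), each = n) - 1L) * n_founders +
      as.vector(g)
    flat <- cbind(rep(seq_len(n), times = m_total), idx)
    dosage[flat] <- dosage[flat] + 1
  }
  structure(feature_block(dosage, block_role = "genome"),
            marker_map = marker_map, founders = founders)
}

marker_map_of <- function(genomes) {
  mm <- attr(genomes, "marker_map")
  if (is.null(mm)) stop("genome block carries no marker_map attribute")
  mm
}

# standardized polygenic score over a sampled set of markers with dense
# founder weights (no single large-effect locus)
polygenic_score <- function(genomes, loci, founder_weights) {
  z <- numeric(nrow(genomes))
  for (k in seq_along(loci)) {
    z <- z + drop(marker_dosage_columns(genomes, loci[k]) %*%
                    founder_weights[[k]])
  }
  if (stats::sd(z) < 1e-12) z else standardize_vec(z)
}

#' Simulate transcripts with controlled local and distal heritability
#'
#' Transcript `t` is built from standardized components,
#' `sqrt(local) z_local + sqrt(distal) z_distal + sqrt(env) s_t W +
#'  sqrt(1 - local - distal - env) e`:
#' `z_local` is the founder-effect signal at the marker nearest the
#' transcript's TSS (founder effects drawn once per transcript);
#' `z_distal` is a dense-weighted polygenic score over markers sampled away
#' from the TSS chromosome; `e` is independent noise. The first
#' `module_size` transcripts form a correlated trait-relevant module - the
#' structure mediation analysis assumes and real co-expression data show:
#' with module sign `s_t` they share a fraction `module_distal_share` of
#' their distal component (one common polygenic factor `Z`) and a common
#' environmental factor `W` with variance fraction `module_env_frac`.
#' Background transcripts have independent architecture and (by default)
#' low heritability.
#'
#' When `calibrate_alpha` is given, module composite weights are drawn
#' (module sign times Uniform(0.5, 1.5)) and the environmental fraction of
#' the module transcripts is solved numerically so that the realized
#' correlation between the module composite `expr \%*\% w` and its genetic
#' part equals `calibrate_alpha` exactly in this sample - the module's
#' summary axis then *is* a latent variable with genome correlation
#' `alpha`, with no further adjustment. The solved weights are stored in
#' the returned truth as `mediator_weights`.
#'
#' @param genomes A genome block from [simulate_genomes()].
#' @param n_transcripts Number of transcripts.
#' @param local_fracs,distal_fracs Per-transcript variance fractions
#'   (recycled). `NULL` (default) assigns `module_local_frac` /
#'   `module_distal_frac` to module transcripts and the background values
#'   elsewhere.
#' @param module_size Number of transcripts in the correlated module (0
#'   disables it).
#' @param module_distal_share Fraction of a module transcript's distal
#'   variance carried by the shared polygenic factor, in \[0, 1\].
#' @param module_env_frac Variance fraction of the shared (non-genetic)
#'   environmental factor in module transcripts; overridden per sample
#'   when `calibrate_alpha` is used.
#' @param module_local_frac,module_distal_frac Variance fractions for
#'   module transcripts when `local_fracs`/`distal_fracs` are `NULL`.
#' @param background_local_frac,background_distal_frac Same for background
#'   transcripts.
#' @param n_distal_loci Markers contributing to each polygenic component.
#' @param calibrate_alpha Optional target genome correlation of the module
#'   composite, in (0, 1); an error reports the achievable range when the
#'   target is not reachable with these heritability settings.
#' @param seed Integer seed.
#' @param architecture Optional architecture from a previous call (element
#'   `architecture` of the returned truth): reuses TSS assignments, founder
#'   local-effect vectors, variance fractions, module signs and composite
#'   weights so that local regulation and module membership are shared,
#'   while all distal loci, distal weights and the environmental factor
#'   are redrawn - the two-population scenario.
#' @return A list with `expr` (transcriptome [feature_block()] with TSS
#'   positions) and `truth` (list: per-transcript fractions, module signs,
#'   `mediator_weights` (when calibrated), the realized genetic-component
#'   matrix, and the reusable `architecture`).
#' @export
simulate_transcriptome <- function(genomes, n_transcripts = 60L,
                                   local_fracs = NULL, distal_fracs = NULL,
                                   module_size = 30L,
                                   module_distal_share = 0.6,
                                   module_env_frac = 0.25,
                                   module_local_frac = 0.05,
                                   module_distal_frac = 0.35,
                                   background_local_frac = 0.05,
                                   background_distal_frac = 0.05,
                                   n_distal_loci = 10L,
                                   calibrate_alpha = NULL, seed = 1L,
                                   architecture = NULL) {
  set.seed(seed)
  mm <- marker_map_of(genomes)
  founders <- attr(genomes, "founders")
  nf <- length(founders)
  n <- nrow(genomes)
  if (is.null(architecture)) {
    if (module_size > n_transcripts) stop("module_size exceeds n_transcripts")
    in_module <- seq_len(n_transcripts) <= module_size
    if (is.null(local_fracs)) {
      local_fracs <- ifelse(in_module, module_local_frac,
                            background_local_frac)
    }
    if (is.null(distal_fracs)) {
      distal_fracs <- ifelse(in_module, module_distal_frac,
                             background_distal_frac)
    }
    local_fracs <- rep_len(local_fracs, n_transcripts)
    distal_fracs <- rep_len(distal_fracs, n_transcripts)
    env_fracs <- ifelse(in_module, module_env_frac, 0)
    if (any(local_fracs + distal_fracs + env_fracs > 1 + 1e-12)) {
      stop("local + distal + environmental fractions must not exceed 1")
    }
    module_signs <- ifelse(in_module,
                           sample(c(-1, 1), n_transcripts, replace = TRUE), 0)
    mediator_weights <- module_signs *
      stats::runif(n_transcripts, 0.5, 1.5)
    # with a module, the first chromosome is reserved as the distal-driver
    # region (a trans-band hotspot): the shared polygenic factor lives
    # there and no transcript TSS does, so distal regulation never leaks
    # into local-haplotype fits through marker reuse
    tss_pool <- if (any(in_module)) {
      mm$marker_id[mm$chromosome != mm$chromosome[1L]]
    } else mm$marker_id
    tss_marker <- sample(tss_pool, n_transcripts, replace = TRUE)
    tss_offset <- sample.int(400000L, n_transcripts, replace = TRUE) *
      sample(c(-1L, 1L), n_transcripts, replace = TRUE)
    founder_effects <- lapply(seq_len(n_transcripts), function(i) {
      f <- stats::rnorm(nf)
      f - mean(f)
    })
    architecture <- list(tss_marker = tss_marker, tss_offset = tss_offset,
                         founder_effects = founder_effects,
                         local_fracs = local_fracs,
                         distal_fracs = distal_fracs,
                         env_fracs = env_fracs,
                         module_signs = module_signs,
                         mediator_weights = mediator_weights,
                         module_distal_share = module_distal_share)
  }
  local_fracs <- architecture$local_fracs
  distal_fracs <- architecture$distal_fracs
  env_fracs <- architecture$env_fracs
  module_signs <- architecture$module_signs
  w0 <- architecture$mediator_weights
  sh <- architecture$module_distal_share
  n_transcripts <- length(architecture$tss_marker)
  tss_chr <- mm$chromosome[match(architecture$tss_marker, mm$marker_id)]
  tss_pos <- mm$position_bp[match(architecture$tss_marker, mm$marker_id)] +
    architecture$tss_offset

  # shared factors, redrawn per population
  has_module <- any(module_signs != 0)
  Z_shared <- W_shared <- numeric(n)
  shared_loci <- NULL
  if (has_module) {
    driver <- mm$marker_id[mm$chromosome == mm$chromosome[1L]]
    shared_loci <- if (n_distal_loci >= length(driver)) driver else
      sample(driver, n_distal_loci)
    Z_shared <- polygenic_score(genomes, shared_loci,
                                replicate(n_distal_loci, stats::rnorm(nf),
                                          simplify = FALSE))
    W_shared <- standardize_vec(stats::rnorm(n))
  }

  # pass 1: standardized per-transcript components. Distal and shared
  # environmental components are residualized in-sample against the
  # transcript's own local haplotype design so that the local/distal
  # decomposition is exactly orthogonal per transcript - a local fit can
  # recover only the local component, never a projection of the distal one
  # (the finite-sample leak that would otherwise blur the split at desk
  # scale).
  genetic <- noise <- Wmat <- matrix(0, n, n_transcripts)
  for (t in seq_len(n_transcripts)) {
    lf <- local_fracs[t]
    df <- distal_fracs[t]
    s_t <- module_signs[t]
    D <- marker_dosage_columns(genomes, architecture$tss_marker[t])
    qr_D <- qr(cbind(1, D))
    perp_std <- function(z) {
      r <- qr.resid(qr_D, z)
      if (stats::sd(r) < 1e-12) numeric(n) else standardize_vec(r)
    }
    z_local <- if (lf > 0) {
      z <- drop(D %*% architecture$founder_effects[[t]])
      if (stats::sd(z) < 1e-12) numeric(n) else standardize_vec(z)
    } else numeric(n)
    z_distal <- numeric(n)
    if (df > 0) {
      pool <- mm$marker_id[mm$chromosome != tss_chr[t]]
      if (n_distal_loci > length(pool)) {
        stop("n_distal_loci exceeds the available markers off the TSS chromosome")
      }
      z_priv <- polygenic_score(genomes, sample(pool, n_distal_loci),
                                replicate(n_distal_loci, stats::rnorm(nf),
                                          simplify = FALSE))
      z_distal <- perp_std(if (s_t != 0) {
        sqrt(sh) * s_t * Z_shared + sqrt(1 - sh) * z_priv
      } else z_priv)
    }
    if (s_t != 0) Wmat[, t] <- perp_std(W_shared)
    genetic[, t] <- sqrt(lf) * z_local + sqrt(df) * z_distal
    noise[, t] <- standardize_vec(stats::rnorm(n))
  }

  # optional calibration: solve the module environmental fraction so the
  # module composite's genetic correlation equals the target in-sample
  if (!is.null(calibrate_alpha) && has_module) {
    if (calibrate_alpha <= 0 || calibrate_alpha >= 1) {
      stop("calibrate_alpha must be in (0, 1)")
    }
    mod <- which(module_signs != 0)
    q <- 1 - local_fracs[mod] - distal_fracs[mod]   # room for env + noise
    g_c <- drop(genetic[, mod, drop = FALSE] %*% w0[mod])
    w_c <- drop(Wmat[, mod, drop = FALSE] %*% (w0[mod] * module_signs[mod]))
    noise_mod <- noise[, mod, drop = FALSE]
    cor_at <- function(ef) {
      n_c <- drop(noise_mod %*% (w0[mod] * sqrt(pmax(q - ef, 0))))
      stats::cor(g_c + sqrt(ef) * w_c + n_c, g_c)
    }
    ef_max <- min(q) - 0.01
    c_hi <- cor_at(0)
    c_lo <- cor_at(ef_max)
    if (calibrate_alpha > c_hi || calibrate_alpha < c_lo) {
      stopf(paste0("calibrate_alpha = %.3f outside the achievable range ",
                   "[%.3f, %.3f] for these heritability settings"),
            calibrate_alpha, c_lo, c_hi)
    }
    ef <- stats::uniroot(function(e) cor_at(e) - calibrate_alpha,
                         c(0, ef_max), tol = 1e-12)$root
    env_fracs[mod] <- ef
    architecture$env_fracs <- env_fracs
  }

  expr <- genetic +
    sweep(Wmat, 2L, sqrt(env_fracs) * module_signs, "*") +
    sweep(noise, 2L,
          sqrt(pmax(0, 1 - local_fracs - distal_fracs - env_fracs)), "*")

  ids <- sprintf("tx%04d", seq_len(n_transcripts))
  dimnames(expr) <- list(rownames(genomes), ids)
  dimnames(genetic) <- dimnames(expr)
  positions <- data.frame(feature_id = ids, chromosome = tss_chr,
                          position_bp = tss_pos)
  list(expr = feature_block(expr, block_role = "transcriptome",
                            positions = positions),
       truth = list(local_fracs = local_fracs, distal_fracs = distal_fracs,
                    env_fracs = env_fracs, module_signs = module_signs,
                    mediator_weights = w0,
                    genetic_component = genetic, shared_loci = shared_loci,
                    architecture = architecture, seed = seed))
}

#' Simulate traits mediated by a latent composite transcript
#'
#' The latent mediator is a pure expression composite,
#' `m = standardize(expr \%*\% w)`, and the latent genome score is the
#' genetic part of the same composite,
#' `g = standardize(genetic_component \%*\% w)`; with a module calibrated
#' by [simulate_transcriptome()] their correlation equals the target
#' `alpha_true` by construction. The latent outcome is
#' `y = beta_true m + sqrt(1 - beta_true^2) e_y + direct_effect g` with
#' `e_y` orthogonal to `m` and `g` in-sample (so `direct_effect = 0`
#' yields perfect mediation: the partial correlation of `g` and `y` given
#' `m` is zero), and each trait is a noisy scaling of `y` with communality
#' `trait_communality`.
#'
#' @param expr_sim Output of [simulate_transcriptome()].
#' @param mediator_weights Per-transcript composite weights (default: the
#'   calibrated module weights stored by [simulate_transcriptome()], else
#'   i.i.d. standard normal).
#' @param alpha_true Documented target correlation of mediator and latent
#'   genome score; the realized value (recorded as `alpha_realized`) is
#'   exactly this when the transcriptome was calibrated to the same
#'   target.
#' @param beta_true Latent mediator -> outcome coefficient, |beta| < 1.
#' @param n_traits Number of measured traits.
#' @param trait_weights Per-trait scaling of the latent outcome (default:
#'   i.i.d. standard normal; only the sign matters after trait
#'   standardization).
#' @param trait_communality Fraction of each trait's variance carried by
#'   the latent outcome, in (0, 1].
#' @param direct_effect Genome -> phenome leakage coefficient; non-zero
#'   values violate perfect mediation on purpose.
#' @param seed Integer seed.
#' @return A list with `phenome` (trait [feature_block()]) and `truth`
#'   (class `"synthetic_truth"`): mediator weights, `alpha_true`,
#'   `alpha_realized`, `beta_true`, variance fractions, `direct_effect`,
#'   the latent vectors `g_latent`, `m`, `y`, and the seed.
#' @export
simulate_phenome <- function(expr_sim, mediator_weights = NULL,
                             alpha_true = 0.6, beta_true = 0.8,
                             n_traits = 15L, trait_weights = NULL,
                             trait_communality = 0.5, direct_effect = 0,
                             seed = 1L) {
  if (abs(beta_true) >= 1) stop("beta_true must lie in (-1, 1)")
  set.seed(seed)
  expr <- unclass(expr_sim$expr)
  genetic <- expr_sim$truth$genetic_component
  n <- nrow(expr)
  p <- ncol(expr)
  if (is.null(mediator_weights)) {
    mediator_weights <- expr_sim$truth$mediator_weights %||% stats::rnorm(p)
  }
  if (length(mediator_weights) != p) {
    stop("mediator_weights must have one entry per transcript")
  }
  m <- standardize_vec(drop(expr %*% mediator_weights))
  g_latent <- standardize_vec(drop(genetic %*% mediator_weights))
  alpha_realized <- stats::cor(m, g_latent)

  eps_y <- standardize_vec(
    stats::lm.fit(cbind(1, m, g_latent), stats::rnorm(n))$residuals)
  y <- beta_true * m + sqrt(1 - beta_true^2) * eps_y +
    direct_effect * g_latent
  if (is.null(trait_weights)) trait_weights <- stats::rnorm(n_traits)
  h <- trait_communality
  if (h <= 0 || h > 1) stop("trait_communality must be in (0, 1]")
  y_std <- standardize_vec(y)
  traits <- matrix(0, n, n_traits)
  for (j in seq_len(n_traits)) {
    shared_part <- sign(trait_weights[j]) * y_std
    noise <- if (h < 1) standardize_vec(stats::rnorm(n)) else numeric(n)
    traits[, j] <- sqrt(h) * shared_part + sqrt(1 - h) * noise
  }
  dimnames(traits) <- list(rownames(expr),
                           sprintf("trait%02d", seq_len(n_traits)))
  truth <- structure(list(mediator_weights = mediator_weights,
                          alpha_true = alpha_true,
                          alpha_realized = alpha_realized,
                          beta_true = beta_true,
                          local_fracs = expr_sim$truth$local_fracs,
                          distal_fracs = expr_sim$truth$distal_fracs,
                          module_signs = expr_sim$truth$module_signs,
                          trait_weights = trait_weights,
                          trait_communality = trait_communality,
                          direct_effect = direct_effect,
                          g_latent = g_latent, m = m, y = y, seed = seed),
                     class = "synthetic_truth")
  list(phenome = feature_block(traits, block_role = "phenome"),
       truth = truth)
}

#' One-call synthetic mediation population
#'
#' Convenience wrapper chaining [simulate_genomes()],
#' [simulate_transcriptome()] (with module calibration to `alpha_true`)
#' and [simulate_phenome()], returning the three blocks, their Gram
#' kernels and the full generative truth. Presets: `"mediation"` (the
#' default perfect-mediation population, distally dominated module),
#' `"null"` (`beta_true = 0`: traits independent of the transcriptome),
#' `"local_mediation"` (the module's heritability is entirely local: no
#' shared polygenic factor, strong local effects) and
#' `"distal_mediation"` (no local heritability in the module at all).
#'
#' @param n Number of individuals.
#' @param preset Scenario name, see above.
#' @param seed Integer seed.
#' @param n_chr,markers_per_chr,switch_prob Genome settings.
#' @param n_transcripts,module_size,n_distal_loci Transcriptome settings.
#' @param alpha_true,beta_true,n_traits,trait_communality,direct_effect
#'   Phenome settings (`beta_true` is overridden by the null preset).
#' @param ... Further arguments to [simulate_transcriptome()].
#' @return List with `genomes`, `expr`, `phenome`, kernels `G_K`, `T_K`,
#'   `P_K`, `marker_map` and `truth`.
#' @export
simulate_mediation_population <- function(n = 400L,
                                          preset = c("mediation", "null",
                                                     "local_mediation",
                                                     "distal_mediation"),
                                          seed = 1L, n_chr = 4L,
                                          markers_per_chr = 5L,
                                          switch_prob = 0.02,
                                          n_transcripts = 60L,
                                          module_size = 30L,
                                          n_distal_loci = 10L,
                                          alpha_true = 0.6, beta_true = 0.8,
                                          n_traits = 15L,
                                          trait_communality = 0.5,
                                          direct_effect = 0, ...) {
  preset <- match.arg(preset)
  tx_args <- list(...)
  calibrate_alpha <- alpha_true
  if (preset == "null") {
    # no mediation: traits are decoupled from the transcriptome, so the
    # genome correlation of the module composite needs no calibration
    beta_true <- 0
    calibrate_alpha <- NULL
  }
  if (preset == "local_mediation") {
    # purely local mediation: no shared polygenic or environmental factor;
    # the mediator is a diffuse composite of locally regulated transcripts
    # and the realized genome correlation is recorded rather than calibrated
    tx_args$module_local_frac <- tx_args$module_local_frac %||% 0.45
    tx_args$module_distal_frac <- tx_args$module_distal_frac %||% 0
    tx_args$module_distal_share <- tx_args$module_distal_share %||% 0
    tx_args$module_env_frac <- tx_args$module_env_frac %||% 0
    tx_args$background_distal_frac <- tx_args$background_distal_frac %||% 0
    calibrate_alpha <- NULL
  }
  if (preset == "distal_mediation") {
    tx_args$module_local_frac <- tx_args$module_local_frac %||% 0
    tx_args$background_local_frac <- tx_args$background_local_frac %||% 0
  }
  genomes <- simulate_genomes(n, n_chr = n_chr,
                              markers_per_chr = markers_per_chr,
                              switch_prob = switch_prob, seed = seed)
  expr_sim <- do.call(simulate_transcriptome,
                      c(list(genomes, n_transcripts = n_transcripts,
                             module_size = module_size,
                             n_distal_loci = n_distal_loci,
                             calibrate_alpha = calibrate_alpha,
                             seed = seed + 1L), tx_args))
  phen_sim <- simulate_phenome(expr_sim, alpha_true = alpha_true,
                               beta_true = beta_true, n_traits = n_traits,
                               trait_communality = trait_communality,
                               direct_effect = direct_effect,
                               seed = seed + 2L)
  list(genomes = genomes, expr = expr_sim$expr, phenome = phen_sim$phenome,
       G_K = gram_kernel(genomes, scale_features = FALSE),
       T_K = gram_kernel(expr_sim$expr),
       P_K = gram_kernel(phen_sim$phenome),
       marker_map = marker_map_of(genomes),
       truth = utils::modifyList(phen_sim$truth,
                                 expr_sim$truth[c("genetic_component",
                                                  "architecture")]))
}

#' Paired populations sharing local but not distal regulation
#'
#' Simulates two populations from independent founder-mosaic genomes. Both
#' share every transcript's TSS assignment, founder local-effect vector,
#' variance fractions, module membership and composite weights (local
#' regulation and the regulatory program match between populations), while
#' distal loci, distal weights and the shared environmental factor are
#' redrawn independently in population B (distal regulation varies).
#' Mediator weights calibrated in population A act on total expression in
#' both populations.
#'
#' @param n_a,n_b Population sizes.
#' @param seed Integer seed.
#' @param alpha_true,beta_true,n_traits,trait_communality,direct_effect
#'   Phenome settings applied in both populations.
#' @param n_chr,markers_per_chr,switch_prob Genome settings.
#' @param n_transcripts,module_size,n_distal_loci Transcriptome settings.
#' @param ... Further arguments to [simulate_transcriptome()].
#' @return List with `pop_a`, `pop_b` (each with blocks, kernels,
#'   `marker_map` and truth) and the shared `architecture`.
#' @export
make_two_population_experiment <- function(n_a = 400L, n_b = 200L, seed = 1L,
                                           alpha_true = 0.6, beta_true = 0.8,
                                           n_traits = 15L,
                                           trait_communality = 0.5,
                                           direct_effect = 0,
                                           n_chr = 4L, markers_per_chr = 5L,
                                           switch_prob = 0.02,
                                           n_transcripts = 60L,
                                           module_size = 30L,
                                           n_distal_loci = 10L, ...) {
  gen_a <- simulate_genomes(n_a, n_chr = n_chr,
                            markers_per_chr = markers_per_chr,
                            switch_prob = switch_prob, seed = seed)
  expr_a <- simulate_transcriptome(gen_a, n_transcripts = n_transcripts,
                                   module_size = module_size,
                                   n_distal_loci = n_distal_loci,
                                   calibrate_alpha = alpha_true,
                                   seed = seed + 1L, ...)
  phen_a <- simulate_phenome(expr_a, alpha_true = alpha_true,
                             beta_true = beta_true, n_traits = n_traits,
                             trait_communality = trait_communality,
                             direct_effect = direct_effect, seed = seed + 2L)
  gen_b <- simulate_genomes(n_b, n_chr = n_chr,
                            markers_per_chr = markers_per_chr,
                            switch_prob = switch_prob, seed = seed + 3L)
  expr_b <- simulate_transcriptome(gen_b, n_distal_loci = n_distal_loci,
                                   seed = seed + 4L,
                                   architecture = expr_a$truth$architecture)
  phen_b <- simulate_phenome(expr_b,
                             mediator_weights = phen_a$truth$mediator_weights,
                             alpha_true = alpha_true, beta_true = beta_true,
                             n_traits = n_traits,
                             trait_communality = trait_communality,
                             direct_effect = direct_effect, seed = seed + 5L)
  pack <- function(gen, expr_sim, phen_sim) {
    list(genomes = gen, expr = expr_sim$expr, phenome = phen_sim$phenome,
         G_K = gram_kernel(gen, scale_features = FALSE),
         T_K = gram_kernel(expr_sim$expr),
         P_K = gram_kernel(phen_sim$phenome),
         marker_map = marker_map_of(gen),
         truth = utils::modifyList(phen_sim$truth,
                                   expr_sim$truth[c("genetic_component",
                                                    "architecture")]))
  }
  list(pop_a = pack(gen_a, expr_a, phen_a),
       pop_b = pack(gen_b, expr_b, phen_b),
       architecture = expr_a$truth$architecture)
}
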