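#' Kinship matrix from founder-haplotype dosages
#'
#' Genomic relationship of each pair of individuals as the average over
#' markers of the inner product of their founder-dosage vectors,
#' `K = (1/m) sum_l d_l d_l'`, scaled so the mean diagonal equals 1.
#' Dosages are expected in \[0, 2\] and to sum to 2 per marker.
#'
#' @param genome_block Haplotype-dosage [feature_block()] with columns named
#'   `marker:founder`.
#' @return An [hdma_kernel()] with role `"genome"`.
#' @export
kinship_matrix <- function(genome_block) {
  cols <- colnames(genome_block)
  markers <- unique(sub(":[^:]*$", "", cols))
  m <- length(markers)
  if (m == 0L || ncol(genome_block) == 0L) stop("no markers in genome block")
  K <- tcrossprod(unclass(genome_block)) / m
  K <- K / mean(diag(K))
  dimnames(K) <- list(rownames(genome_block), rownames(genome_block))
  hdma_kernel(K, block_role = "genome")
}

#' REML heritability with a single genetic variance component
#'
#' Fits `y = X c + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` and returns the restricted-maximum-likelihood
#' estimate of `h^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`. One symmetric
#' eigendecomposition of `K` rotates the model to independent errors, after
#' which the restricted profile likelihood in `h^2` is maximized on \[0, 1\]
#' by scalar optimization.
#'
#' @param y Numeric n-vector (non-constant).
#' @param K Kinship [hdma_kernel()] or symmetric PSD matrix.
#' @param covars Optional covariate matrix/[feature_block()]; an intercept
#'   is always included.
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)`, reusable
#'   across many traits on the same individuals.
#' @param tol Optimizer tolerance.
#' @return The estimate, a single numeric in \[0, 1\], with attribute
#'   `boundary` (`TRUE` when the optimum sits at 0 or 1) and `loglik`.
#' @export
estimate_h2 <- function(y, K, covars = NULL, eig = NULL, tol = 1e-6) {
  n <- length(y)
  if (stats::sd(y) < .Machine$double.eps) stop("y is constant")
  if (is.null(eig)) eig <- eigen(unclass(K), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  X <- covariate_design(covars, n = n)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  q <- ncol(Xt)
  neg_restricted_ll <- function(h2) {
    v <- h2 * d + (1 - h2)
    v <- pmax(v, 1e-12)
    XtVX <- crossprod(Xt, Xt / v)
    bhat <- solve(XtVX, crossprod(Xt, yt / v))
    r <- yt - drop(Xt %*% bhat)
    rss <- sum(r^2 / v)
    0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus +
             (n - q) * log(rss))
  }
  opt <- stats::optimize(neg_restricted_ll, interval = c(0, 1), tol = tol)
  h2 <- opt$minimum
  # optimize() never returns the exact endpoints; snap when the endpoint
  # value is at least as good
  for (endpoint in c(0, 1)) {
    if (abs(h2 - endpoint) < 2 * tol &&
        neg_restricted_ll(endpoint) <= opt$objective + 1e-10) {
      h2 <- endpoint
    }
  }
  structure(max(0, min(1, h2)),
            boundary = h2 <= tol || h2 >= 1 - tol,
            loglik = -opt$objective)
}

#' Local/distal heritability decomposition of one transcript
#'
#' For a covariate-adjusted, variance-1 transcript: the variance of the
#' local haplotype fit is its local heritability; the variance of the
#' residual multiplied by the kinship heritability of the residual is its
#' distal heritability.
#'
#' @param transcript Numeric n-vector, adjusted and scaled to variance 1.
#' @param local_design n x h haplotype dosages at the nearest marker.
#' @param K Kinship matrix.
#' @param covars Optional covariates passed to both fits.
#' @param eig Optional precomputed eigendecomposition of `K`.
#' @param feature_id Identifier carried into the record.
#' @return A one-row `data.frame` (class `"heritability_record"`) with
#'   `feature_id`, `local_h2`, `distal_h2`, `residual_h2`.
#' @export
local_distal_decomposition <- function(transcript, local_design, K,
                                       covars = NULL, eig = NULL,
                                       feature_id = NA_character_) {
  fit <- fit_local_model(transcript, local_design, covars = covars)
  local_h2 <- stats::var(fit$fitted)
  res <- fit$residual
  distal_h2 <- if (stats::sd(res) < 1e-10) 0 else {
    stats::var(res) * as.numeric(estimate_h2(res, K, covars = covars, eig = eig))
  }
  out <- data.frame(feature_id = feature_id,
                    local_h2 = min(1, local_h2),
                    distal_h2 = min(1, distal_h2),
                    residual_h2 = if (stats::sd(res) < 1e-10) 0 else
                      distal_h2 / stats::var(res))
  class(out) <- c("heritability_record", "data.frame")
  out
}

#' Trait relevance of each transcript
#'
#' Maximum absolute Spearman correlation of each (covariate-adjusted)
#' transcript across all (covariate-adjusted) traits. Constant traits are
#' skipped with a warning.
#'
#' @param expr_block,trait_block Aligned, covariate-adjusted feature blocks.
#' @param covars Optional covariates; when given, both blocks are adjusted
#'   internally first.
#' @return Named numeric vector, one value in \[0, 1\] per transcript.
#' @export
trait_relevance <- function(expr_block, trait_block, covars = NULL) {
  if (!is.null(covars)) {
    expr_block <- adjust_covariates(expr_block, covars)
    trait_block <- adjust_covariates(trait_block, covars)
  }
  keep <- apply(unclass(trait_block), 2L, stats::sd) > .Machine$double.eps
  if (!all(keep)) {
    warnf("skipping constant trait(s): %s",
          paste(colnames(trait_block)[!keep], collapse = ", "))
  }
  traits <- unclass(trait_block)[, keep, drop = FALSE]
  if (ncol(traits) == 0L) stop("no non-constant traits")
  rho <- stats::cor(unclass(expr_block), traits, method = "spearman")
  stats::setNames(apply(abs(rho), 1L, max), colnames(expr_block))
}

#' Impute expression from local genotype
#'
#' Multiplies a (new) haplotype design at the transcript's nearest marker by
#' the eQTL coefficients estimated in the training population. No intercept
#' or covariate term enters, so the imputation carries only the genetically
#' encoded expression component.
#'
#' @param local_design n x h haplotype dosages in the target population;
#'   column order must match the training design.
#' @param coefficients Haplotype coefficients from [fit_local_model()].
#' @return Numeric n-vector of imputed expression.
#' @export
impute_expression <- function(local_design, coefficients) {
  local_design <- as.matrix(local_design)
  if (ncol(local_design) != length(coefficients)) {
    stop("founder order / count mismatch between design and coefficients")
  }
  if (!is.null(colnames(local_design)) && !is.null(names(coefficients))) {
    want <- sub("^.*:", "", names(coefficients))
    have <- sub("^.*:", "", colnames(local_design))
    if (!identical(want, have)) {
      stop("founder order mismatch between design and coefficients")
    }
  }
  drop(local_design %*% coefficients)
}

#' Diploid F1 dosage from two inbred parents
#'
#' The expected founder-haplotype probabilities of an F1 individual are the
#' element-wise mean of its two (near one-hot) parental probability vectors
#' at every locus; on the diploid dosage scale in \[0, 2\] the mean of the
#' parental dosages.
#'
#' @param parent1_probs,parent2_probs Numeric vectors (or matrices,
#'   loci x founders) of equal shape.
#' @return Object of the same shape: the element-wise mean.
#' @export
f1_haplotype_average <- function(parent1_probs, parent2_probs) {
  if (!identical(dim(parent1_probs), dim(parent2_probs)) ||
      length(parent1_probs) != length(parent2_probs)) {
    stop("parental probability objects must have identical shape")
  }
  (parent1_probs + parent2_probs) / 2
}

#' Transcriptome-wide association of imputed expression with traits
#'
#' Pearson correlation of each locally-imputed transcript with each
#' covariate-adjusted trait, with significance by label permutation: each
#' permutation shuffles the individuals of the imputed block (the same
#' shuffle across all traits) and recomputes all correlations. A pair is
#' flagged significant when its observed absolute correlation exceeds the
#' maximum absolute permuted correlation for that pair - the "more extreme
#' than every permutation" criterion.
#'
#' @param imputed_block Imputed-expression [feature_block()] (or matrix).
#' @param trait_block Trait [feature_block()] on the same individuals.
#' @param covars Optional covariates; traits are adjusted internally when
#'   given.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A `data.frame` (class `"twas_result"`) with one row per
#'   transcript-trait pair: `transcript_id`, `trait_id`, `correlation`,
#'   `max_null_abs_correlation`, `significant`.
#' @export
twas <- function(imputed_block, trait_block, covars = NULL, n_perm = 100L,
                 seed = 1L) {
  if (!is_count(n_perm)) stop("n_perm must be a positive integer")
  if (!is.null(covars)) trait_block <- adjust_covariates(trait_block, covars)
  E <- unclass(imputed_block)
  Y <- unclass(trait_block)
  if (nrow(E) != nrow(Y)) stop("blocks must share individuals")
  obs <- stats::cor(E, Y)
  set.seed(seed)
  max_null <- matrix(0, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  n <- nrow(E)
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    max_null <- pmax(max_null, abs(stats::cor(E[p, , drop = FALSE], Y)))
  }
  out <- data.frame(
    transcript_id = rep(rownames(obs) %||% paste0("t", seq_len(nrow(obs))),
                        times = ncol(obs)),
    trait_id = rep(colnames(obs) %||% paste0("y", seq_len(ncol(obs))),
                   each = nrow(obs)),
    correlation = as.vector(obs),
    max_null_abs_correlation = as.vector(max_null),
    significant = as.vector(abs(obs) > max_null))
  class(out) <- c("twas_result", "data.frame")
  out
}
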