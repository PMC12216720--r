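#' Rank-based inverse normal (Blom) transform
#'
#' Maps a vector to normal scores via `qnorm((rank - 3/8) / (n + 1/4))`,
#' the Blom offset commonly used to normalize expression and trait values.
#' Ties receive their average rank, so tied inputs map to equal outputs.
#'
#' @param x Numeric vector, length at least 2, finite, not constant.
#' @return Numeric vector of normal scores, monotone in `x`.
#' @export
rank_normal <- function(x) {
  if (length(x) < 2L) stop("rank_normal needs at least two values")
  if (any(!is.finite(x))) stop("rank_normal requires finite values")
  if (stats::sd(x) < .Machine$double.eps) {
    stop("rank_normal is undefined for a constant vector")
  }
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Residualize a block on covariates
#'
#' Replaces every column of `block` by its least-squares residual on the
#' covariate design (an intercept is always included), removing e.g. sex,
#' batch wave and generation effects before kernelization. Rank-deficient
#' covariate columns are dropped with a warning.
#'
#' @param block A [feature_block()].
#' @param covars A covariate [feature_block()] on the same individuals, or
#'   `NULL` for intercept-only adjustment (column centering).
#' @return A [feature_block()] of residuals, columns mean-zero.
#' @export
adjust_covariates <- function(block, covars = NULL) {
  if (is.null(covars)) {
    return(as_feature_block(center_cols(block), block))
  }
  if (!identical(rownames(block), rownames(covars))) {
    aligned <- align_individuals(list(block, covars))
    block <- aligned[[1L]]
    covars <- aligned[[2L]]
  }
  design <- covariate_design(covars)
  qr_d <- qr(design)
  resid <- qr.resid(qr_d, unclass(block))
  dimnames(resid) <- dimnames(block)
  as_feature_block(resid, block)
}

# intercept + covariate columns, dropping linearly dependent columns
covariate_design <- function(covars, n = NULL) {
  if (is.null(covars)) {
    return(matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)")))
  }
  design <- cbind("(Intercept)" = 1, unclass(covars))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warnf("dropping linearly dependent covariate column(s): %s",
          paste(dropped, collapse = ", "))
    design <- design[, sort(keep), drop = FALSE]
  }
  design
}

#' Nearest marker to a transcription start site
#'
#' @param chromosome,position_bp TSS location of the transcript.
#' @param marker_map `data.frame` with columns `marker_id`, `chromosome`,
#'   `position_bp`.
#' @return The `marker_id` on the same chromosome minimizing the distance to
#'   the TSS; ties broken toward the lower coordinate.
#' @export
nearest_marker <- function(chromosome, position_bp, marker_map) {
  on_chr <- marker_map[marker_map$chromosome == chromosome, , drop = FALSE]
  if (nrow(on_chr) == 0L) {
    stopf("no marker on chromosome '%s'", chromosome)
  }
  d <- abs(on_chr$position_bp - position_bp)
  cand <- which(d == min(d))
  if (length(cand) > 1L) {
    cand <- cand[which.min(on_chr$position_bp[cand])]
  }
  on_chr$marker_id[cand]
}

#' Fit a transcript on its local haplotype design
#'
#' Ordinary least squares of one transcript on the founder-haplotype dosage
#' columns of its nearest marker, optionally adjusting for covariates. When
#' the haplotype dosages sum to a constant (diploid dosages sum to 2) the
#' last founder column is dropped as the reference, noted in the result.
#'
#' The returned `fitted` vector is the intercept plus the haplotype
#' contribution only; covariate contributions are excluded so that
#' `var(fitted)` of a variance-1 transcript is its local heritability.
#' `residual` is the residual of the full fit, hence orthogonal to every
#' design column including the haplotype dosages.
#'
#' @param transcript Numeric n-vector.
#' @param local_design n x h haplotype-dosage matrix at the nearest marker.
#' @param covars Optional covariate matrix/[feature_block()].
#' @param marker_id Identifier stored in the result.
#' @param kinship Optional kinship [hdma_kernel()]/matrix. When supplied,
#'   the fit controls for genome-wide relatedness as a random effect
#'   (generalized least squares at the transcript's REML heritability), so
#'   polygenic distal signal is absorbed by the variance model instead of
#'   leaking into the local haplotype coefficients. With `NULL` (default)
#'   the fit is ordinary least squares.
#' @param eig Optional precomputed `eigen(kinship, symmetric = TRUE)`.
#' @return A list of class `"local_fit"` with elements `fitted`, `residual`,
#'   `coefficients` (per retained haplotype column), `marker_id`,
#'   `dropped_column`.
#' @export
fit_local_model <- function(transcript, local_design, covars = NULL,
                            marker_id = NA_character_, kinship = NULL,
                            eig = NULL) {
  local_design <- as.matrix(local_design)
  n <- length(transcript)
  if (nrow(local_design) != n) stop("design rows must match transcript length")
  dropped <- NA_character_
  rs <- rowSums(local_design)
  if (ncol(local_design) > 1L && stats::sd(rs) < 1e-10) {
    dropped <- colnames(local_design)[ncol(local_design)] %||%
      as.character(ncol(local_design))
    local_design <- local_design[, -ncol(local_design), drop = FALSE]
  }
  cov_design <- covariate_design(covars, n = n)
  full <- cbind(cov_design, local_design)
  if (is.null(kinship)) {
    qr_f <- qr(full)
    coefs <- qr.coef(qr_f, transcript)
    coefs[is.na(coefs)] <- 0
  } else {
    if (is.null(eig)) eig <- eigen(unclass(kinship), symmetric = TRUE)
    h2 <- as.numeric(estimate_h2(transcript, kinship, covars = covars,
                                 eig = eig))
    v <- pmax(h2 * pmax(eig$values, 0) + (1 - h2), 1e-8)
    Xt <- crossprod(eig$vectors, full) / sqrt(v)
    yt <- drop(crossprod(eig$vectors, transcript)) / sqrt(v)
    coefs <- qr.coef(qr(Xt), yt)
    coefs[is.na(coefs)] <- 0
  }
  residual <- transcript - drop(full %*% coefs)
  h_idx <- seq.int(ncol(cov_design) + 1L, ncol(full))
  hap_coef <- coefs[h_idx]
  fitted <- drop(local_design %*% hap_coef) + coefs[1L]
  structure(list(fitted = fitted, residual = residual,
                 coefficients = hap_coef, marker_id = marker_id,
                 dropped_column = dropped),
            class = "local_fit")
}

#' Split expression into locally-determined and distal components
#'
#' For every transcript, fits the local haplotype model at the marker
#' nearest its TSS and returns two blocks: the fitted (locally determined)
#' expression and the residual (distal plus noise) expression. The two sum
#' to the input exactly when `expr_block` is already covariate-adjusted.
#'
#' @param expr_block Transcript [feature_block()] with `positions`.
#' @param genome_block Haplotype-dosage [feature_block()] with columns named
#'   `marker:founder`.
#' @param marker_map `data.frame(marker_id, chromosome, position_bp)`.
#' @param covars Optional covariates, regressed out of both components.
#' @param kinship Optional kinship matrix forwarded to
#'   [fit_local_model()] (relatedness-controlled local fits, recommended
#'   when building local-only / distal-only kernel variants).
#' @return List with `local_block`, `distal_block` (both feature blocks)
#'   and `fits` (per-transcript [fit_local_model()] results).
#' @export
split_local_distal <- function(expr_block, genome_block, marker_map,
                               covars = NULL, kinship = NULL) {
  eig <- if (!is.null(kinship)) eigen(unclass(kinship), symmetric = TRUE)
  pos <- attr(expr_block, "positions")
  if (is.null(pos)) stop("expr_block must carry transcript positions")
  if (!identical(rownames(expr_block), rownames(genome_block))) {
    stop("expression and genome blocks must be aligned on individuals")
  }
  local_m <- distal_m <- matrix(NA_real_, nrow(expr_block), ncol(expr_block),
                                dimnames = dimnames(expr_block))
  fits <- vector("list", ncol(expr_block))
  names(fits) <- colnames(expr_block)
  for (j in seq_len(ncol(expr_block))) {
    tss <- pos[j, ]
    mk <- nearest_marker(tss$chromosome, tss$position_bp, marker_map)
    design <- marker_dosage_columns(genome_block, mk)
    fit <- fit_local_model(expr_block[, j], design, covars = covars,
                           marker_id = mk, kinship = kinship, eig = eig)
    local_m[, j] <- fit$fitted
    distal_m[, j] <- fit$residual
    fits[[j]] <- fit
  }
  list(local_block = as_feature_block(local_m, expr_block, positions = pos),
       distal_block = as_feature_block(distal_m, expr_block, positions = pos),
       fits = fits)
}

# extract the founder-dosage columns of one marker ("marker:founder" naming)
marker_dosage_columns <- function(genome_block, marker_id) {
  idx <- grep(paste0("^", marker_id, ":"), colnames(genome_block))
  if (length(idx) == 0L) stopf("no dosage columns for marker '%s'", marker_id)
  unclass(genome_block)[, idx, drop = FALSE]
}
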