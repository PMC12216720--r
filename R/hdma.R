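#' High-dimensional mediation analysis on kernelized blocks
#'
#' Alternates two updates until the structural parameters stabilize:
#' given current `alpha` (latent genome -> transcriptome coefficient) and
#' `beta` (latent transcriptome -> phenome coefficient), the perfect-mediation
#' log-likelihood reduces to a weighted sum of correlations with weights
#' proportional to `2 alpha / (1 - alpha^2)` and `2 beta / (1 - beta^2)`;
#' the kernel-space loadings are updated by [wsumcor()] with those weights
#' (normalized to sum to 1), scores are recomputed as the standardized
#' kernel projections, and `alpha`, `beta` are refreshed as the score
#' correlations. Iteration stops when both change by less than `tol`.
#'
#' Weight magnitudes use `|alpha|` and `|beta|`; a negative interim value is
#' equivalent to a sign flip of the corresponding latent and is resolved at
#' exit, where scores and loadings are flipped so that `alpha >= 0` and
#' `beta >= 0` (and, optionally, so the phenome score correlates positively
#' with an anchor trait).
#'
#' @param G_K,T_K,P_K Genome, transcriptome and phenome kernels
#'   ([hdma_kernel()] or plain symmetric matrices) over the same
#'   individuals, identically ordered.
#' @param tol Convergence tolerance on the change in `alpha` and `beta`.
#' @param max_iter Maximum outer iterations; on exhaustion the last iterate
#'   is returned with `converged = FALSE` and a warning.
#' @param lambda Shrinkage intensity for the block constraints. The default
#'   `1` is the covariance-form (mode-A) normalization: loadings are
#'   unit-norm up to the block's scale, the standard regularization regime
#'   for kernelized multiblock models, where sample canonical correlations
#'   between n x n Gram blocks are otherwise dominated by chance subspace
#'   alignment. `NULL` requests the analytic Schafer-Strimmer estimate per
#'   block (appropriate for low-dimensional raw blocks), and intermediate
#'   fixed values interpolate.
#' @param init Initialization for the loading vectors, see [wsumcor()].
#' @param anchor Optional numeric vector (e.g. a measured trait) used to fix
#'   the overall sign of the score triple: scores are flipped jointly so
#'   `cor(P_C, anchor) >= 0`.
#' @param inner_tol,inner_max_iter Convergence controls for the inner
#'   [wsumcor()] calls.
#'
#' @return An object of class `"hdma_result"` with elements `alpha`, `beta`,
#'   `path_coefficient` (`alpha * beta`), `kernel_loadings` (list `a`, `b`,
#'   `c` of n-vectors), `scores` (list `G_C`, `T_C`, `P_C`, each mean 0,
#'   variance 1, named by individual), `partials` (partial correlations
#'   `gc_tc_given_pc`, `tc_pc_given_gc`, `gc_pc_given_tc`), `weights`, the
#'   per-iteration `objective_trace` (iteration, alpha, beta, objective),
#'   `lambda`, `n_iter` and `converged`.
#' @export
run_hdma <- function(G_K, T_K, P_K, tol = 1e-6, max_iter = 1000L,
                     lambda = 1, init = "svd", anchor = NULL,
                     inner_tol = 1e-8, inner_max_iter = 200L) {
  ids <- rownames(G_K)
  n <- nrow(G_K)
  if (n < 10L) stop("run_hdma needs at least 10 individuals")
  for (k in list(T_K, P_K)) {
    if (nrow(k) != n) stop("kernels must share dimensions")
    if (!is.null(ids) && !is.null(rownames(k)) &&
        !identical(rownames(k), ids)) {
      stop("kernels must be aligned on identical individuals")
    }
  }
  for (k in list(G_K, T_K, P_K)) {
    if (sum(diag(as.matrix(k))) < n * 1e-12) {
      stop("degenerate kernel: trace is numerically zero")
    }
  }
  setup <- wsumcor_setup(unclass(G_K), unclass(T_K), unclass(P_K),
                         lambda = lambda, scale = FALSE)

  alpha <- 0.5
  beta <- 0.5
  loadings <- NULL
  trace <- vector("list", 0L)
  converged <- FALSE
  iter <- 0L
  w1 <- w2 <- 0.5
  scores <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    a_cl <- clip_structural(alpha)
    b_cl <- clip_structural(beta)
    wa <- 2 * abs(a_cl) / (1 - a_cl^2)
    wb <- 2 * abs(b_cl) / (1 - b_cl^2)
    d <- wa + wb
    if (d < 1e-12) {
      w1 <- w2 <- 0.5
    } else {
      w1 <- wa / d
      w2 <- wb / d
    }
    ws <- wsumcor_core(setup, w1, w2, tol = inner_tol,
                       max_iter = inner_max_iter, init = init,
                       init_loadings = loadings)
    loadings <- ws[c("a", "b", "c")]
    scores <- list(G_C = standardize_vec(drop(setup$x$B %*% ws$a)),
                   T_C = standardize_vec(drop(setup$m$B %*% ws$b)),
                   P_C = standardize_vec(drop(setup$y$B %*% ws$c)))
    alpha_new <- stats::cor(scores$G_C, scores$T_C)
    beta_new <- stats::cor(scores$T_C, scores$P_C)
    trace[[iter]] <- c(iter = iter, alpha = alpha_new, beta = beta_new,
                       objective = utils::tail(ws$objective_trace, 1L) %||% NA_real_)
    if (abs(alpha_new - alpha) < tol && abs(beta_new - beta) < tol) {
      alpha <- alpha_new
      beta <- beta_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
    beta <- beta_new
  }
  if (!converged) {
    warnf("run_hdma did not converge in %d iterations", max_iter)
  }

  # sign fixing: alpha and beta reported non-negative
  if (alpha < 0) {
    scores$G_C <- -scores$G_C
    loadings$a <- -loadings$a
    alpha <- -alpha
  }
  if (beta < 0) {
    scores$P_C <- -scores$P_C
    loadings$c <- -loadings$c
    beta <- -beta
  }
  if (!is.null(anchor)) {
    if (length(anchor) != n) stop("anchor must have one value per individual")
    if (stats::cor(scores$P_C, anchor) < 0) {
      scores <- lapply(scores, `-`)
      loadings <- lapply(loadings, `-`)
    }
  }
  if (!is.null(ids)) scores <- lapply(scores, stats::setNames, ids)

  partials <- c(
    gc_tc_given_pc = partial_correlation(scores$G_C, scores$T_C, scores$P_C),
    tc_pc_given_gc = partial_correlation(scores$T_C, scores$P_C, scores$G_C),
    gc_pc_given_tc = partial_correlation(scores$G_C, scores$P_C, scores$T_C))

  trace_df <- as.data.frame(do.call(rbind, trace))
  structure(list(alpha = alpha, beta = beta,
                 path_coefficient = alpha * beta,
                 kernel_loadings = loadings, scores = scores,
                 partials = partials,
                 weights = c(w1 = w1, w2 = w2),
                 objective_trace = trace_df,
                 lambda = c(x = setup$x$lambda, m = setup$m$lambda,
                            y = setup$y$lambda),
                 n_iter = iter, converged = converged,
                 individual_ids = ids),
            class = "hdma_result")
}

clip_structural <- function(x) {
  lim <- 1 - 1e-12
  if (abs(x) >= lim) {
    warnf("structural parameter at %.3f clipped to +/-%g", x, lim)
    x <- sign(x) * lim
  }
  x
}

#' @export
print.hdma_result <- function(x, ...) {
  cat("High-dimensional mediation result\n")
  cat(sprintf("  n = %d individuals, %d iterations (%s)\n",
              length(x$scores$G_C), x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  alpha (G_C~T_C) = %.4f, beta (T_C~P_C) = %.4f\n",
              x$alpha, x$beta))
  cat(sprintf("  path coefficient = %.4f\n", x$path_coefficient))
  cat(sprintf("  partial cor G_C,P_C | T_C = %.4f\n",
              x$partials["gc_pc_given_tc"]))
  invisible(x)
}

#' Path coefficient of a mediation result
#'
#' The strength of the mediated pathway: the product of the latent
#' genome-transcriptome and transcriptome-phenome correlations.
#'
#' @param alpha Either an `"hdma_result"` or the numeric latent
#'   genome -> transcriptome coefficient.
#' @param beta Numeric latent transcriptome -> phenome coefficient (ignored
#'   when `alpha` is a result object).
#' @return `alpha * beta`.
#' @export
path_coefficient <- function(alpha, beta = NULL) {
  if (inherits(alpha, "hdma_result")) return(alpha$alpha * alpha$beta)
  if (is.null(beta)) stop("supply beta or an hdma_result")
  alpha * beta
}

#' Partial correlation of two vectors given a third
#'
#' Pearson correlation of the residuals of `u` and `v` after regression on
#' `w` (with intercept); equals
#' `(r_uv - r_uw r_vw) / sqrt((1 - r_uw^2)(1 - r_vw^2))`.
#'
#' @param u,v,w Numeric vectors of equal length, non-constant.
#' @return A single correlation in \[-1, 1\].
#' @export
partial_correlation <- function(u, v, w) {
  r_uv <- stats::cor(u, v)
  r_uw <- stats::cor(u, w)
  r_vw <- stats::cor(v, w)
  if (abs(r_uw) >= 1 - 1e-12 || abs(r_vw) >= 1 - 1e-12) {
    stop("degenerate conditioning: conditioning variable collinear with input")
  }
  (r_uv - r_uw * r_vw) / sqrt((1 - r_uw^2) * (1 - r_vw^2))
}

#' Back-project a kernel-space loading onto features
#'
#' A kernel-space loading `a~` (one coefficient per individual) is mapped to
#' per-feature loadings `a = X' a~`, then rescaled so the feature-space
#' score `X a` has unit variance. Because `X (X' a~) = (X X') a~`, the
#' feature-space score reproduces the kernel-space score exactly (up to the
#' common standardization). Per-tissue loadings are obtained by applying
#' each tissue's preprocessed matrix to the shared transcriptome loading.
#'
#' @param kernel_loading Numeric n-vector from an [run_hdma()] result.
#' @param block The preprocessed [feature_block()] (or matrix) whose Gram
#'   kernel entered the analysis.
#' @param scale_features Must match the `scale_features` used in
#'   [gram_kernel()] for this block.
#' @return Named numeric vector of per-feature loadings.
#' @export
feature_loadings <- function(kernel_loading, block, scale_features = TRUE) {
  if (length(kernel_loading) != nrow(block)) {
    stop("kernel loading length must equal the block's individual count")
  }
  x <- if (scale_features) standardize_cols(unclass(block))
       else center_cols(unclass(block))
  loading <- drop(crossprod(x, kernel_loading))
  s <- stats::sd(drop(x %*% loading))
  if (s < .Machine$double.eps) stop("degenerate loading: constant score")
  stats::setNames(loading / s, colnames(block))
}

#' Summarize a mediation result against the measured phenome
#'
#' Reports the partial correlations and path coefficient together with the
#' share of measured trait variance captured by the composite phenome score
#' (`100 x` the mean squared correlation of `P_C` with each trait) and the
#' per-trait loadings.
#'
#' @param result A converged [run_hdma()] result.
#' @param phenome The preprocessed phenome [feature_block()] whose kernel
#'   entered the analysis.
#' @param scale_features As used when kernelizing the phenome.
#' @return A list of class `"mediation_summary"`.
#' @export
mediation_summary <- function(result, phenome, scale_features = TRUE) {
  pc <- result$scores$P_C
  if (length(pc) != nrow(phenome)) {
    stop("phenome block does not match the result's individuals")
  }
  r2 <- as.vector(stats::cor(unclass(phenome), pc))^2
  structure(list(partials = result$partials,
                 path_coefficient = result$path_coefficient,
                 pct_phenome_variance = 100 * mean(r2),
                 trait_r2 = stats::setNames(r2, colnames(phenome)),
                 trait_loadings = feature_loadings(result$kernel_loadings$c,
                                                  phenome, scale_features)),
            class = "mediation_summary")
}

#' @export
print.mediation_summary <- function(x, ...) {
  cat("Mediation summary\n")
  cat(sprintf("  path coefficient = %.4f\n", x$path_coefficient))
  cat(sprintf("  %% phenome variance captured by P_C = %.1f\n",
              x$pct_phenome_variance))
  invisible(x)
}

#' Run the mediation model with local-only and distal-only transcriptome kernels
#'
#' Re-runs [run_hdma()] replacing the transcriptome kernel by each of the
#' two variants built from [split_local_distal()] output: the local-only
#' kernel (Gram of locally-imputed expression) and the distal-only kernel
#' (Gram of local-model residuals). Used to dissociate which part of the
#' regulated transcriptome carries the mediated signal.
#'
#' @param G_K,P_K Genome and phenome kernels.
#' @param local_T_K,distal_T_K Transcriptome kernel variants.
#' @param ... Passed to [run_hdma()].
#' @return List with elements `local`, `distal` (both `"hdma_result"`) and
#'   `comparison`, a `data.frame` of (variant, alpha, beta, path
#'   coefficient) pairs.
#' @export
run_variant_kernels <- function(G_K, local_T_K, distal_T_K, P_K, ...) {
  res_local <- run_hdma(G_K, local_T_K, P_K, ...)
  res_distal <- run_hdma(G_K, distal_T_K, P_K, ...)
  comparison <- data.frame(
    variant = c("local_only", "distal_only"),
    gc_tc_cor = c(res_local$alpha, res_distal$alpha),
    tc_pc_cor = c(res_local$beta, res_distal$beta),
    path_coefficient = c(res_local$path_coefficient,
                         res_distal$path_coefficient))
  list(local = res_local, distal = res_distal, comparison = comparison)
}
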