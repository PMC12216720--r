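#' Schafer-Strimmer shrinkage covariance
#'
#' Analytic shrinkage of a sample covariance toward the identity, used to
#' regularize the per-block normalization constraints of the SUMCOR
#' optimizer. With column-standardized input the sample covariance is the
#' correlation matrix `S` and the shrinkage intensity is
#' `lambda* = clip( sum_{i != j} Var-hat(s_ij) / sum_{i != j} s_ij^2, 0, 1)`,
#' estimated in closed form with no cross-validation. The returned matrix is
#' `(1 - lambda*) S + lambda* I`, whose eigenvalues are floored at
#' `lambda*`.
#'
#' @param X n x p matrix with column-standardized data (n >= 3).
#' @param lambda Optional fixed intensity overriding the analytic estimate
#'   (used in tests and for unregularized small problems).
#' @return A list of class `"shrunk_cov"` with elements `lambda` and
#'   `matrix`.
#' @export
shrink_covariance <- function(X, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3L) stop("shrink_covariance needs n >= 3")
  if (p == 1L) {
    return(structure(list(lambda = 0, matrix = matrix(1, 1, 1)),
                     class = "shrunk_cov"))
  }
  S <- crossprod(X) / (n - 1)
  lam <- if (is.null(lambda)) shrinkage_intensity(X) else lambda
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  out <- (1 - lam) * S
  diag(out) <- diag(out) + lam
  structure(list(lambda = lam, matrix = out), class = "shrunk_cov")
}

# closed-form intensity: ratio of summed sampling variances of the
# off-diagonal covariances to their summed squares (identity target)
shrinkage_intensity <- function(X) {
  n <- nrow(X)
  R <- crossprod(X) / (n - 1)
  W2 <- crossprod(X^2)           # sum_k x_ki^2 x_kj^2
  Wbar <- crossprod(X) / n       # mean_k x_ki x_kj
  # Var-hat(s_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2
  var_s <- n^2 / (n - 1)^3 * (W2 / n - Wbar^2)
  off <- upper.tri(R)
  den <- sum(R[off]^2)
  if (den <= .Machine$double.eps) return(1)
  min(1, max(0, sum(var_s[off]) / den))
}

# Precompute the per-block state reused across repeated wSUMCOR calls with
# different weights (the outer mediation loop re-enters with new w1, w2 but
# unchanged data, so covariance shrinkage and Cholesky factors are done
# once). Blocks are column-centered; with scale = TRUE also standardized.
# The constraint matrix is (1 - lambda) S + lambda * nu * I with
# nu = mean(diag(S)), which reduces to the identity-target form on
# standardized columns and makes the constraint scale with the block, so
# scores are exactly invariant to positive rescaling of a block.
wsumcor_setup <- function(X, M, Y, lambda = NULL, scale = FALSE) {
  prep <- function(B, lam) {
    B <- if (scale) standardize_cols(as.matrix(B)) else center_cols(as.matrix(B))
    n <- nrow(B)
    S <- crossprod(B) / (n - 1)
    nu <- mean(diag(S))
    if (nu <= 0) stop("degenerate block: zero variance in every column")
    if (is.null(lam)) lam <- shrinkage_intensity(B / sqrt(nu))
    Cmat <- (1 - lam) * S
    diag(Cmat) <- diag(Cmat) + lam * nu
    R <- tryCatch(chol(Cmat), error = function(e) {
      jitter <- 1e-10 * nu
      chol(Cmat + diag(jitter, ncol(Cmat)))
    })
    list(B = B, R = R, lambda = lam)
  }
  lams <- if (is.null(lambda)) list(NULL, NULL, NULL) else as.list(rep_len(lambda, 3L))
  list(x = prep(X, lams[[1L]]), m = prep(M, lams[[2L]]), y = prep(Y, lams[[3L]]),
       n = nrow(as.matrix(X)))
}

# maximize t(v) %*% g subject to t(v) %*% C %*% v = 1, C = t(R) %*% R:
# v = C^{-1} g / sqrt(t(g) %*% C^{-1} g)
constrained_max <- function(R, g) {
  u <- backsolve(R, forwardsolve(t(R), g))
  nrm <- sqrt(sum(g * u))
  if (!is.finite(nrm) || nrm < 1e-300) {
    stop("degenerate block: zero neighbour score direction")
  }
  u / nrm
}

dominant_right_singular <- function(B) {
  # dgesdd occasionally fails to converge on near-degenerate inputs; the
  # symmetric eigensolver on the smaller cross-product is robust
  if (nrow(B) <= ncol(B)) {
    u <- eigen(tcrossprod(B), symmetric = TRUE)$vectors[, 1L]
    v <- drop(crossprod(B, u))
    v / sqrt(sum(v^2))
  } else {
    eigen(crossprod(B), symmetric = TRUE)$vectors[, 1L]
  }
}

init_loading <- function(B, R, how, seed_vec = NULL) {
  v <- if (!is.null(seed_vec)) seed_vec
  else if (identical(how, "svd")) dominant_right_singular(B)
  else stats::rnorm(ncol(B))
  # rescale to satisfy the constraint
  q <- drop(crossprod(R %*% v))
  v / sqrt(q)
}

wsumcor_core <- function(setup, w1, w2, tol = 1e-8, max_iter = 500L,
                         init = "svd", init_loadings = NULL) {
  X <- setup$x$B; M <- setup$m$B; Y <- setup$y$B
  Rx <- setup$x$R; Rm <- setup$m$R; Ry <- setup$y$R
  n1 <- setup$n - 1
  a <- init_loading(X, Rx, init, init_loadings$a)
  b <- init_loading(M, Rm, init, init_loadings$b)
  cc <- init_loading(Y, Ry, init, init_loadings$c)
  sx <- drop(X %*% a); sm <- drop(M %*% b); sy <- drop(Y %*% cc)
  inner_obj <- function() (w1 * sum(sx * sm) + w2 * sum(sm * sy)) / n1
  trace <- numeric(0)
  f_old <- inner_obj()
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (w1 > 0) {
      a <- constrained_max(Rx, crossprod(X, sm) / n1)
      sx <- drop(X %*% a)
    }
    g_m <- crossprod(M, w1 * sx + w2 * sy) / n1
    if (w1 > 0 || w2 > 0) {
      b <- constrained_max(Rm, g_m)
      sm <- drop(M %*% b)
    }
    if (w2 > 0) {
      cc <- constrained_max(Ry, crossprod(Y, sm) / n1)
      sy <- drop(Y %*% cc)
    }
    f_new <- inner_obj()
    trace <- c(trace, f_new)
    if (abs(f_new - f_old) < tol) {
      converged <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  structure(list(a = drop(a), b = drop(b), c = drop(cc),
                 objective = NA_real_, objective_trace = trace,
                 converged = converged, n_iter = iter,
                 lambda = c(x = setup$x$lambda, m = setup$m$lambda,
                            y = setup$y$lambda)),
            class = "block_loadings")
}

#' Weighted sum-of-correlations (SUMCOR) over three chained blocks
#'
#' Block-coordinate ascent on
#' `L = w1 * corr(X a, M b) + w2 * corr(M b, Y c)` for the chain design
#' X -- M -- Y (Horst scheme: plain correlations, no absolute value or
#' square). Each update solves the constrained maximization of the block's
#' linear term against the weighted sum of its neighbours' current scores:
#' with constraint matrix `C_j` (the shrunk block covariance) the maximizer
#' of `v' g` under `v' C_j v = 1` is `C_j^{-1} g` renormalized, which is the
#' exact correlation-form update because each score's scale is pinned by its
#' constraint-induced norm. The recorded objective trace is the constrained
#' covariance form, which coincides with the correlation form at lambda = 0
#' and is non-decreasing at every step by construction of the updates.
#'
#' @param X,M,Y n x p_j numeric blocks on the same individuals.
#' @param w1,w2 Non-negative weights summing to 1 for the X--M and M--Y
#'   edges.
#' @param lambda Optional shrinkage intensity (scalar or length-3) forced on
#'   every block; `NULL` (default) uses the analytic Schafer-Strimmer
#'   estimate per block.
#' @param scale Standardize block columns to unit variance first.
#' @param tol Convergence tolerance on the objective improvement.
#' @param max_iter Maximum coordinate-ascent sweeps.
#' @param init `"svd"` (deterministic, dominant right singular vector) or
#'   `"random"`.
#' @return An object of class `"block_loadings"`: loadings `a`, `b`, `c`
#'   (each normalized so `v' C_j v = 1`), the per-iteration
#'   `objective_trace`, the final Pearson-form `objective`, `converged`,
#'   `n_iter` and per-block shrinkage `lambda`.
#' @export
wsumcor <- function(X, M, Y, w1, w2, lambda = NULL, scale = FALSE,
                    tol = 1e-8, max_iter = 500L, init = c("svd", "random")) {
  init <- match.arg(init)
  if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  setup <- wsumcor_setup(X, M, Y, lambda = lambda, scale = scale)
  out <- wsumcor_core(setup, w1, w2, tol = tol, max_iter = max_iter,
                      init = init)
  out$objective <- wsumcor_objective(setup$x$B, setup$m$B, setup$y$B,
                                     out$a, out$b, out$c, w1, w2)
  out
}

#' Pearson-form SUMCOR objective
#'
#' `w1 * corr(X a, M b) + w2 * corr(M b, Y c)` with plain Pearson
#' correlations of the block scores.
#'
#' @inheritParams wsumcor
#' @param a,b,c Loading vectors.
#' @return A single numeric value.
#' @export
wsumcor_objective <- function(X, M, Y, a, b, c, w1, w2) {
  sx <- drop(as.matrix(X) %*% a)
  sm <- drop(as.matrix(M) %*% b)
  sy <- drop(as.matrix(Y) %*% c)
  for (s in list(sx, sm, sy)) {
    if (stats::sd(s) < .Machine$double.eps) {
      stop("constant score vector: objective undefined")
    }
  }
  w1 * stats::cor(sx, sm) + w2 * stats::cor(sm, sy)
}
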