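# shared fixture builders; everything is generated in code

tiny_block <- function(n = 5, p = 3, role = "transcriptome", seed = 1) {
  set.seed(seed)
  feature_block(matrix(rnorm(n * p), n, p,
                       dimnames = list(sprintf("m%02d", seq_len(n)),
                                       sprintf("f%02d", seq_len(p)))),
                block_role = role)
}

# n x p matrix whose sample correlation matrix is exactly `target`
# (empirically whiten iid columns, then apply the Cholesky factor)
exact_corr_data <- function(n, target, seed = 1) {
  set.seed(seed)
  p <- ncol(target)
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, scale = FALSE)
  z <- z %*% solve(chol(cov(z)))   # sample covariance exactly I
  z %*% chol(target)
}

small_population <- function(n = 120, seed = 1, ...) {
  simulate_mediation_population(n = n, seed = seed, ...)
}
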