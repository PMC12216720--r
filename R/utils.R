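# internal helpers shared across modules

# column-center a matrix
center_cols <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# center and scale columns to unit sample variance; zero-variance columns
# are left centered (all-zero) rather than producing NaN
standardize_cols <- function(x) {
  x <- center_cols(x)
  s <- apply(x, 2L, stats::sd)
  s[s < .Machine$double.eps] <- 1
  sweep(x, 2L, s, "/")
}

# standardize a vector to mean 0, variance 1
standardize_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) {
    stop("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
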