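#' Construct and validate an individual-similarity kernel
#'
#' A kernel is an n x n symmetric positive-semidefinite Gram matrix over
#' individuals, tagged with the omics block it came from and whether it was
#' built from full, local-only or distal-only signal.
#'
#' @param values Square numeric matrix with identical row/column ids.
#' @param block_role Origin block role (genome/transcriptome/phenome).
#' @param variant One of `"full"`, `"local_only"`, `"distal_only"`.
#' @return An object of class `"hdma_kernel"`.
#' @export
hdma_kernel <- function(values, block_role = "transcriptome",
                        variant = c("full", "local_only", "distal_only")) {
  variant <- match.arg(variant)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("kernel must be square")
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("ind", seq_len(n))
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("kernel row and column ids must match")
  }
  if (max(abs(values - t(values))) > 1e-10 * max(1, max(abs(values)))) {
    stop("kernel is not symmetric to tolerance 1e-10")
  }
  values <- (values + t(values)) / 2
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(sum(diag(values)), .Machine$double.eps) / n
  if (min(ev) < -tol) {
    stopf("kernel is not positive semidefinite (min eigenvalue %.3e)", min(ev))
  }
  structure(values, class = c("hdma_kernel", "matrix", "array"),
            block_role = block_role, variant = variant)
}

#' @export
print.hdma_kernel <- function(x, ...) {
  cat(sprintf("<hdma_kernel role=%s variant=%s> %d x %d individuals\n",
              attr(x, "block_role"), attr(x, "variant"), nrow(x), ncol(x)))
  invisible(x)
}

#' Gram kernel of a feature block
#'
#' Reduces an individuals x features block to the n x n matrix of
#' covariance-type similarities among individuals, `K = X X^T`, after
#' column centering (always) and optional per-feature unit-variance scaling.
#' This is the linear kernelization that lets loading vectors be restricted
#' to the span of the observed individuals.
#'
#' @param block A [feature_block()].
#' @param scale_features Scale each feature to unit variance before the
#'   cross-product, so features contribute equally.
#' @return An [hdma_kernel()] carrying the block's role.
#' @export
gram_kernel <- function(block, scale_features = TRUE) {
  if (ncol(block) == 0L) stop("block has no features")
  x <- if (scale_features) standardize_cols(block) else center_cols(block)
  k <- tcrossprod(x)
  dimnames(k) <- list(rownames(block), rownames(block))
  hdma_kernel(k, block_role = attr(block, "block_role") %||% "transcriptome")
}

#' Combine per-tissue kernels into one transcriptome kernel
#'
#' Each kernel is trace-normalized (scaled so its trace equals n) and the
#' normalized kernels are summed, then the sum is trace-normalized again.
#' This equals, up to a global scale, the Gram kernel of the column-wise
#' standardized concatenation of the tissue blocks, and is scale-fair across
#' tissues with different transcript counts.
#'
#' @param kernels List of [hdma_kernel()] objects on identical individuals.
#' @return A single combined [hdma_kernel()].
#' @export
combine_tissue_kernels <- function(kernels) {
  if (!is.list(kernels) || length(kernels) < 1L) stop("need at least one kernel")
  ids <- rownames(kernels[[1L]])
  n <- length(ids)
  for (k in kernels) {
    if (!identical(rownames(k), ids)) {
      stop("kernels must share identical individual ids and order")
    }
  }
  norm1 <- function(k) {
    tr <- sum(diag(k))
    if (tr <= 0) stop("kernel with non-positive trace cannot be normalized")
    unclass(k) * (n / tr)
  }
  total <- Reduce(`+`, lapply(kernels, norm1))
  total <- total * (n / sum(diag(total)))
  hdma_kernel(total, block_role = attr(kernels[[1L]], "block_role"),
              variant = attr(kernels[[1L]], "variant"))
}

#' Write / read a kernel as square TSV with ids on both axes
#' @param kernel An [hdma_kernel()].
#' @param path Output path.
#' @export
write_kernel_tsv <- function(kernel, path) {
  write_matrix_tsv(unclass(kernel), path, id_col = "individual_id")
}

#' @rdname write_kernel_tsv
#' @param block_role,variant Metadata to attach on read.
#' @export
read_kernel_tsv <- function(path, block_role = "transcriptome",
                            variant = "full") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  hdma_kernel(as.matrix(tab), block_role = block_role, variant = variant)
}
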