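#' Construct a feature block
#'
#' A feature block is the basic data container of the package: a numeric
#' matrix of individuals (rows) by features (columns) with unique row and
#' column identifiers, an assigned role, and optional genomic positions for
#' the features (used for nearest-marker lookups).
#'
#' @param values Numeric matrix, individuals in rows, features in columns.
#'   Dimnames are used as identifiers when `individual_ids`/`feature_ids`
#'   are not given.
#' @param block_role One of `"genome"`, `"transcriptome"`, `"phenome"`,
#'   `"covariates"`.
#' @param individual_ids,feature_ids Character vectors of unique identifiers.
#' @param positions Optional `data.frame` with columns `feature_id`,
#'   `chromosome`, `position_bp` (1-based), one row per feature.
#'
#' @return An object of class `"feature_block"`: the numeric matrix with
#'   attributes `block_role` and (optionally) `positions`.
#' @export
feature_block <- function(values, block_role = c("genome", "transcriptome",
                                                 "phenome", "covariates"),
                          individual_ids = NULL, feature_ids = NULL,
                          positions = NULL) {
  block_role <- match.arg(block_role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(individual_ids)) rownames(values) <- individual_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("ind", seq_len(nrow(values)))
  }
  if (is.null(colnames(values)) && ncol(values) > 0L) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  check_unique_ids(rownames(values), "individual")
  check_unique_ids(colnames(values), "feature")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stopf("non-finite value at individual '%s', feature '%s'",
          rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  }
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    need <- c("feature_id", "chromosome", "position_bp")
    if (!all(need %in% names(positions))) {
      stopf("positions must have columns %s", paste(need, collapse = ", "))
    }
    if (!setequal(positions$feature_id, colnames(values)) ||
        nrow(positions) != ncol(values)) {
      stop("positions must contain exactly one row per feature")
    }
    positions <- positions[match(colnames(values), positions$feature_id), ]
    rownames(positions) <- NULL
  }
  structure(values, class = c("feature_block", "matrix", "array"),
            block_role = block_role, positions = positions)
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stopf("duplicate %s id(s): %s", what,
          paste(utils::head(dup, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block role=%s> %d individuals x %d features\n",
              attr(x, "block_role"), nrow(x), ncol(x)))
  if (!is.null(attr(x, "positions"))) cat("  with feature positions\n")
  invisible(x)
}

block_role <- function(x) attr(x, "block_role")
block_positions <- function(x) attr(x, "positions")

# rebuild a feature_block from a plain matrix, keeping metadata from template
as_feature_block <- function(values, template, positions = NULL) {
  feature_block(values, block_role = attr(template, "block_role"),
                positions = positions %||% {
                  pos <- attr(template, "positions")
                  if (!is.null(pos) &&
                      setequal(pos$feature_id, colnames(values))) pos else NULL
                })
}

#' Read a feature block from a delimited text file
#'
#' Reads a TSV or CSV matrix with one header row and the identifiers in the
#' first column. Files stored features-by-individuals are transposed on load
#' so the returned block is always individuals by features.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param orientation Layout of the file on disk.
#' @param block_role Role assigned to the returned block.
#' @param positions Optional positions table, see [feature_block()].
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#'
#' @return A [feature_block()] in individuals-by-features orientation, row
#'   and column order preserved from the file.
#' @export
read_feature_block <- function(path,
                               orientation = c("individuals_by_features",
                                               "features_by_individuals"),
                               block_role = "transcriptome",
                               positions = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  lines <- readLines(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stopf("ragged row at line %d (%d fields, expected %d)", bad, nf[bad], nf[1L])
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  check_unique_ids(ids, "row")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  check_unique_ids(colnames(m), "column")
  if (orientation == "features_by_individuals") m <- t(m)
  feature_block(m, block_role = block_role, positions = positions)
}

#' Write a feature block (or any matrix) as TSV
#'
#' Values are written in full-precision scientific notation (17 significant
#' digits) so that write/read round-trips are bit-lossless.
#'
#' @param x Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x),
                   apply(x, 2L, function(col) sprintf("%.16e", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict blocks to their shared individuals
#'
#' All blocks are reduced to the intersection of their individual ids and
#' reordered into a single canonical (lexicographic) order, so downstream
#' kernels are aligned regardless of input row order. Individuals with any
#' missing (non-finite) entry in a block never occur here because
#' [feature_block()] rejects non-finite values at load time.
#'
#' @param blocks A list of two or more [feature_block()] objects.
#' @param verbose Report the number of individuals dropped per block.
#' @return A list of blocks, all with identical, lexicographically ordered
#'   individual ids.
#' @export
align_individuals <- function(blocks, verbose = FALSE) {
  if (!is.list(blocks) || length(blocks) < 2L) {
    stop("align_individuals needs a list of at least two blocks")
  }
  shared <- Reduce(intersect, lapply(blocks, rownames))
  if (length(shared) == 0L) stop("no individuals shared across blocks")
  shared <- sort(shared)
  out <- lapply(blocks, function(b) {
    dropped <- nrow(b) - length(shared)
    if (verbose && dropped > 0L) {
      message(sprintf("align_individuals: dropped %d individual(s) from %s block",
                      dropped, attr(b, "block_role")))
    }
    as_feature_block(b[shared, , drop = FALSE], b,
                     positions = attr(b, "positions"))
  })
  names(out) <- names(blocks)
  out
}
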