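#' Read a flat key-value run configuration
#'
#' The configuration format is flat `key = value` (or `key: value`) lines;
#' blank lines and `#` comments are ignored. Recognized numeric keys
#' (`tol`, `max_iter`, `n_perm`, `seed`, ...) are coerced.
#'
#' @param path Path to the configuration file.
#' @return A named list of class `"run_config"` with defaults filled in
#'   (`tol = 1e-6`, `max_iter = 1000`, `n_perm = 1000`, `seed = 1`).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stopf("malformed config line: '%s'", lines[bad[1L]])
  cfg <- stats::setNames(lapply(kv, function(x) trimws(x[3L])),
                         vapply(kv, function(x) trimws(x[2L]), ""))
  numeric_keys <- c("tol", "max_iter", "n_perm", "seed", "n", "n_transcripts",
                    "n_traits", "local_frac", "distal_frac", "alpha_true",
                    "beta_true", "switch_prob", "direct_effect")
  for (k in intersect(names(cfg), numeric_keys)) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  cfg <- utils::modifyList(list(tol = 1e-6, max_iter = 1000, n_perm = 1000,
                                seed = 1), cfg)
  if (cfg$tol <= 0) stop("tol must be positive")
  if (cfg$n_perm < 1) stop("n_perm must be at least 1")
  structure(cfg, class = c("run_config", "list"))
}

#' Write the tables of a mediation run to a directory
#'
#' Emits a scores table (`individual_id`, `G_C`, `T_C`, `P_C`), one loading
#' table per supplied block (`feature_id`, `loading`), and a summary table
#' (alpha, beta, path coefficient, partial correlations, iterations,
#' convergence flag, seed). All floating values are written in
#' full-precision scientific notation; a `manifest.tsv` lists every file
#' with its MD5 checksum.
#'
#' @param result An [run_hdma()] result (converged or not).
#' @param out_dir Output directory, created if needed.
#' @param loadings Optional named list of per-feature loading vectors (e.g.
#'   from [feature_loadings()]); each becomes `loadings_<name>.tsv`.
#' @param seed Seed recorded in the summary.
#' @return Invisibly, the manifest `data.frame` (file, md5).
#' @export
write_result_tables <- function(result, out_dir, loadings = NULL, seed = NA) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    stopf("cannot write to directory '%s'", out_dir)
  }
  fmt <- function(x) sprintf("%.16e", x)
  files <- character(0)

  scores_path <- file.path(out_dir, "scores.tsv")
  ids <- result$individual_ids %||% names(result$scores$G_C) %||%
    paste0("ind", seq_along(result$scores$G_C))
  utils::write.table(
    data.frame(individual_id = ids, G_C = fmt(result$scores$G_C),
               T_C = fmt(result$scores$T_C), P_C = fmt(result$scores$P_C)),
    scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, scores_path)

  for (nm in names(loadings)) {
    p <- file.path(out_dir, paste0("loadings_", nm, ".tsv"))
    utils::write.table(
      data.frame(feature_id = names(loadings[[nm]]),
                 loading = fmt(loadings[[nm]])),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }

  summary_path <- file.path(out_dir, "summary.tsv")
  summ <- data.frame(
    key = c("alpha", "beta", "path_coefficient",
            names(result$partials), "n_iter", "converged", "seed"),
    value = c(fmt(c(result$alpha, result$beta, result$path_coefficient,
                    result$partials)),
              as.character(result$n_iter),
              tolower(as.character(result$converged)),
              as.character(seed)))
  utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, summary_path)

  manifest <- data.frame(file = basename(files),
                         md5 = vapply(files, function(f) tools::md5sum(f)[[1L]], ""))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read back a scores table written by [write_result_tables()]
#' @param path Path to `scores.tsv`.
#' @return `data.frame` with numeric score columns.
#' @export
read_scores_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  for (col in c("G_C", "T_C", "P_C")) tab[[col]] <- as.numeric(tab[[col]])
  tab
}
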