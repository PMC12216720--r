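#' Re-key a loading vector through an ortholog / identifier map
#'
#' Maps per-feature loadings (e.g. mouse transcript loadings) onto a new
#' identifier space (e.g. human genes). Features without a mapping are
#' dropped and counted; a source id mapping to several targets propagates
#' its loading to each target; several sources mapping to one target are
#' averaged.
#'
#' @param loadings Named numeric vector of loadings in the source id space.
#' @param id_map `data.frame` (or two-column matrix) with columns
#'   `source_id`, `target_id`.
#' @return A list of class `"loading_vector"` with `loadings` (named by
#'   target id), `n_mapped`, `n_dropped`.
#' @export
map_orthologs <- function(loadings, id_map) {
  id_map <- as.data.frame(id_map)
  if (ncol(id_map) < 2L) stop("id_map needs two columns (source, target)")
  names(id_map)[1:2] <- c("source_id", "target_id")
  hit <- id_map[id_map$source_id %in% names(loadings), , drop = FALSE]
  mapped_sources <- unique(hit$source_id)
  n_dropped <- length(loadings) - length(mapped_sources)
  if (nrow(hit) == 0L) stop("no loading feature has a mapping")
  vals <- loadings[hit$source_id]
  out <- tapply(vals, hit$target_id, mean)
  structure(list(loadings = stats::setNames(as.numeric(out), names(out)),
                 n_mapped = length(mapped_sources), n_dropped = n_dropped),
            class = "loading_vector")
}

#' Predict a metabolic disease index from expression and loadings
#'
#' For every individual of a new cohort, standardizes each matched
#' transcript across the cohort's individuals (mean 0, variance 1),
#' multiplies by the training loading, and averages over matched
#' transcripts. Higher values predict a higher disease index. Features of
#' the loading vector absent from the expression data are dropped and
#' counted.
#'
#' @param expr_new Expression [feature_block()] (individuals x transcripts)
#'   for the new cohort.
#' @param loadings Named numeric vector or a `"loading_vector"` from
#'   [map_orthologs()].
#' @return A list of class `"mdi_prediction"` with `predicted_mdi` (named
#'   numeric per individual), `n_features_used`, `n_features_dropped`.
#' @export
predict_mdi <- function(expr_new, loadings) {
  if (inherits(loadings, "loading_vector")) loadings <- loadings$loadings
  shared <- intersect(names(loadings), colnames(expr_new))
  if (length(shared) == 0L) stop("no overlapping features between loadings and expression")
  x <- standardize_cols(unclass(expr_new)[, shared, drop = FALSE])
  pred <- drop(x %*% loadings[shared]) / length(shared)
  structure(list(predicted_mdi = stats::setNames(pred, rownames(expr_new)),
                 n_features_used = length(shared),
                 n_features_dropped = length(loadings) - length(shared)),
            class = "mdi_prediction")
}

#' Evaluate predicted disease index against an observed trait
#'
#' Simple linear regression of the observed trait on the prediction. In
#' group mode (e.g. per-strain replicates), observed values and predictions
#' are first averaged within group and the regression is across group
#' means.
#'
#' @param pred An `"mdi_prediction"` or named numeric vector.
#' @param observed_trait Named numeric vector of observed values.
#' @param groups Optional grouping factor (same length/names as
#'   `observed_trait`) for per-group averaging.
#' @return A list of class `"prediction_fit"`: `r_squared`, `slope`,
#'   `slope_se`, `t`, `p_value`, `n`.
#' @export
evaluate_prediction <- function(pred, observed_trait, groups = NULL) {
  p <- if (inherits(pred, "mdi_prediction")) pred$predicted_mdi else pred
  if (!is.null(names(p)) && !is.null(names(observed_trait))) {
    shared <- intersect(names(p), names(observed_trait))
    p <- p[shared]
    observed_trait <- observed_trait[shared]
    if (!is.null(groups) && !is.null(names(groups))) groups <- groups[shared]
  }
  if (!is.null(groups)) {
    p <- tapply(p, groups, mean)
    observed_trait <- tapply(observed_trait, groups, mean)
  }
  if (length(p) < 3L) stop("need at least three groups or individuals")
  if (stats::sd(p) < .Machine$double.eps) stop("zero-variance predictions")
  fit <- stats::lm(observed_trait ~ p)
  sm <- summary(fit)
  structure(list(r_squared = sm$r.squared,
                 slope = sm$coefficients["p", "Estimate"],
                 slope_se = sm$coefficients["p", "Std. Error"],
                 t = sm$coefficients["p", "t value"],
                 p_value = sm$coefficients["p", "Pr(>|t|)"],
                 n = length(p)),
            class = "prediction_fit")
}

#' Compare predicted disease index between two groups
#'
#' Without replicates: Welch's unequal-variance t-test on the two groups.
#' With technical replicates (`replicate_ids` given), values are averaged
#' per subject first and the Welch test is applied to the subject-level
#' means; a random-intercept model is the natural alternative for
#' replicated designs but subject-level averaging is the supported path.
#'
#' @param pred An `"mdi_prediction"` or numeric vector.
#' @param group_labels Factor/character with exactly two levels.
#' @param replicate_ids Optional subject identifiers marking technical
#'   replicates.
#' @return The `htest` object from [stats::t.test()], with an added
#'   `$note` when replicate averaging was applied.
#' @export
group_comparison <- function(pred, group_labels, replicate_ids = NULL) {
  x <- if (inherits(pred, "mdi_prediction")) pred$predicted_mdi else pred
  group_labels <- as.factor(group_labels)
  if (nlevels(droplevels(group_labels)) != 2L) {
    stop("group_labels must define exactly two non-empty groups")
  }
  note <- NULL
  if (!is.null(replicate_ids)) {
    x <- tapply(x, replicate_ids, mean)
    group_labels <- as.factor(tapply(as.character(group_labels),
                                     replicate_ids, `[`, 1L))
    note <- "technical replicates averaged per subject before testing"
  }
  if (min(table(group_labels)) < 2L) {
    stop("each group needs at least two (subject-level) observations")
  }
  out <- stats::t.test(x ~ group_labels)
  out$note <- note
  out
}
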