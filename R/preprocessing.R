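#' Quantile-normalize an expression matrix
#'
#' Forces every observation (column) to share the same empirical
#' distribution: the across-column mean of order statistics.  Ties within a
#' column receive the mean of the reference values they span.  Delegates to
#' `limma::normalizeQuantiles`, the standard microarray implementation.
#' Normalization is performed within one platform at a time; the miR and
#' mRNA matrices have incomparable probe counts, so a joint reference
#' distribution would be ill-defined.
#'
#' @param matrix An `expression_matrix`.
#' @return The normalized `expression_matrix` (probe/observation ids and
#'   platform unchanged).
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (ncol(matrix$values) < 2L) {
    warning("single observation: quantile normalization is a no-op")
    return(matrix)
  }
  norm <- limma::normalizeQuantiles(matrix$values, ties = TRUE)
  expression_matrix(norm, matrix$probe_ids, matrix$observation_ids,
                    matrix$platform)
}

#' Probewise one-way ANOVA filter
#'
#' Tests each probe for differential expression across the stage groups
#' with a fixed-effects one-way ANOVA F-test and retains the probes whose
#' unadjusted p-value is below `alpha`.  Probes for which the F statistic
#' is undefined (zero within-group *and* zero between-group variance) are
#' dropped.  Grouping always uses the disease-stage labels (the grouped
#' design), regardless of which ordering is later fitted.
#'
#' By default replicates within a sample (expression set) are averaged
#' first so that samples, not technical replicates, act as the ANOVA
#' replicates; set `set_average = FALSE` to test at replicate level.
#'
#' @param matrix An `expression_matrix`.
#' @param groups Named character vector mapping observation id to group
#'   (stage) label.
#' @param alpha Significance level in (0, 1); default 0.05, unadjusted.
#' @param set_average Average within-sample replicates before testing?
#'   Requires `sets` when `TRUE` and replicates exist.
#' @param sets Optional named character vector mapping observation id to
#'   sample (set) id, used for set-averaging.
#' @return Character vector of retained probe ids.
#' @export
anova_filter <- function(matrix, groups, alpha = 0.05,
                         set_average = TRUE, sets = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  vals <- matrix$values
  grp <- groups[matrix$observation_ids]
  if (anyNA(grp)) stop("some observations have no group label")
  if (set_average && !is.null(sets)) {
    set_id <- sets[matrix$observation_ids]
    if (anyNA(set_id)) stop("some observations have no set id")
    key <- factor(set_id, levels = unique(set_id))
    vals <- t(apply(vals, 1L, function(v) tapply(v, key, mean)))
    colnames(vals) <- levels(key)
    grp <- tapply(grp, key, function(g) g[1L])[levels(key)]
  }
  grp <- factor(unname(grp))
  if (nlevels(grp) < 2L) stop("ANOVA filter needs at least two groups")
  tab <- table(grp)
  if (any(tab < 2L)) {
    stop("group(s) with a single member: ",
         paste(names(tab)[tab < 2L], collapse = ", "),
         "; use a different grouping for filtering")
  }
  keep <- vapply(seq_len(nrow(vals)), function(i) {
    v <- vals[i, ]
    between <- stats::var(tapply(v, grp, mean))
    within <- sum(tapply(v, grp, function(x) sum((x - mean(x))^2)))
    if (between < 1e-300 && within < 1e-300) return(FALSE)  # undefined F
    p <- stats::oneway.test(v ~ grp, var.equal = TRUE)$p.value
    is.finite(p) && p < alpha
  }, logical(1))
  matrix$probe_ids[keep]
}

#' Restrict probe sets to those with at least one predicted interaction
#'
#' Keeps exactly the miRs and genes that participate in one or more
#' candidate (miR, gene) pairs of the prediction set, intersected with the
#' supplied id lists.
#'
#' @param mir_ids Character vector of miR ids under consideration.
#' @param gene_ids Character vector of gene ids under consideration.
#' @param predictions A `prediction_set`.
#' @return List with elements `mir_ids` and `gene_ids` (order of the
#'   inputs preserved).
#' @export
restrict_to_predicted <- function(mir_ids, gene_ids, predictions) {
  stopifnot(inherits(predictions, "prediction_set"))
  pairs <- predictions$pairs
  active <- pairs$mir %in% mir_ids & pairs$gene %in% gene_ids
  list(mir_ids = mir_ids[mir_ids %in% pairs$mir[active]],
       gene_ids = gene_ids[gene_ids %in% pairs$gene[active]])
}

#' Scale each probe to mean zero, standard deviation one
#'
#' Uses the sample standard deviation (n-1 denominator) across all
#' observations of the probe.  Zero-variance probes are an error: they
#' should have been removed by the ANOVA filter.
#'
#' @param matrix An `expression_matrix`.
#' @return The re-scaled `expression_matrix`.
#' @export
zscale <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  m <- rowMeans(matrix$values)
  s <- apply(matrix$values, 1L, stats::sd)
  if (any(s == 0)) {
    stop("zero-variance probe(s): ",
         paste(utils::head(matrix$probe_ids[s == 0], 5L), collapse = ", "))
  }
  expression_matrix((matrix$values - m) / s, matrix$probe_ids,
                    matrix$observation_ids, matrix$platform)
}

subset_probes <- function(matrix, probe_ids) {
  expression_matrix(matrix$values[probe_ids, , drop = FALSE], probe_ids,
                    matrix$observation_ids, matrix$platform)
}

#' Run the full preprocessing pipeline on a paired dataset
#'
#' Composes the pre-analysis steps in their fixed order: quantile
#' normalization (within platform), probewise ANOVA filtering against the
#' stage labels, restriction to probes involved in at least one predicted
#' interaction, and per-probe z-scaling.
#'
#' @param dataset An `expression_dataset`.
#' @param predictions A `prediction_set` of candidate (miR, gene) pairs.
#' @param alpha ANOVA significance level (default 0.05).
#' @param set_average Passed to [anova_filter()].
#' @return List: `dataset` (the filtered, scaled `expression_dataset`) and
#'   `report` (data frame of probe counts after each step, per platform).
#' @export
preprocess_dataset <- function(dataset, predictions, alpha = 0.05,
                               set_average = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  ann <- dataset$annotation
  groups <- stats::setNames(ann$stage, ann$observation_id)
  sets <- stats::setNames(ann$sample_id, ann$observation_id)
  counts <- function(mir, mrna, step) {
    data.frame(step = step, mir = length(mir), mrna = length(mrna))
  }
  report <- counts(dataset$mir$probe_ids, dataset$mrna$probe_ids, "input")

  mir <- quantile_normalize(dataset$mir)
  mrna <- quantile_normalize(dataset$mrna)
  report <- rbind(report, counts(mir$probe_ids, mrna$probe_ids, "quantile_normalized"))

  keep_mir <- anova_filter(mir, groups, alpha, set_average, sets)
  keep_mrna <- anova_filter(mrna, groups, alpha, set_average, sets)
  report <- rbind(report, counts(keep_mir, keep_mrna, "anova_filtered"))

  kept <- restrict_to_predicted(keep_mir, keep_mrna, predictions)
  if (!length(kept$mir_ids) || !length(kept$gene_ids)) {
    stop("no probes survive the predicted-pair restriction")
  }
  report <- rbind(report, counts(kept$mir_ids, kept$gene_ids, "prediction_restricted"))

  mir <- zscale(subset_probes(mir, kept$mir_ids))
  mrna <- zscale(subset_probes(mrna, kept$gene_ids))
  report <- rbind(report, counts(mir$probe_ids, mrna$probe_ids, "zscaled"))

  list(dataset = expression_dataset(mir, mrna, ann), report = report)
}
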