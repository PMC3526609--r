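#' Rank candidate interactions by posterior significance
#'
#' Significance of a candidate pair is its posterior z-score: posterior
#' mean divided by posterior standard deviation.  By default pairs are
#' sorted by |z| descending (both repression and activation count); with
#' `negative_only = TRUE` positive-mean pairs are dropped and the rest
#' sorted by z ascending (most significantly negative first).  Ties are
#' broken lexicographically by (miR id, gene id).
#'
#' @param state A fitted `mirord_state` (or a data frame as returned by
#'   [interaction_posterior()]).
#' @param negative_only Restrict to inferred negative interactions?
#' @return Data frame of class `ranked_interactions`: `rank` (1-based),
#'   `mir`, `gene`, `mean`, `sd`, `z`, `predicted_by`.
#' @export
rank_interactions <- function(state, negative_only = FALSE) {
  post <- if (is.data.frame(state)) state else interaction_posterior(state)
  if (negative_only) post <- post[post$mean < 0, , drop = FALSE]
  key <- if (negative_only) post$z else -abs(post$z)
  ord <- order(key, post$mir, post$gene)
  out <- post[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("ranked_interactions", "data.frame")
  out
}

#' miRs with a significant trend through the ordering
#'
#' Selects the miRs whose trend parameter's posterior mean lies more than
#' `z_threshold` posterior standard deviations from zero, in either
#' direction, and reports the direction of the drift.
#'
#' @param state A fitted `mirord_state` (or a [trend_posterior()] data
#'   frame).
#' @param z_threshold Positive significance threshold (default 3).
#' @return Data frame: `mir`, `direction` (`"+"` or `"-"`), `z`
#'   (absolute z-score), sorted by `z` descending.
#' @export
significant_trends <- function(state, z_threshold = 3) {
  stopifnot(z_threshold > 0)
  post <- if (is.data.frame(state)) state else trend_posterior(state)
  keep <- abs(post$z) > z_threshold
  out <- data.frame(mir = post$mir[keep],
                    direction = ifelse(post$mean[keep] >= 0, "+", "-"),
                    z = abs(post$z[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$mir), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate interactions by Pearson correlation
#'
#' The correlation baseline: for each candidate pair, the Pearson
#' correlation between the miR and mRNA expression profiles across
#' samples (within-array replicates are averaged per sample first).
#' `mode = "abs"` ranks by strongest absolute correlation,
#' `mode = "negative"` by most negative correlation; ties are broken
#' lexicographically.
#'
#' @param data An `expression_dataset`.
#' @param candidates Data frame with columns `mir`, `gene` (e.g. the
#'   `pairs` element of a `prediction_set`).
#' @param mode `"abs"` or `"negative"`.
#' @return Data frame of class `ranked_interactions`: `rank`, `mir`,
#'   `gene`, `correlation`.  Pairs with a zero-variance profile are
#'   skipped with a warning.
#' @export
correlation_ranking <- function(data, candidates, mode = c("abs", "negative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "expression_dataset"))
  ann <- data$annotation
  key <- factor(ann$sample_id, levels = unique(ann$sample_id))
  avg <- function(m) {
    out <- t(rowsum(t(m[, ann$observation_id, drop = FALSE]), key)) /
      rep(as.integer(table(key)), each = nrow(m))
    out
  }
  mir_prof <- avg(data$mir$values)
  gene_prof <- avg(data$mrna$values)
  mir <- as.character(candidates$mir)
  gene <- as.character(candidates$gene)
  keep <- mir %in% rownames(mir_prof) & gene %in% rownames(gene_prof)
  mir <- mir[keep]; gene <- gene[keep]
  r <- vapply(seq_along(mir), function(k) {
    a <- mir_prof[mir[k], ]
    b <- gene_prof[gene[k], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (anyNA(r)) {
    warning(sum(is.na(r)), " pair(s) skipped (zero-variance profile)")
    mir <- mir[!is.na(r)]; gene <- gene[!is.na(r)]; r <- r[!is.na(r)]
  }
  ord <- if (mode == "abs") order(-abs(r), mir, gene) else order(r, mir, gene)
  out <- data.frame(rank = seq_along(ord), mir = mir[ord], gene = gene[ord],
                    correlation = r[ord], stringsAsFactors = FALSE)
  class(out) <- c("ranked_interactions", "data.frame")
  out
}

#' Average relative rank statistic
#'
#' Compares two rankings through the positions of a common set of
#' validated pairs: both rank lists are sorted ascending, divided
#' elementwise (first by second) and averaged.  Values below 1 mean the
#' first ranking places the validated pairs nearer the top; the statistic
#' estimates the relative number of pairs that would need to be tested
#' experimentally to reach the same number of validations.
#'
#' @param ranks_a,ranks_b Equal-length vectors of positive integer rank
#'   positions.
#' @return A single number, `mean(sort(ranks_a) / sort(ranks_b))`.
#' @export
average_relative_rank <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b)) {
    stop("rank lists have different lengths")
  }
  if (!length(ranks_a)) stop("empty rank lists")
  if (any(ranks_a < 1) || any(ranks_b < 1)) {
    stop("ranks must be positive (1-based)")
  }
  mean(sort(ranks_a) / sort(ranks_b))
}

#' Look up the rank positions of validated pairs
#'
#' @param ranked A `ranked_interactions` data frame.
#' @param validated_pairs Data frame with columns `mir`, `gene`.
#' @return List: `ranks` (1-based positions of the validated pairs found
#'   in the ranking, in validated-list order) and `not_ranked` (data
#'   frame of validated pairs absent from the candidate ranking, e.g.
#'   missing from the prediction lists).
#' @export
validated_rank_lookup <- function(ranked, validated_pairs) {
  key_r <- paste(ranked$mir, ranked$gene, sep = "\r")
  key_v <- paste(as.character(validated_pairs$mir),
                 as.character(validated_pairs$gene), sep = "\r")
  idx <- match(key_v, key_r)
  list(ranks = ranked$rank[idx[!is.na(idx)]],
       not_ranked = validated_pairs[is.na(idx), c("mir", "gene"),
                                    drop = FALSE])
}

#' Read a validated-pair list (2-column TSV: mir, gene)
#' @param path File path; TSV with header columns `mir` and `gene`.
#' @return Data frame with character columns `mir`, `gene`.
#' @export
read_validated_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("mir", "gene") %in% names(tab))) {
    stop("validated-pair file needs columns 'mir' and 'gene'")
  }
  tab[, c("mir", "gene")]
}
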