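#' Construct a prediction set
#'
#' Candidate (miR, gene) pairs with per-algorithm targeting scores.  The
#' algorithm order is fixed at construction time because it determines the
#' layout of the prior feature vectors (and hence the ordering of the
#' coefficient vector estimated by the model).
#'
#' @param pairs Data frame with columns `mir`, `gene`, `algorithm`,
#'   `score` (one row per pair-algorithm combination; a pair may appear
#'   once per algorithm).
#' @param algorithms Character vector fixing the algorithm order; defaults
#'   to order of first appearance.
#' @return An object of class `prediction_set` with elements `algorithms`
#'   and `pairs` (wide data frame: `mir`, `gene`, one indicator and one
#'   score column per algorithm).
#' @export
prediction_set <- function(pairs, algorithms = unique(pairs$algorithm)) {
  stopifnot(all(c("mir", "gene", "algorithm", "score") %in% names(pairs)))
  algorithms <- as.character(algorithms)
  bad <- setdiff(unique(pairs$algorithm), algorithms)
  if (length(bad)) stop("algorithm(s) not declared: ", paste(bad, collapse = ", "))
  pairs$mir <- as.character(pairs$mir)
  pairs$gene <- as.character(pairs$gene)
  key <- paste(pairs$mir, pairs$gene, sep = "\r")
  wide <- unique(data.frame(mir = pairs$mir, gene = pairs$gene,
                            key = key, stringsAsFactors = FALSE))
  for (alg in algorithms) {
    sub <- pairs[pairs$algorithm == alg, ]
    idx <- match(wide$key, paste(sub$mir, sub$gene, sep = "\r"))
    wide[[paste0("predicted_", alg)]] <- as.integer(!is.na(idx))
    sc <- sub$score[idx]
    sc[is.na(sc)] <- 0
    wide[[paste0("score_", alg)]] <- sc
  }
  if (any(rowSums(wide[, paste0("predicted_", algorithms), drop = FALSE]) == 0)) {
    stop("pair without any algorithm score")
  }
  wide$key <- NULL
  rownames(wide) <- NULL
  structure(list(algorithms = algorithms, pairs = wide),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("prediction set: %d candidate pairs, %d miRs, %d genes; algorithms: %s\n",
              nrow(x$pairs), length(unique(x$pairs$mir)),
              length(unique(x$pairs$gene)),
              paste(x$algorithms, collapse = ", ")))
  invisible(x)
}

#' Column specifications for common prediction-table dialects
#'
#' Returns the default column names for the bulk-download table formats of
#' the supported target-prediction databases: TargetScan (context+ scores)
#' and miRanda (mirSVR scores).
#'
#' @param dialect `"targetscan"` or `"miranda"`.
#' @return List with entries `mir`, `gene`, `score` (column names).
#' @export
prediction_dialect <- function(dialect = c("targetscan", "miranda")) {
  switch(match.arg(dialect),
         targetscan = list(mir = "miRNA", gene = "Gene Symbol",
                           score = "context+ score"),
         miranda = list(mir = "mirna_name", gene = "gene_symbol",
                        score = "mirsvr_score"))
}

strip_transcript_version <- function(x) sub("\\.\\d+$", "", x)

#' Read a target-prediction table
#'
#' Parses a tab-separated prediction download into a `prediction_set` for a
#' single algorithm.  Duplicate rows for a (miR, gene) pair collapse to the
#' single best score; both context+ and mirSVR scores are "better" when
#' more negative, so the minimum is kept.  Gene identifiers are matched
#' case-insensitively after stripping transcript-version suffixes
#' (`".1"`, `".2"`, ...); rows whose score cannot be parsed are skipped and
#' counted.
#'
#' @param path File path (TSV with header).
#' @param algorithm_name Name under which the algorithm's scores are
#'   stored (e.g. `"targetscan"`).
#' @param column_spec List with entries `mir`, `gene`, `score` giving
#'   column names or indices; see [prediction_dialect()] for defaults.
#' @return A `prediction_set` with a single algorithm.  The number of
#'   skipped rows is reported via `message()` and attached as attribute
#'   `skipped`.
#' @export
read_prediction_table <- function(path, algorithm_name,
                                  column_spec = prediction_dialect(algorithm_name)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(col) {
    if (is.numeric(col)) return(tab[[col]])
    if (!col %in% names(tab)) stop("column '", col, "' not found in ", path)
    tab[[col]]
  }
  mir <- as.character(pick(column_spec$mir))
  gene <- toupper(strip_transcript_version(as.character(pick(column_spec$gene))))
  score <- suppressWarnings(as.numeric(pick(column_spec$score)))
  ok <- !is.na(score) & nzchar(mir) & nzchar(gene)
  skipped <- sum(!ok)
  if (skipped) message(skipped, " row(s) skipped (unparseable score or empty id)")
  if (!any(ok)) stop("no parseable prediction rows in ", path)
  pairs <- data.frame(mir = mir[ok], gene = gene[ok], score = score[ok],
                      stringsAsFactors = FALSE)
  # collapse duplicates to the best (most negative) score
  key <- paste(pairs$mir, pairs$gene, sep = "\r")
  best <- tapply(pairs$score, key, min)
  first <- !duplicated(key)
  pairs <- pairs[first, ]
  pairs$score <- as.numeric(best[paste(pairs$mir, pairs$gene, sep = "\r")])
  pairs$algorithm <- algorithm_name
  out <- prediction_set(pairs, algorithms = algorithm_name)
  attr(out, "skipped") <- skipped
  out
}

#' Merge prediction sets from several algorithms
#'
#' Takes the union of candidate pairs; a pair keeps one indicator/score
#' block per algorithm, zero where that algorithm did not predict it.
#'
#' @param ... `prediction_set` objects with distinct algorithm names.
#' @return A combined `prediction_set`; algorithm order follows the
#'   argument order.
#' @export
merge_prediction_sets <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "prediction_set")))
  algorithms <- unlist(lapply(sets, `[[`, "algorithms"))
  if (anyDuplicated(algorithms)) stop("duplicate algorithm names across sets")
  long <- do.call(rbind, lapply(sets, function(s) {
    do.call(rbind, lapply(s$algorithms, function(alg) {
      p <- s$pairs[s$pairs[[paste0("predicted_", alg)]] == 1L, ]
      data.frame(mir = p$mir, gene = p$gene, algorithm = alg,
                 score = p[[paste0("score_", alg)]],
                 stringsAsFactors = FALSE)
    }))
  }))
  prediction_set(long, algorithms)
}

#' Restrict a prediction set to given probe id universes
#' @param predictions A `prediction_set`.
#' @param mir_ids,gene_ids Ids to keep (genes matched after upper-casing).
#' @return The restricted `prediction_set`.
#' @export
subset_predictions <- function(predictions, mir_ids, gene_ids) {
  keep <- predictions$pairs$mir %in% mir_ids &
    predictions$pairs$gene %in% toupper(gene_ids)
  out <- predictions
  out$pairs <- predictions$pairs[keep, , drop = FALSE]
  rownames(out$pairs) <- NULL
  out
}

#' Prior feature vector of a candidate pair
#'
#' Lays out the fixed prediction features of one (miR, gene) pair as
#' `[indicator_alg1, indicator_alg1 * score_alg1, indicator_alg2, ...]`.
#' The per-algorithm indicator plays the role of an intercept for that
#' algorithm's predictions: a score of exactly zero is still
#' distinguishable from "not predicted" because its indicator is 1.
#'
#' @param mir,gene Pair identifiers; the pair must be present in
#'   `predictions`.
#' @param predictions A `prediction_set`.
#' @return Numeric vector of length `2 * length(predictions$algorithms)`,
#'   named `ind_<alg>` / `score_<alg>`.
#' @export
feature_vector <- function(mir, gene, predictions) {
  fm <- feature_matrix(predictions)
  idx <- which(predictions$pairs$mir == mir & predictions$pairs$gene == gene)
  if (!length(idx)) stop("pair (", mir, ", ", gene, ") not in prediction set")
  fm[idx[1L], ]
}

#' Feature matrix over all candidate pairs
#'
#' Stacks [feature_vector()] over the rows of `predictions$pairs`.  Rows
#' are never all-zero (every candidate pair is predicted by at least one
#' algorithm).
#'
#' @param predictions A `prediction_set`.
#' @return Numeric matrix, pairs x (2 * algorithms).
#' @export
feature_matrix <- function(predictions) {
  algs <- predictions$algorithms
  p <- predictions$pairs
  out <- matrix(0, nrow(p), 2L * length(algs))
  cn <- character(2L * length(algs))
  for (a in seq_along(algs)) {
    ind <- p[[paste0("predicted_", algs[a])]]
    out[, 2L * a - 1L] <- ind
    out[, 2L * a] <- ind * p[[paste0("score_", algs[a])]]
    cn[2L * a - 1L] <- paste0("ind_", algs[a])
    cn[2L * a] <- paste0("score_", algs[a])
  }
  colnames(out) <- cn
  out
}

#' Write the candidate-pair table for audit
#' @param predictions A `prediction_set`.
#' @param path Output TSV path.
#' @export
write_candidate_table <- function(predictions, path) {
  utils::write.table(predictions$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
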