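#' Construct an expression matrix
#'
#' A thin validated container for log-scale expression values: probes (miR
#' probes or mRNA probesets) in rows, observations (one column per
#' replicate measurement) in columns.  Missing values are rejected at
#' construction time; downstream code may therefore assume a complete
#' matrix.
#'
#' @param values Numeric matrix, probes x observations.
#' @param probe_ids Character vector of unique probe identifiers (defaults
#'   to rownames).
#' @param observation_ids Character vector of unique observation/column
#'   identifiers (defaults to colnames).
#' @param platform `"miR"` or `"mRNA"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              observation_ids = colnames(values),
                              platform = c("miR", "mRNA")) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(observation_ids)) {
    stop("probe_ids and observation_ids are required (or set dimnames)")
  }
  probe_ids <- as.character(probe_ids)
  observation_ids <- as.character(observation_ids)
  if (length(probe_ids) != nrow(values) ||
      length(observation_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids")
  if (anyDuplicated(observation_ids)) stop("duplicate observation ids")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression matrix contains missing or non-finite values")
  }
  dimnames(values) <- list(probe_ids, observation_ids)
  structure(list(values = values, probe_ids = probe_ids,
                 observation_ids = observation_ids, platform = platform),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("%s expression matrix: %d probes x %d observations\n",
              x$platform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expected layout: header row of observation ids, first column probe ids,
#' real-valued body (log-scale expression).
#'
#' @param path File path.
#' @inheritParams expression_matrix
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, platform = c("miR", "mRNA")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  probe_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- probe_ids
  expression_matrix(values, platform = match.arg(platform))
}

#' Write an expression matrix to TSV
#' @param x An `expression_matrix`.
#' @param path Output file path.
#' @export
write_expression_tsv <- function(x, path) {
  tab <- data.frame(probe_id = x$probe_ids, x$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an observation annotation table
#'
#' Maps every observation (column of the expression matrices) to its sample
#' (= expression set / array) and within-array replicate, plus the sample's
#' stage label used for grouping.  TSV with header columns
#' `observation_id`, `sample_id`, `stage`, `replicate_id`.
#'
#' @param path File path.
#' @return Data frame with character columns.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("observation_id", "sample_id", "stage", "replicate_id")
  if (!all(need %in% names(tab))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$observation_id)) stop("duplicate observation ids")
  tab[, need]
}

#' Bundle paired miR/mRNA expression with a shared observation annotation
#'
#' Both platforms are measured on the same arrays, so a single annotation
#' applies: each observation column maps to a sample (expression set) and a
#' within-array replicate.  The `stage` column carries the grouping label
#' used by the ANOVA filter and by the ordering builders; the model's stage
#' structure itself always comes from a `partial_order`.
#'
#' @param mir An `expression_matrix` with `platform = "miR"`.
#' @param mrna An `expression_matrix` with `platform = "mRNA"`.
#' @param annotation Data frame with columns `observation_id`, `sample_id`,
#'   `stage`, `replicate_id` covering every observation of both matrices.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(mir, mrna, annotation) {
  stopifnot(inherits(mir, "expression_matrix"),
            inherits(mrna, "expression_matrix"))
  if (mir$platform != "miR" || mrna$platform != "mRNA") {
    stop("platform mismatch: pass miR matrix first, mRNA second")
  }
  for (col in c("observation_id", "sample_id", "stage", "replicate_id")) {
    if (is.null(annotation[[col]])) stop("annotation lacks column ", col)
    annotation[[col]] <- as.character(annotation[[col]])
  }
  for (m in list(mir, mrna)) {
    missing <- setdiff(m$observation_ids, annotation$observation_id)
    if (length(missing)) {
      stop("observations missing from annotation: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  structure(list(mir = mir, mrna = mrna, annotation = annotation),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(paste0("paired expression dataset: %d miR probes, ",
                     "%d mRNA probesets, %d observations, %d samples\n"),
              nrow(x$mir$values), nrow(x$mrna$values),
              nrow(x$annotation), length(unique(x$annotation$sample_id))))
  invisible(x)
}
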