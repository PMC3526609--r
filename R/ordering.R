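#' Construct a partial ordering of stages
#'
#' A partial order is the backbone of the staged expression model: a directed
#' acyclic graph (DAG) whose nodes are *stages* (groups of observations
#' treated as replicates of one latent expression state) and whose edges
#' point from a parent stage to its children.  Latent expression is
#' propagated along the edges, so every valid order must be acyclic and must
#' contain at least one initial stage (a stage with no parents) at which the
#' propagation can start.
#'
#' @param stages Character vector of stage identifiers (case-sensitive,
#'   unique).
#' @param parents Named list mapping each stage to a character vector of its
#'   parent stages (may be empty). Stages missing from the list are taken to
#'   have no parents.
#' @param members Named list mapping each stage to the character vector of
#'   sample identifiers assigned to it. Every sample must belong to exactly
#'   one stage.
#' @return An object of class `partial_order` with elements `stages`,
#'   `parents` and `members`.
#' @seealso [validate_partial_order()], [build_grouped_ordered()],
#'   [build_individual_ordered()], [build_individual_reference()]
#' @export
partial_order <- function(stages, parents = list(), members = list()) {
  stages <- as.character(stages)
  parents <- lapply(stages, function(s) as.character(parents[[s]] %||% character()))
  names(parents) <- stages
  members <- lapply(stages, function(s) as.character(members[[s]] %||% character()))
  names(members) <- stages
  structure(list(stages = stages, parents = parents, members = members),
            class = "partial_order")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.partial_order <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  n_members <- sum(lengths(x$members))
  cat(sprintf("partial order: %d stages, %d edges, %d member samples\n",
              length(x$stages), n_edges, n_members))
  init <- initial_stages(x)
  cat("initial stage(s):", paste(init, collapse = ", "), "\n")
  invisible(x)
}

#' Stages with no parents
#' @param order A `partial_order`.
#' @return Character vector of initial stage identifiers.
#' @export
initial_stages <- function(order) {
  order$stages[lengths(order$parents[order$stages]) == 0L]
}

#' Validate a partial order
#'
#' Checks the three structural invariants required by the model: the parent
#' relation is acyclic, at least one initial stage exists, and every sample
#' identifier is a member of exactly one stage.  Violations are returned as
#' human-readable strings rather than raised, so callers can report all
#' problems at once.
#'
#' @param order A `partial_order`.
#' @return Character vector of violation descriptions; empty if the order is
#'   valid.
#' @export
validate_partial_order <- function(order) {
  violations <- character()
  stages <- order$stages
  if (anyDuplicated(stages)) {
    violations <- c(violations, sprintf(
      "duplicate stage identifier(s): %s",
      paste(unique(stages[duplicated(stages)]), collapse = ", ")))
  }
  unknown <- setdiff(unlist(order$parents), stages)
  if (length(unknown)) {
    violations <- c(violations, sprintf(
      "parent(s) not in stage list: %s", paste(unknown, collapse = ", ")))
  }
  topo <- try(topological_stages(order), silent = TRUE)
  if (inherits(topo, "try-error")) {
    violations <- c(violations, "cycle: the parent relation is not acyclic")
  }
  if (length(stages) && length(initial_stages(order)) == 0L) {
    violations <- c(violations, "no initial stage (every stage has parents)")
  }
  memb <- unlist(order$members, use.names = FALSE)
  if (anyDuplicated(memb)) {
    violations <- c(violations, sprintf(
      "sample(s) assigned to more than one stage: %s",
      paste(unique(memb[duplicated(memb)]), collapse = ", ")))
  }
  violations
}

#' Topologically sort the stages of a partial order
#'
#' Kahn's algorithm with deterministic tie-breaking: among stages whose
#' parents have all been emitted, the one that appears first in
#' `order$stages` is emitted next, so the result is stable under permutation
#' of observations and of the parent lists.
#'
#' @param order A `partial_order`.
#' @return Character vector of stage ids, parents always before children.
#' @export
topological_stages <- function(order) {
  stages <- order$stages
  remaining <- stages
  done <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(s) {
      all(order$parents[[s]] %in% done)
    }, logical(1))]
    if (!length(ready)) {
      stop("partial order contains a cycle; topological sort impossible")
    }
    done <- c(done, ready[1L])
    remaining <- setdiff(remaining, ready[1L])
  }
  done
}

check_sample_table <- function(sample_table) {
  if (!all(c("sample_id", "stage") %in% names(sample_table))) {
    stop("sample table needs columns 'sample_id' and 'stage'")
  }
  sample_table$sample_id <- as.character(sample_table$sample_id)
  sample_table$stage <- as.character(sample_table$stage)
  if (anyDuplicated(sample_table$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_table$sample_id[duplicated(sample_table$sample_id)]),
               collapse = ", "))
  }
  sample_table
}

check_labels <- function(sample_table, stage_labels, branches) {
  known <- c(stage_labels, names(branches))
  bad <- setdiff(unique(sample_table$stage), known)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  bad_attach <- setdiff(unlist(branches), stage_labels)
  if (length(bad_attach)) {
    stop("branch attachment point(s) not in stage_labels: ",
         paste(bad_attach, collapse = ", "))
  }
  invisible(TRUE)
}

#' Build the grouped-ordered (G-O) partial order
#'
#' Samples sharing a stage label are grouped as replicates of a single
#' stage; consecutive labels of the ordered main sequence are connected
#' parent to child, and each branch label is attached as a child of its
#' declared attachment stage.  This is the natural design for staged disease
#' data: e.g. the Durie-Salmon stages in order, with plasma-cell leukemia as
#' a separate branch off the initial stage.
#'
#' @param sample_table Data frame with columns `sample_id` and `stage`.
#' @param stage_labels Character vector giving the ordered main sequence of
#'   labels (earliest first).
#' @param branches Named list: `list(branch_label = attachment_label)`;
#'   each branch stage becomes a child of its attachment stage.
#' @return A `partial_order` with one stage per label that occurs in the
#'   table (main-sequence edges skip labels with no samples).
#' @export
build_grouped_ordered <- function(sample_table, stage_labels,
                                  branches = list()) {
  sample_table <- check_sample_table(sample_table)
  check_labels(sample_table, stage_labels, branches)
  present <- stage_labels[stage_labels %in% sample_table$stage]
  branch_present <- names(branches)[names(branches) %in% sample_table$stage]
  stages <- c(present, branch_present)
  parents <- list()
  if (length(present) > 1L) {
    for (k in 2:length(present)) parents[[present[k]]] <- present[k - 1L]
  }
  for (b in branch_present) parents[[b]] <- unname(branches[[b]])
  members <- split(sample_table$sample_id, sample_table$stage)[stages]
  names(members) <- stages
  partial_order(stages, parents, members)
}

#' Build the individual-ordered (I-O) partial order
#'
#' Each sample becomes its own single-member stage; every sample of a label
#' has as parents *all* samples of the immediately preceding main-sequence
#' label, and every branch-label sample has all samples of the branch's
#' attachment label as parents.  This keeps the stage ordering of the
#' grouped design but lets the model see variation between individuals of
#' the same stage.
#'
#' @inheritParams build_grouped_ordered
#' @return A `partial_order` with one stage per sample (stage id = sample
#'   id).
#' @export
build_individual_ordered <- function(sample_table, stage_labels,
                                     branches = list()) {
  sample_table <- check_sample_table(sample_table)
  check_labels(sample_table, stage_labels, branches)
  by_label <- split(sample_table$sample_id, sample_table$stage)
  present <- stage_labels[stage_labels %in% sample_table$stage]
  parents <- list()
  for (k in seq_along(present)) {
    for (smp in by_label[[present[k]]]) {
      parents[[smp]] <- if (k > 1L) by_label[[present[k - 1L]]] else character()
    }
  }
  for (b in intersect(names(branches), names(by_label))) {
    for (smp in by_label[[b]]) parents[[smp]] <- by_label[[branches[[b]]]]
  }
  stages <- sample_table$sample_id
  members <- as.list(stages)
  names(members) <- stages
  partial_order(stages, parents, members)
}

#' Build the individual-reference (I-R) partial order
#'
#' Each sample becomes its own single-member stage; samples of the reference
#' label have no parents, and every other sample has *all* reference samples
#' as parents (a depth-one DAG).  This design largely ignores the natural
#' ordering and focuses on differences between individuals and the
#' reference group.
#'
#' @param sample_table Data frame with columns `sample_id` and `stage`.
#' @param reference_label The stage label whose samples act as references.
#' @return A `partial_order` with one stage per sample.
#' @export
build_individual_reference <- function(sample_table, reference_label) {
  sample_table <- check_sample_table(sample_table)
  refs <- sample_table$sample_id[sample_table$stage == reference_label]
  if (!length(refs)) {
    stop("reference label '", reference_label, "' not present in sample table")
  }
  stages <- sample_table$sample_id
  parents <- list()
  for (smp in stages) {
    parents[[smp]] <- if (smp %in% refs) character() else refs
  }
  members <- as.list(stages)
  names(members) <- stages
  partial_order(stages, parents, members)
}

#' Read / write a partial order as JSON
#'
#' The JSON layout is declarative: `{"stages": [...], "edges": [[parent,
#' child], ...], "members": {"stage": ["sample", ...]}}`, so arbitrary DAGs
#' (not only the three built-in designs) can be specified in a file.
#'
#' @param path File path.
#' @return `read_ordering_json` returns a `partial_order`;
#'   `write_ordering_json` returns `path` invisibly.
#' @export
read_ordering_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stages <- as.character(spec$stages)
  parents <- list()
  edges <- spec$edges
  if (!is.null(edges) && length(edges)) {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (!is.matrix(edges)) edges <- do.call(rbind, edges)
    for (k in seq_len(nrow(edges))) {
      child <- as.character(edges[k, 2L])
      parents[[child]] <- c(parents[[child]], as.character(edges[k, 1L]))
    }
  }
  members <- lapply(spec$members, as.character)
  ord <- partial_order(stages, parents, members)
  bad <- validate_partial_order(ord)
  if (length(bad)) stop("invalid ordering file: ", paste(bad, collapse = "; "))
  ord
}

#' @rdname read_ordering_json
#' @param order A `partial_order`.
#' @export
write_ordering_json <- function(order, path) {
  edges <- do.call(rbind, lapply(order$stages, function(s) {
    ps <- order$parents[[s]]
    if (length(ps)) cbind(ps, s) else NULL
  }))
  spec <- list(stages = order$stages,
               edges = if (is.null(edges)) list() else unname(apply(edges, 1L, as.list)),
               members = order$members)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a sample table (TSV with header sample_id, stage)
#' @param path File path to a tab-separated table with a header containing
#'   at least the columns `sample_id` and `stage`.
#' @return Data frame with character columns `sample_id` and `stage`.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  check_sample_table(tab[, c("sample_id", "stage")])
}

#' Map each sample to its stage in a partial order
#' @param order A `partial_order`.
#' @return Named character vector: names are sample ids, values stage ids.
#' @keywords internal
stage_of_sample <- function(order) {
  out <- rep(names(order$members), lengths(order$members))
  names(out) <- unlist(order$members, use.names = FALSE)
  out
}
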