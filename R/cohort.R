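#' Construct a cohort dataset
#'
#' The unit all analyses consume: a subjects-by-edges matrix of Fisher-z
#' connectivity values (canonical edge order, see [edge_pairs()]) together
#' with binary diagnosis labels (1 = patient, 0 = control) and subject ids.
#'
#' @param edges numeric `n_subjects x n_edges` matrix.
#' @param labels binary vector, 1 = patient, 0 = control; both classes must
#'   be present with at least 2 subjects each.
#' @param subject_ids optional character ids (default `sub001`, ...).
#' @param n_nodes node count consistent with `n_edges`; inferred from the
#'   edge count when omitted.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(edges, labels, subject_ids = NULL, n_nodes = NULL) {
  stopifnot(is.matrix(edges), is.numeric(edges))
  if (!all(is.finite(edges))) {
    stop("edge matrix contains non-finite values", call. = FALSE)
  }
  labels <- check_binary_labels(labels)
  if (length(labels) != nrow(edges)) {
    stop("length(labels) = ", length(labels), " but edges has ", nrow(edges),
         " rows", call. = FALSE)
  }
  if (sum(labels == 0) < 2L || sum(labels == 1) < 2L) {
    stop("both classes must have at least 2 subjects (got ",
         sum(labels == 0), " controls, ", sum(labels == 1), " patients)",
         call. = FALSE)
  }
  if (is.null(n_nodes)) {
    n_nodes <- nodes_for_n_edges(ncol(edges))
  } else if (n_edges_for_nodes(n_nodes) != ncol(edges)) {
    stop("n_nodes = ", n_nodes, " implies ", n_edges_for_nodes(n_nodes),
         " edges but edge matrix has ", ncol(edges), " columns", call. = FALSE)
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub%03d", seq_len(nrow(edges)))
  }
  stopifnot(length(subject_ids) == nrow(edges))
  if (anyDuplicated(subject_ids)) {
    stop("duplicated subject ids", call. = FALSE)
  }
  structure(list(subject_ids = as.character(subject_ids),
                 edges = edges, labels = labels,
                 n_nodes = as.integer(n_nodes)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", length(x$labels), " subjects (",
      sum(x$labels == 1), " patients / ", sum(x$labels == 0), " controls), ",
      x$n_nodes, " nodes, ", ncol(x$edges), " edges\n", sep = "")
  invisible(x)
}

# Subset a cohort by subject index, relaxing the two-per-class floor (CV
# folds may legitimately hold out down to n-1 subjects).
subset_cohort <- function(data, idx) {
  structure(list(subject_ids = data$subject_ids[idx],
                 edges = data$edges[idx, , drop = FALSE],
                 labels = data$labels[idx],
                 n_nodes = data$n_nodes),
            class = "cohort_dataset")
}
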