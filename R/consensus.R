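#' Consensus edges across cross-validation folds
#'
#' An edge is a consensus edge for a direction if it appears in at least
#' `fraction` of the folds' masks for that direction (inclusive: an edge
#' present in exactly 90 of 100 folds is selected at `fraction = 0.9`).
#' `fraction` near 0 yields the union of fold masks, `fraction = 1` the
#' intersection.
#'
#' @param fold_selections list of `directional_selection` objects (e.g.
#'   `cv_outcome$fold_selections`).
#' @param direction `"increased"` or `"decreased"`.
#' @param fraction required fraction of folds, in (0, 1].
#' @return An object of class `edge_mask`: logical `selected` (canonical
#'   edge order), `direction`, `fraction`, and `fold_fraction` (per-edge
#'   fraction of folds selecting it).
#' @export
consensus_edges <- function(fold_selections, direction = c("increased",
                                                           "decreased"),
                            fraction = 0.9) {
  direction <- match.arg(direction)
  stopifnot(is.list(fold_selections), length(fold_selections) >= 1L,
            fraction > 0, fraction <= 1)
  lens <- vapply(fold_selections, function(s) length(s[[direction]]),
                 integer(1))
  if (length(unique(lens)) != 1L) {
    stop("fold selections disagree on the number of edges: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(fold_selections,
                               function(s) as.integer(s[[direction]])))
  n_folds <- length(fold_selections)
  # inclusive boundary: an integer count k qualifies iff k / n >= fraction;
  # the 1e-9 guards against floating-point in fraction * n (e.g. 0.9 * 100),
  # and k = 0 never qualifies since fraction > 0
  k_min <- max(1L, as.integer(ceiling(fraction * n_folds - 1e-9)))
  selected <- counts >= k_min
  structure(list(selected = selected, direction = direction,
                 fraction = fraction, fold_fraction = counts / n_folds,
                 n_folds = n_folds),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat("<edge_mask> ", sum(x$selected), " ", x$direction,
      " consensus edges (>= ", x$fraction * 100, "% of ", x$n_folds,
      " folds)\n", sep = "")
  invisible(x)
}

#' Count selected edges per network pair
#'
#' Aggregates a selected-edge mask into an L x L symmetric matrix of counts
#' over network pairs: each selected edge (i, j) increments the cell for
#' (network(i), network(j)) and its mirror; the diagonal counts
#' within-network edges once each. The total over the upper triangle plus
#' diagonal equals the number of selected edges.
#'
#' @param mask an `edge_mask` (or logical vector in canonical edge order).
#' @param atlas an [make_atlas()] table covering all nodes.
#' @return An object of class `network_counts`: `labels` and integer
#'   `counts` matrix.
#' @export
network_pair_counts <- function(mask, atlas) {
  stopifnot(inherits(atlas, "atlas"))
  selected <- if (inherits(mask, "edge_mask")) mask$selected else as.logical(mask)
  n_nodes <- nrow(atlas)
  if (length(selected) != n_edges_for_nodes(n_nodes)) {
    stop("mask length ", length(selected), " does not match the atlas's ",
         n_edges_for_nodes(n_nodes), " edges (", n_nodes, " nodes)",
         call. = FALSE)
  }
  if (anyNA(atlas$network)) {
    stop("atlas has node(s) without a network label", call. = FALSE)
  }
  labels <- levels(atlas$network)
  L <- length(labels)
  counts <- matrix(0L, L, L, dimnames = list(labels, labels))
  if (any(selected)) {
    pairs <- edge_pairs(n_nodes)[selected, , drop = FALSE]
    a <- as.integer(atlas$network[pairs$node_i + 1L])
    b <- as.integer(atlas$network[pairs$node_j + 1L])
    for (e in seq_along(a)) {
      counts[a[e], b[e]] <- counts[a[e], b[e]] + 1L
      if (a[e] != b[e]) counts[b[e], a[e]] <- counts[b[e], a[e]] + 1L
    }
  }
  structure(list(labels = labels, counts = counts), class = "network_counts")
}

#' @export
print.network_counts <- function(x, ...) {
  cat("<network_counts> ", sum(x$counts[upper.tri(x$counts, diag = TRUE)]),
      " selected edges over ", length(x$labels), " networks\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Rank network pairs by selected-edge count
#'
#' Lists all unordered network pairs (including within-network pairs) sorted
#' by count, descending; ties are broken lexicographically by the pair
#' label `"A-B"` (networks within a pair ordered by the atlas label order).
#'
#' @param counts a `network_counts` object.
#' @param k number of top pairs to return.
#' @return data.frame with columns `pair`, `network_a`, `network_b`,
#'   `count`.
#' @export
top_networks <- function(counts, k) {
  stopifnot(inherits(counts, "network_counts"), k >= 1)
  L <- length(counts$labels)
  idx <- which(upper.tri(counts$counts, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(
    network_a = counts$labels[idx[, 1]],
    network_b = counts$labels[idx[, 2]],
    count = counts$counts[idx])
  out$pair <- paste(out$network_a, out$network_b, sep = "-")
  out <- out[order(-out$count, out$pair), c("pair", "network_a", "network_b",
                                            "count")]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Export an edge mask as a delimited edge list
#'
#' Writes one row per selected edge with columns `node_i`, `node_j`
#' (0-based), `direction`, `fold_fraction`.
#'
#' @param mask an `edge_mask`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(mask, path) {
  stopifnot(inherits(mask, "edge_mask"))
  n_nodes <- nodes_for_n_edges(length(mask$selected))
  pairs <- edge_pairs(n_nodes)[mask$selected, , drop = FALSE]
  out <- data.frame(pairs,
                    direction = mask$direction,
                    fold_fraction = mask$fold_fraction[mask$selected])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
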