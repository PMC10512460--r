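#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores whatever state existed before the call. All stochastic
#' operations in conncpm draw their randomness through this wrapper, so a
#' single integer seed fully determines their output and no call leaves a
#' footprint on the caller's RNG stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Draw a child seed from the current RNG stream (used to split one top-level
# seed into per-component seeds; documented in the methods vignette).
draw_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

#' Number of unique node pairs (edges) for a node count
#'
#' @param n_nodes number of atlas nodes.
#' @return `n_nodes * (n_nodes - 1) / 2`.
#' @examples
#' n_edges_for_nodes(268)  # 35778
#' @export
n_edges_for_nodes <- function(n_nodes) {
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1, n_nodes == round(n_nodes))
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

# Inverse of n_edges_for_nodes; errors if n_edges is not a triangular number.
nodes_for_n_edges <- function(n_edges) {
  n <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop("edge count ", n_edges, " does not correspond to an integer number of nodes",
         call. = FALSE)
  }
  as.integer(round(n))
}

#' Node pairs in canonical edge order
#'
#' The canonical edge order used throughout the package is the strict upper
#' triangle of the connectivity matrix traversed row-major: pairs (i, j) with
#' i < j, sorted by i then j, with 0-based node indices. All edge vectors and
#' masks follow this order.
#'
#' @param n_nodes number of nodes.
#' @return data.frame with integer columns `node_i`, `node_j` (0-based),
#'   one row per edge in canonical order.
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  if (n_nodes == 1L) {
    return(data.frame(node_i = integer(0), node_j = integer(0)))
  }
  i <- rep.int(seq_len(n_nodes - 1L) - 1L, times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(k) k:(n_nodes - 1L)),
              use.names = FALSE)
  data.frame(node_i = as.integer(i), node_j = as.integer(j))
}

check_binary_labels <- function(labels, what = "labels") {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    bad <- unique(labels[!(labels %in% c(0, 1))])
    stop(what, " must be coded 0 (control) / 1 (patient); found value(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  as.integer(labels)
}
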