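#' Canonical network labels
#'
#' The ten large-scale functional systems used to group atlas nodes, in the
#' fixed order used for all network-level outputs: cerebellum (CBL),
#' subcortical (SC), salience (SAL), visual association (VAs), visual A (VI),
#' visual B (VII), motor (Mot), default mode (DMN), frontoparietal (FP), and
#' medial frontal (MF).
#'
#' @return character vector of the ten network labels.
#' @export
canonical_networks <- function() {
  c("CBL", "SC", "SAL", "VAs", "VI", "VII", "Mot", "DMN", "FP", "MF")
}

#' Build an atlas assigning nodes to networks
#'
#' Assigns nodes (0-based indices, in order) to networks in contiguous
#' blocks. The default emulates a whole-brain functional parcellation
#' grouped into the ten canonical networks: when `network_sizes` is omitted,
#' nodes are split across the ten labels in near-equal contiguous blocks.
#'
#' @param n_nodes number of nodes.
#' @param network_sizes integer vector of block sizes, one per label; must
#'   sum to `n_nodes`.
#' @param labels network labels, one per block (default the ten canonical
#'   networks, or their first `length(network_sizes)` when sizes are given).
#' @return An object of class `atlas`: a data.frame with columns `node`
#'   (0-based integer) and `network` (factor with the label set as levels).
#' @examples
#' a <- make_atlas(268)
#' table(a$network)
#' @export
make_atlas <- function(n_nodes, network_sizes = NULL, labels = NULL) {
  stopifnot(n_nodes >= 1)
  if (is.null(network_sizes)) {
    k <- min(10L, n_nodes)
    base <- n_nodes %/% k
    network_sizes <- rep(base, k)
    extra <- n_nodes - base * k
    if (extra > 0) network_sizes[seq_len(extra)] <- network_sizes[seq_len(extra)] + 1L
  }
  if (is.null(labels)) {
    if (length(network_sizes) > 10L) {
      stop("supply labels explicitly when using more than 10 networks",
           call. = FALSE)
    }
    labels <- canonical_networks()[seq_along(network_sizes)]
  }
  stopifnot(length(labels) == length(network_sizes), !anyDuplicated(labels))
  if (sum(network_sizes) != n_nodes) {
    stop("network_sizes sum to ", sum(network_sizes), " but n_nodes = ",
         n_nodes, call. = FALSE)
  }
  network <- factor(rep(labels, times = network_sizes), levels = labels)
  structure(data.frame(node = 0:(n_nodes - 1L), network = network),
            class = c("atlas", "data.frame"))
}

#' Read an atlas table
#'
#' Reads a two-column delimited table with header `node,network`, nodes
#' numbered 0..n-1 in order.
#'
#' @param path file path.
#' @param levels optional explicit level order for the network factor;
#'   defaults to the canonical order for canonical labels, otherwise order
#'   of first appearance.
#' @return An `atlas` object.
#' @export
read_atlas <- function(path, levels = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  if (!all(c("node", "network") %in% names(tab))) {
    stop("atlas file must have header 'node,network': ", path, call. = FALSE)
  }
  if (!identical(as.integer(tab$node), 0:(nrow(tab) - 1L))) {
    stop("atlas nodes must be 0..n-1 in order: ", path, call. = FALSE)
  }
  if (anyNA(tab$network) || any(tab$network == "")) {
    stop("atlas has node(s) without a network label: ", path, call. = FALSE)
  }
  if (is.null(levels)) {
    canon <- canonical_networks()
    levels <- if (all(tab$network %in% canon)) {
      canon[canon %in% tab$network]
    } else {
      unique(tab$network)
    }
  }
  structure(data.frame(node = as.integer(tab$node),
                       network = factor(tab$network, levels = levels)),
            class = c("atlas", "data.frame"))
}

#' Write an atlas table
#'
#' @param atlas an `atlas` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas"))
  utils::write.table(
    data.frame(node = atlas$node, network = as.character(atlas$network)),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
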