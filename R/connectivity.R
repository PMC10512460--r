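#' Fisher r-to-z transformation
#'
#' Converts Pearson correlation coefficients to Fisher z scores,
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform conventionally applied to functional connectivity values before
#' group analysis.
#'
#' @param r numeric vector of correlations, each strictly inside (-1, 1).
#' @return numeric vector of z scores.
#' @examples
#' fisher_z(0)    # 0
#' fisher_z(0.5)  # 0.549306...
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r) || anyNA(r)) {
    stop("r must be numeric with no missing values", call. = FALSE)
  }
  bad <- which(abs(r) >= 1)
  if (length(bad)) {
    stop("fisher_z is undefined for |r| >= 1; offending value ", r[bad[1]],
         " at position ", bad[1],
         " (this usually signals a constant or duplicated time series)",
         call. = FALSE)
  }
  atanh(r)
}

#' Construct a panel of node time series
#'
#' Bundles per-subject node-by-time signal matrices (rows = nodes, columns =
#' timepoints) with subject identifiers. All subjects must share the same
#' number of nodes; at least 3 timepoints per subject are required for a
#' defined correlation.
#'
#' @param data list of numeric matrices, one per subject, each
#'   `n_nodes x n_timepoints`.
#' @param subject_ids character vector of ids, same length as `data`.
#' @return An object of class `timeseries_panel`.
#' @export
timeseries_panel <- function(data, subject_ids = NULL) {
  stopifnot(is.list(data), length(data) >= 1L)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub%03d", seq_along(data))
  }
  stopifnot(length(subject_ids) == length(data))
  n_nodes <- nrow(data[[1]])
  for (s in seq_along(data)) {
    m <- data[[s]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop("subject ", subject_ids[s], ": time series must be a numeric matrix",
           call. = FALSE)
    }
    if (nrow(m) != n_nodes) {
      stop("subject ", subject_ids[s], ": ", nrow(m),
           " nodes but first subject has ", n_nodes, call. = FALSE)
    }
    if (ncol(m) < 3L) {
      stop("subject ", subject_ids[s], ": need at least 3 timepoints, got ",
           ncol(m), call. = FALSE)
    }
    if (!all(is.finite(m))) {
      stop("subject ", subject_ids[s], ": non-finite values in time series",
           call. = FALSE)
    }
  }
  structure(list(subject_ids = as.character(subject_ids), data = data,
                 n_nodes = n_nodes),
            class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  tp <- vapply(x$data, ncol, integer(1))
  cat("<timeseries_panel> ", length(x$data), " subjects, ", x$n_nodes,
      " nodes, ", min(tp), "-", max(tp), " timepoints\n", sep = "")
  invisible(x)
}

#' Compute Fisher-z functional connectivity matrices
#'
#' For each subject, Pearson-correlates the mean time courses of every node
#' pair and applies the Fisher r-to-z transform, producing a symmetric
#' `n_nodes x n_nodes` connectivity matrix with a zero diagonal
#' (self-connectivity is excluded by convention; `atanh(1)` is undefined).
#' Time courses are mean-centered per node as part of the Pearson
#' correlation; no detrending or filtering is applied here.
#'
#' @param panel a [timeseries_panel()].
#' @return list of connectivity matrices, one per subject, named by
#'   subject id.
#' @export
compute_fc <- function(panel) {
  stopifnot(inherits(panel, "timeseries_panel"))
  out <- vector("list", length(panel$data))
  names(out) <- panel$subject_ids
  for (s in seq_along(panel$data)) {
    ts <- panel$data[[s]]
    sds <- apply(ts, 1, stats::sd)
    if (any(sds == 0)) {
      stop("subject ", panel$subject_ids[s], ": node ",
           which(sds == 0)[1] - 1L,
           " has a constant time course (zero variance)", call. = FALSE)
    }
    r <- stats::cor(t(ts))
    off <- r[upper.tri(r)]
    if (any(abs(off) >= 1 - 1e-15)) {
      stop("subject ", panel$subject_ids[s],
           ": |r| = 1 between distinct nodes (duplicated or affinely ",
           "dependent signals); Fisher z is undefined", call. = FALSE)
    }
    z <- atanh(r)
    diag(z) <- 0
    z <- (z + t(z)) / 2  # remove any asymmetric rounding from cor()
    out[[s]] <- z
  }
  out
}

check_connectivity_matrix <- function(m, tol = 1e-12, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(what, " is asymmetric beyond tolerance (max |m - t(m)| = ",
         format(asym), " > ", format(tol), ")", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Flatten a connectivity matrix to its canonical edge vector
#'
#' Extracts the strict upper triangle in canonical row-major order (pairs
#' (i, j) with i < j, sorted by i then j; see [edge_pairs()]). This ordering
#' is the contract for all edge vectors and masks in the package and
#' round-trips exactly with [devectorize_edges()].
#'
#' @param m symmetric numeric connectivity matrix (zero diagonal).
#' @param tol symmetry tolerance; matrices asymmetric beyond it are rejected.
#' @return numeric vector of length `n_nodes * (n_nodes - 1) / 2`.
#' @export
vectorize_edges <- function(m, tol = 1e-12) {
  m <- check_connectivity_matrix(m, tol = tol)
  tm <- t(m)
  tm[lower.tri(tm)]  # column-major lower triangle of t(m) = row-major upper of m
}

#' Rebuild a connectivity matrix from a canonical edge vector
#'
#' Inverse of [vectorize_edges()]: places the edge values back into the
#' strict upper triangle (row-major order), mirrors them, and zeroes the
#' diagonal.
#'
#' @param v numeric edge vector in canonical order.
#' @param n_nodes number of nodes the vector encodes.
#' @return symmetric `n_nodes x n_nodes` matrix with zero diagonal.
#' @export
devectorize_edges <- function(v, n_nodes) {
  expected <- n_edges_for_nodes(n_nodes)
  if (length(v) != expected) {
    stop("edge vector has length ", length(v), " but n_nodes = ", n_nodes,
         " requires length ", expected, call. = FALSE)
  }
  m <- matrix(0, n_nodes, n_nodes)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m + t(m)
}
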