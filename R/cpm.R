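#' Edge-wise correlation with the group label
#'
#' Pearson-correlates every edge with the binary diagnosis label (the
#' point-biserial correlation) and returns two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. This
#' is mathematically identical to an equal-variance two-sample t-test
#' comparing the groups on each edge. Edges with zero variance get
#' `r = 0, p = 1` and are therefore never selected.
#'
#' @param edges numeric `n x E` matrix of edge values.
#' @param labels binary vector (1 = patient, 0 = control), both classes
#'   present; `n >= 4` so that df >= 2.
#' @return list with numeric vectors `r` and `p` of length `E`.
#' @export
edgewise_label_correlation <- function(edges, labels) {
  stopifnot(is.matrix(edges))
  labels <- check_binary_labels(labels)
  n <- nrow(edges)
  if (length(labels) != n) stop("labels/edges size mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("labels are all one class; correlation with the group label is undefined",
         call. = FALSE)
  }
  if (n < 4L) {
    stop("need at least 4 subjects (df = n - 2 >= 2); got n = ", n,
         call. = FALSE)
  }
  yc <- labels - mean(labels)
  sxy <- as.vector(crossprod(edges, yc))
  sx <- .colSums(edges, n, ncol(edges))
  sxx <- .colSums(edges * edges, n, ncol(edges))
  ssx <- sxx - sx^2 / n
  ssy <- sum(yc^2)
  # zero-variance guard: constant edges get r = 0, p = 1
  const <- ssx <= 0 | ssx < 1e-12 * pmax(sxx, 1)
  denom <- sqrt(pmax(ssx, .Machine$double.xmin) * ssy)
  r <- sxy / denom
  r[const] <- 0
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[const] <- 1
  p <- pmin(p, 1)
  list(r = r, p = p)
}

#' Split significant edges by direction of alteration
#'
#' Thresholds the edge-wise p-values and divides surviving edges by the sign
#' of their correlation with the patient label: `increased` edges (r > 0,
#' connectivity higher in patients) and `decreased` edges (r < 0). The two
#' masks are disjoint by construction; edges with r exactly 0 are never
#' selected.
#'
#' @param r,p numeric vectors from [edgewise_label_correlation()].
#' @param threshold p-value threshold in (0, 1).
#' @return An object of class `directional_selection` with fields `r`, `p`,
#'   `threshold`, and logical masks `increased`, `decreased`.
#' @export
select_directional_features <- function(r, p, threshold) {
  stopifnot(length(r) == length(p),
            length(threshold) == 1L, threshold > 0, threshold < 1)
  sig <- p < threshold
  structure(list(r = r, p = p, threshold = threshold,
                 increased = sig & r > 0,
                 decreased = sig & r < 0),
            class = "directional_selection")
}

#' @export
print.directional_selection <- function(x, ...) {
  cat("<directional_selection> p < ", x$threshold, ": ",
      sum(x$increased), " increased, ", sum(x$decreased),
      " decreased of ", length(x$r), " edges\n", sep = "")
  invisible(x)
}

direction_modes <- c("increased", "decreased", "both")

check_mode <- function(mode) {
  match.arg(mode, direction_modes)
}

#' Sum selected edges into predictive scores
#'
#' Reduces the high-dimensional edge matrix to one or two per-subject
#' scores: the sum of each subject's values over the increased-edge mask
#' and/or the decreased-edge mask. For `mode = "both"` the columns are
#' ordered `[increased_sum, decreased_sum]`. An empty mask yields a column
#' that is identically 0; which masks were empty is recorded in the
#' `"empty_masks"` attribute (the model fit falls back to majority-class
#' prediction when all of a mode's masks are empty).
#'
#' @param edges numeric `n x E` matrix.
#' @param selection a `directional_selection` (masks of length E).
#' @param mode one of `"increased"`, `"decreased"`, `"both"`.
#' @return numeric `n x k` matrix (k = 1 or 2) with attribute
#'   `"empty_masks"` (character vector of empty directions used).
#' @export
summarize_features <- function(edges, selection, mode) {
  mode <- check_mode(mode)
  stopifnot(inherits(selection, "directional_selection"),
            ncol(edges) == length(selection$increased))
  sum_mask <- function(mask) {
    if (!any(mask)) return(rep(0, nrow(edges)))
    .rowSums(edges[, mask, drop = FALSE], nrow(edges), sum(mask))
  }
  dirs <- if (mode == "both") c("increased", "decreased") else mode
  feats <- vapply(dirs, function(d) sum_mask(selection[[d]]),
                  numeric(nrow(edges)))
  feats <- matrix(feats, nrow = nrow(edges),
                  dimnames = list(NULL, paste0(dirs, "_sum")))
  empty <- dirs[!vapply(dirs, function(d) any(selection[[d]]), logical(1))]
  attr(feats, "empty_masks") <- empty
  feats
}

# Fit a soft-margin linear classifier (hinge loss, box constraint C, no
# feature standardization) on the 1- or 2-column score matrix and extract an
# explicit decision rule: predict 1 iff x . w + b >= 0. The >= gives the
# documented tie-break (decision value exactly 0 -> class 1).
fit_linear_rule <- function(x, y, C) {
  fast_linear_svm(unname(as.matrix(x)), as.integer(y), C)
}

#' Fit the directional CPM classifier
#'
#' Runs the full training pipeline on the training cohort only:
#' [edgewise_label_correlation()] against the diagnosis label,
#' [select_directional_features()] at the p-threshold,
#' [summarize_features()] for the requested direction mode, then a
#' soft-margin linear classifier (hinge loss, box constraint `C`, no
#' standardization) on the resulting 1- or 2-dimensional scores. If every
#' mask the mode uses is empty, the model is a majority-class fallback
#' (training-label majority, ties toward control) and a warning is issued.
#'
#' @param train a [cohort_dataset()] (training subjects only).
#' @param mode `"increased"`, `"decreased"`, or `"both"`.
#' @param threshold p-value threshold for feature selection.
#' @param C box constraint of the linear classifier (default 1).
#' @return An object of class `cpm_model`.
#' @export
fit_cpm <- function(train, mode, threshold = 0.05, C = 1) {
  mode <- check_mode(mode)
  stopifnot(inherits(train, "cohort_dataset"), C > 0)
  if (length(unique(train$labels)) < 2L) {
    stop("training set contains a single class; cannot fit", call. = FALSE)
  }
  rp <- edgewise_label_correlation(train$edges, train$labels)
  selection <- select_directional_features(rp$r, rp$p, threshold)
  feats <- summarize_features(train$edges, selection, mode)
  dirs <- if (mode == "both") c("increased", "decreased") else mode
  all_empty <- length(attr(feats, "empty_masks")) == length(dirs)
  model <- list(mode = mode, threshold = threshold, C = C,
                selection = selection, n_nodes = train$n_nodes,
                n_edges = ncol(train$edges),
                fallback = all_empty, fallback_label = NA_integer_,
                w = NULL, b = NULL)
  if (all_empty) {
    n1 <- sum(train$labels == 1)
    n0 <- sum(train$labels == 0)
    model$fallback_label <- if (n1 > n0) 1L else 0L  # tie -> control
    warning("no edges survived selection at p < ", threshold, " for mode '",
            mode, "'; falling back to majority class ", model$fallback_label,
            call. = FALSE)
  } else {
    rule <- fit_linear_rule(feats, train$labels, C)
    model$w <- rule$w
    model$b <- rule$b
  }
  structure(model, class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  cat("<cpm_model> mode ", x$mode, ", p < ", x$threshold, ", C = ", x$C,
      "\n", sep = "")
  if (x$fallback) {
    cat("  fallback model: always predicts ", x$fallback_label, "\n", sep = "")
  } else {
    cat("  ", sum(x$selection$increased), " increased / ",
        sum(x$selection$decreased), " decreased edges; weights [",
        paste(signif(x$w, 4), collapse = ", "), "], intercept ",
        signif(x$b, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Predict group labels with a fitted CPM
#'
#' Computes the summed-edge scores of new subjects using the masks derived
#' from the model's training data (never refit on test data) and applies the
#' stored linear decision rule: predict patient (1) iff the decision value
#' is >= 0. A fallback model predicts its stored majority label for every
#' subject. Predictions depend only on edges inside the model's masks.
#'
#' @param model a `cpm_model`.
#' @param test_edges numeric `m x E` matrix (same edge order and count as
#'   training), or a [cohort_dataset()].
#' @return integer vector of predicted labels (0/1).
#' @export
predict_cpm <- function(model, test_edges) {
  stopifnot(inherits(model, "cpm_model"))
  if (inherits(test_edges, "cohort_dataset")) test_edges <- test_edges$edges
  stopifnot(is.matrix(test_edges))
  if (ncol(test_edges) != model$n_edges) {
    stop("test edge matrix has ", ncol(test_edges),
         " columns but the model was trained with ", model$n_edges,
         call. = FALSE)
  }
  if (model$fallback) {
    return(rep(model$fallback_label, nrow(test_edges)))
  }
  feats <- summarize_features(test_edges, model$selection, model$mode)
  dv <- as.vector(feats %*% model$w + model$b)
  as.integer(dv >= 0)
}
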