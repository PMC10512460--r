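#' Read a phenotype table
#'
#' Delimited text with header `subject,label` (label 0 = control,
#' 1 = patient); extra covariate columns are carried through but ignored by
#' the core analyses.
#'
#' @param path file path.
#' @return data.frame with character `subject` and integer `label`.
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  if (!all(c("subject", "label") %in% names(tab))) {
    stop("phenotype table must have header 'subject,label': ", path,
         call. = FALSE)
  }
  bad <- which(!(tab$label %in% c(0, 1)))
  if (length(bad)) {
    stop("phenotype row ", bad[1], " (subject ", tab$subject[bad[1]],
         ") has label '", tab$label[bad[1]], "'; labels must be 0 or 1",
         call. = FALSE)
  }
  tab$subject <- as.character(tab$subject)
  tab$label <- as.integer(tab$label)
  tab
}

find_subject_file <- function(dir, subject) {
  cand <- file.path(dir, c(subject, paste0(subject, c(".txt", ".csv", ".tsv"))))
  hit <- cand[file.exists(cand)]
  if (!length(hit)) {
    stop("no connectivity matrix file for subject '", subject, "' in ", dir,
         call. = FALSE)
  }
  hit[1]
}

read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  as.matrix(utils::read.table(path, header = FALSE, sep = sep))
}

#' Load a cohort from per-subject connectivity matrix files
#'
#' Reads one square delimited matrix file per phenotype row (file name =
#' subject id, optionally with a `.txt`/`.csv`/`.tsv` extension), validates
#' symmetry and finiteness, converts raw correlation inputs to Fisher z if
#' `scale = "r"`, and assembles the canonical subjects-by-edges matrix in
#' phenotype-table order.
#'
#' @param matrix_dir directory of per-subject matrix files.
#' @param phenotype_path path to the phenotype table ([read_phenotype()]).
#' @param scale `"z"` if the stored matrices are already Fisher-z (the usual
#'   deposit convention) or `"r"` for raw Pearson correlations. There is no
#'   default: the caller must declare the input scale.
#' @return A [cohort_dataset()].
#' @export
load_cohort <- function(matrix_dir, phenotype_path, scale = c("z", "r")) {
  scale <- match.arg(scale)
  pheno <- read_phenotype(phenotype_path)
  mats <- vector("list", nrow(pheno))
  n_nodes <- NULL
  for (i in seq_len(nrow(pheno))) {
    path <- find_subject_file(matrix_dir, pheno$subject[i])
    m <- tryCatch(read_matrix_file(path),
                  error = function(e) stop("subject ", pheno$subject[i], " (",
                                           path, "): ", conditionMessage(e),
                                           call. = FALSE))
    if (nrow(m) != ncol(m)) {
      stop("subject ", pheno$subject[i], ": matrix is ", nrow(m), "x",
           ncol(m), ", expected square", call. = FALSE)
    }
    if (is.null(n_nodes)) {
      n_nodes <- nrow(m)
    } else if (nrow(m) != n_nodes) {
      stop("subject ", pheno$subject[i], ": ", nrow(m),
           " nodes but previous subjects have ", n_nodes, call. = FALSE)
    }
    if (!all(is.finite(m))) {
      stop("subject ", pheno$subject[i], ": non-finite values in ", path,
           call. = FALSE)
    }
    v <- tryCatch(vectorize_edges(m),
                  error = function(e) stop("subject ", pheno$subject[i], ": ",
                                           conditionMessage(e), call. = FALSE))
    if (scale == "r") v <- fisher_z(v)
    mats[[i]] <- v
  }
  edges <- do.call(rbind, mats)
  cohort_dataset(edges, pheno$label, subject_ids = pheno$subject,
                 n_nodes = n_nodes)
}

#' Write a cohort as per-subject matrix files plus a phenotype table
#'
#' The on-disk inverse of [load_cohort()] (always written on the Fisher-z
#' scale): one `<subject>.txt` whitespace-delimited square matrix per
#' subject and a `phenotype.csv`.
#'
#' @param cohort a [cohort_dataset()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$subject_ids)) {
    m <- devectorize_edges(cohort$edges[i, ], cohort$n_nodes)
    utils::write.table(m, file.path(dir, paste0(cohort$subject_ids[i], ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(data.frame(subject = cohort$subject_ids,
                                label = cohort$labels),
                     file.path(dir, "phenotype.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a panel of node time series from delimited files
#'
#' One file per subject (rows = nodes, columns = timepoints), file name =
#' subject id as in [load_cohort()].
#'
#' @param ts_dir directory of per-subject time-series files.
#' @param phenotype_path phenotype table path.
#' @return list with `panel` (a [timeseries_panel()]) and `labels`.
#' @export
load_timeseries <- function(ts_dir, phenotype_path) {
  pheno <- read_phenotype(phenotype_path)
  data <- vector("list", nrow(pheno))
  for (i in seq_len(nrow(pheno))) {
    path <- find_subject_file(ts_dir, pheno$subject[i])
    data[[i]] <- read_matrix_file(path)
  }
  list(panel = timeseries_panel(data, pheno$subject), labels = pheno$label)
}

#' Serialize a fitted CPM model to JSON
#'
#' Stores the mode, threshold, box constraint, 0-based mask indices in
#' canonical edge order, classifier weights and intercept, and the fallback
#' state, sufficient to reconstruct the exact decision rule with
#' [read_cpm_model()].
#'
#' @param model a `cpm_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cpm_model <- function(model, path) {
  stopifnot(inherits(model, "cpm_model"))
  doc <- list(mode = model$mode, threshold = model$threshold, C = model$C,
              n_nodes = model$n_nodes, n_edges = model$n_edges,
              increased_edges = which(model$selection$increased) - 1L,
              decreased_edges = which(model$selection$decreased) - 1L,
              weights = model$w, intercept = model$b,
              fallback = model$fallback,
              fallback_label = model$fallback_label)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a CPM model serialized with [write_cpm_model()]
#'
#' @param path JSON file path.
#' @return A `cpm_model` usable with [predict_cpm()].
#' @export
read_cpm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_edges <- as.integer(doc$n_edges)
  mask <- function(idx) {
    m <- logical(n_edges)
    m[as.integer(idx) + 1L] <- TRUE
    m
  }
  selection <- structure(list(r = NULL, p = NULL, threshold = doc$threshold,
                              increased = mask(doc$increased_edges),
                              decreased = mask(doc$decreased_edges)),
                         class = "directional_selection")
  structure(list(mode = doc$mode, threshold = doc$threshold, C = doc$C,
                 selection = selection, n_nodes = as.integer(doc$n_nodes),
                 n_edges = n_edges,
                 fallback = isTRUE(doc$fallback),
                 fallback_label = if (is.null(doc$fallback_label) ||
                                      is.na(doc$fallback_label)) NA_integer_
                                  else as.integer(doc$fallback_label),
                 w = if (is.null(doc$weights)) NULL else as.numeric(doc$weights),
                 b = if (is.null(doc$intercept)) NULL else as.numeric(doc$intercept)),
            class = "cpm_model")
}
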