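#' Assemble a run report
#'
#' Collects the outcomes of a full analysis run -- per-mode cross-validation
#' accuracies, permutation and sign-test p-values, an optional
#' threshold-search table, and network count matrices -- into a single
#' self-contained list that can be written as JSON and rendered as plain
#' text. Every report embeds the configuration and seed that produced it, so
#' the text rendering is regenerable from the JSON alone.
#'
#' @param outcomes named list of `cv_outcome` objects (names are row labels,
#'   e.g. the mode).
#' @param permutations optional named list of `permutation_result` objects.
#' @param sign_tests optional named numeric vector of sign-test p-values.
#' @param search optional `$table` data.frame from [threshold_search()].
#' @param network_counts optional named list of `network_counts` objects.
#' @param config optional list echoing the run configuration (threshold, k,
#'   B, C, seed, paths...).
#' @return An object of class `cpm_report`.
#' @export
cpm_report <- function(outcomes, permutations = NULL, sign_tests = NULL,
                       search = NULL, network_counts = NULL, config = NULL) {
  stopifnot(is.list(outcomes), length(outcomes) >= 1L,
            !is.null(names(outcomes)))
  rows <- lapply(names(outcomes), function(nm) {
    o <- outcomes[[nm]]
    list(name = nm, mode = o$mode, threshold = o$threshold,
         n = length(o$predictions), accuracy = o$accuracy,
         confusion = unname(apply(o$confusion, 1, as.list)))
  })
  perm <- if (!is.null(permutations)) {
    lapply(permutations, function(p) {
      list(observed_accuracy = p$observed_accuracy, p_value = p$p_value,
           B = p$B, seed = p$seed, evaluator = p$evaluator, mode = p$mode)
    })
  }
  nets <- if (!is.null(network_counts)) {
    lapply(network_counts, function(nc) {
      list(labels = nc$labels, counts = unname(apply(nc$counts, 1, as.list)))
    })
  }
  structure(list(results = rows, permutations = perm,
                 sign_tests = as.list(sign_tests),
                 threshold_search = search, network_counts = nets,
                 config = config),
            class = "cpm_report")
}

#' Write a report as JSON plus a plain-text summary
#'
#' @param report a [cpm_report()].
#' @param json_path,text_path destination files; either may be `NULL` to
#'   skip.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(report, "cpm_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  if (!is.null(text_path)) {
    writeLines(report_text(report), text_path)
  }
  invisible(report)
}

#' Re-read a report written by [write_report()]
#'
#' @param json_path JSON file path.
#' @return A `cpm_report` whose [report_text()] rendering is identical to
#'   the original's.
#' @export
read_report <- function(json_path) {
  doc <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  if (!is.null(doc$threshold_search)) {
    doc$threshold_search <- do.call(rbind, lapply(doc$threshold_search, \(r)
      data.frame(threshold = r$threshold, accuracy = r$accuracy)))
  }
  structure(doc, class = "cpm_report")
}

#' Render a report as deterministic plain text
#'
#' @param report a [cpm_report()].
#' @return character vector of lines.
#' @export
report_text <- function(report) {
  stopifnot(inherits(report, "cpm_report"))
  num <- function(x) format(as.numeric(x), digits = 6)
  out <- c("=== directional CPM run report ===", "")
  out <- c(out, "-- classification accuracy --")
  for (r in report$results) {
    cm <- r$confusion
    out <- c(out, sprintf("%-28s mode=%-9s p<%s  n=%d  accuracy=%s",
                          r$name, r$mode, num(r$threshold), as.integer(r$n),
                          num(r$accuracy)),
             sprintf("    confusion [true x pred]: [[%d, %d], [%d, %d]]",
                     as.integer(cm[[1]][[1]]), as.integer(cm[[1]][[2]]),
                     as.integer(cm[[2]][[1]]), as.integer(cm[[2]][[2]])))
  }
  if (length(report$permutations)) {
    out <- c(out, "", "-- permutation tests --")
    for (nm in names(report$permutations)) {
      p <- report$permutations[[nm]]
      out <- c(out, sprintf("%-28s %s  accuracy=%s  p=%s  (B=%d, seed=%d)",
                            nm, p$evaluator, num(p$observed_accuracy),
                            num(p$p_value), as.integer(p$B),
                            as.integer(p$seed)))
    }
  }
  if (length(report$sign_tests)) {
    out <- c(out, "", "-- sign tests --")
    for (nm in names(report$sign_tests)) {
      out <- c(out, sprintf("%-28s p=%s", nm, num(report$sign_tests[[nm]])))
    }
  }
  if (!is.null(report$threshold_search)) {
    out <- c(out, "", "-- threshold search (LOOCV accuracy) --")
    tab <- report$threshold_search
    for (i in seq_len(nrow(tab))) {
      out <- c(out, sprintf("p < %-8s accuracy=%s", num(tab$threshold[i]),
                            num(tab$accuracy[i])))
    }
  }
  if (length(report$network_counts)) {
    out <- c(out, "", "-- network pair edge counts --")
    for (nm in names(report$network_counts)) {
      nc <- report$network_counts[[nm]]
      labels <- unlist(nc$labels)
      out <- c(out, paste0(nm, ":"),
               paste0("    ", paste(sprintf("%4s", labels), collapse = " ")))
      for (i in seq_along(labels)) {
        row <- vapply(nc$counts[[i]], function(x) as.integer(x), integer(1))
        out <- c(out, paste0(sprintf("%4s", labels[i]),
                             paste(sprintf("%4d", row), collapse = " "), ""))
      }
    }
  }
  if (!is.null(report$config)) {
    out <- c(out, "", "-- config --")
    cfg <- report$config
    for (nm in names(cfg)) {
      out <- c(out, sprintf("%s = %s", nm,
                            paste(format(unlist(cfg[[nm]])), collapse = ", ")))
    }
  }
  out
}

#' @export
print.cpm_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}
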