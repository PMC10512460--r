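# Thin call into libsvm (via e1071's registered 'svmtrain' routine) for the
# package's only classifier shape: binary C-classification with a linear
# kernel on 1-2 features, no scaling. Skipping the high-level wrapper
# matters because cross-validation and permutation nulls refit this
# classifier hundreds of thousands of times; equivalence with e1071::svm is
# asserted in the test suite.

.svm_cache <- new.env(parent = emptyenv())

svmtrain_symbol <- function() {
  if (is.null(.svm_cache$sym)) {
    dll <- getLoadedDLLs()[["e1071"]]
    if (is.null(dll)) {
      loadNamespace("e1071")
      dll <- getLoadedDLLs()[["e1071"]]
    }
    .svm_cache$sym <- getDLLRegisteredRoutines(dll)$.C[["svmtrain"]]
  }
  .svm_cache$sym
}

# x: numeric matrix (n x k), y01: integer 0/1 labels, C: box constraint.
# Returns the explicit rule list(w, b) with the orientation normalised so
# that decision value x . w + b > 0 means class 1.
fast_linear_svm <- function(x, y01, C) {
  nr <- nrow(x)
  nc <- ncol(x)
  empty_string <- paste(rep(" ", 255), collapse = "")
  cret <- .C(svmtrain_symbol(),
             as.double(t(x)), as.integer(nr), as.integer(nc),
             as.double(y01 + 1), as.integer(0), as.integer(0),
             as.integer(0),           # type: C-classification
             as.integer(0),           # kernel: linear
             as.integer(3),           # degree (unused for linear)
             as.double(1 / nc),       # gamma (unused for linear)
             as.double(0),            # coef0
             as.double(C),            # cost
             as.double(0.5),          # nu (unused)
             integer(0), double(0), as.integer(0),  # no class weights
             as.double(40),           # cachesize
             as.double(0.001),        # tolerance
             as.double(0.1),          # epsilon (unused)
             as.integer(1),           # shrinking
             as.integer(0),           # cross
             as.integer(0),           # sparse
             as.integer(0),           # probability
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(1), ctotal1 = double(1),
             ctotal2 = double(1), error = empty_string)
  if (cret$error != empty_string) {
    stop("libsvm: ", trimws(cret$error), call. = FALSE)
  }
  nsv <- cret$nr
  idx <- cret$index[seq_len(nsv)]
  coefs <- cret$coefs[seq_len(nsv)]
  w <- as.vector(crossprod(coefs, x[idx, , drop = FALSE]))
  b <- -cret$rho[1]
  # libsvm orients the decision function toward the class it saw first
  # (labels[1], on the 1/2 coding used above); flip so positive means class 1
  if (cret$labels[1] == 1L) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}
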