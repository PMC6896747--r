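# TF-IDF weighting with top-fraction token retention, fitted on training
# rows only so that held-out folds never leak into the feature space.

#' Fit TF-IDF weights and top-fraction token selection
#'
#' Computes, on the training matrix only, the inverse document frequency
#' `idf(token) = ln(N / df(token))` (N = number of training documents, df =
#' number of training documents containing the token; no smoothing), ranks
#' tokens by their total TF-IDF mass over the training documents (descending,
#' ties broken lexicographically) and retains the top
#' `ceiling(retain_fraction * V)` of the `V` tokens observed in the training
#' documents (minimum 1). Tokens absent from every training document carry no
#' information for the fit and are excluded, which also makes the fitted
#' model invariant to tokens that occur only in held-out documents.
#'
#' @param training_dtm a `screen_dtm` with `weighting = "tf"`.
#' @param retain_fraction fraction of the training vocabulary to keep,
#'   in (0, 1]; default 0.04 (the "top 4%" rule).
#' @return an object of class `tfidf_model`: list with `vocabulary` (retained
#'   tokens in rank order), `idf` (named numeric), `n_training_docs`,
#'   `retain_fraction`.
#' @seealso [apply_tfidf()], [align_features()]
#' @export
fit_tfidf <- function(training_dtm, retain_fraction = 0.04) {
  stopifnot(inherits(training_dtm, "screen_dtm"))
  if (training_dtm$weighting != "tf") {
    stop("fit_tfidf() expects a TF-weighted matrix", call. = FALSE)
  }
  if (!is.numeric(retain_fraction) || length(retain_fraction) != 1 ||
      retain_fraction <= 0 || retain_fraction > 1) {
    stop("retain_fraction must be in (0, 1]", call. = FALSE)
  }
  m <- training_dtm$weights
  n <- nrow(m)
  df <- Matrix::colSums(m > 0)
  present <- df > 0
  tokens <- colnames(m)[present]
  df <- df[present]
  idf <- log(n / df)
  mass <- as.numeric(Matrix::colSums(m[, present, drop = FALSE])) * idf
  ord <- order(-mass, tokens)
  v <- length(tokens)
  n_keep <- max(1L, min(v, as.integer(ceiling(retain_fraction * v))))
  keep <- ord[seq_len(n_keep)]
  structure(
    list(
      vocabulary = tokens[keep],
      idf = stats::setNames(idf[keep], tokens[keep]),
      n_training_docs = n,
      retain_fraction = retain_fraction
    ),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf(
    "<tfidf_model> %d tokens retained (top %.1f%%) from %d training documents\n",
    length(x$vocabulary), 100 * x$retain_fraction, x$n_training_docs))
  cat("  idf range: [", sprintf("%.4f", min(x$idf)), ", ",
      sprintf("%.4f", max(x$idf)), "]\n", sep = "")
  invisible(x)
}

#' Rescale a DTM with a fitted TF-IDF model
#'
#' Aligns the matrix to the model's retained vocabulary (see
#' [align_features()]) and multiplies each column by the idf fitted on the
#' training data. The idf values are never re-estimated from `dtm`, so the
#' transform is leakage-safe for held-out folds: a held-out document whose
#' tokens are all outside the model vocabulary simply becomes an all-zero
#' row.
#'
#' @param model a `tfidf_model` from [fit_tfidf()].
#' @param dtm a `screen_dtm` with `weighting = "tf"`.
#' @return a `screen_dtm` with `weighting = "tfidf"` and columns exactly
#'   `model$vocabulary`.
#' @export
apply_tfidf <- function(model, dtm) {
  stopifnot(inherits(model, "tfidf_model"), inherits(dtm, "screen_dtm"))
  if (dtm$weighting != "tf") {
    stop("apply_tfidf() expects a TF-weighted matrix", call. = FALSE)
  }
  aligned <- align_features(model$vocabulary, dtm)
  w <- aligned$weights %*% Matrix::Diagonal(x = model$idf)
  w <- as(w, "CsparseMatrix")
  dimnames(w) <- dimnames(aligned$weights)
  new_screen_dtm(w, weighting = "tfidf", labels = dtm$labels)
}

#' Align a DTM to a reference vocabulary
#'
#' Reorders the columns of `dtm` to exactly match `vocabulary`: columns
#' absent from the matrix are added as zeros, columns not in the vocabulary
#' are dropped, rows are untouched. This is the feature-alignment step that
#' adapts a held-out (or external) document set to the feature space fitted
#' on training data.
#'
#' @param vocabulary character vector of tokens defining the target columns
#'   and their order.
#' @param dtm a `screen_dtm`.
#' @return a `screen_dtm` with columns exactly `vocabulary`, same weighting
#'   and labels as the input.
#' @export
align_features <- function(vocabulary, dtm) {
  stopifnot(inherits(dtm, "screen_dtm"))
  m <- dtm$weights
  pos <- match(vocabulary, colnames(m))
  out <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(nrow(m), length(vocabulary)),
    dimnames = list(rownames(m), vocabulary)
  )
  found <- !is.na(pos)
  if (any(found)) {
    out[, which(found)] <- m[, pos[found], drop = FALSE]
  }
  new_screen_dtm(as(out, "CsparseMatrix"), dtm$weighting, dtm$labels)
}

#' Serialise a TF-IDF model to a two-column table
#'
#' Writes (token, idf) rows in rank order; reading restores an equivalent
#' model given the training-set size.
#'
#' @param model a `tfidf_model`.
#' @param path file path for a delimited (CSV) table.
#' @return `write_tfidf_model()` returns `path` invisibly;
#'   `read_tfidf_model()` returns a `tfidf_model` (with `n_training_docs`
#'   and `retain_fraction` as stored in the file's comment-free columns).
#' @export
write_tfidf_model <- function(model, path) {
  df <- data.frame(
    token = model$vocabulary,
    idf = unname(model$idf),
    n_training_docs = model$n_training_docs,
    retain_fraction = model$retain_fraction
  )
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tfidf_model
#' @export
read_tfidf_model <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8",
                 colClasses = c(token = "character"))
  structure(
    list(
      vocabulary = df$token,
      idf = stats::setNames(df$idf, df$token),
      n_training_docs = df$n_training_docs[1],
      retain_fraction = df$retain_fraction[1]
    ),
    class = "tfidf_model"
  )
}
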