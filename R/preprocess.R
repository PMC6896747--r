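# Text preprocessing: tokenisation, stemming, bigrams, sparse DTM.

#' Tokenise and stem free text
#'
#' Applies the standard preprocessing chain for bag-of-words screening
#' models: lowercase, replace every character outside `a-z` with a space,
#' split on whitespace, drop tokens shorter than two letters (artifacts of
#' punctuation stripping), and stem each token with [porter_stem()].
#'
#' @param raw character vector; elements are concatenated with single spaces
#'   before tokenisation (so `preprocess_text(c(title, abstract))` treats the
#'   two fields as one text).
#' @return character vector of stemmed unigram tokens (possibly empty).
#' @examples
#' preprocess_text("Randomized, Controlled Trials.")
#' @export
preprocess_text <- function(raw) {
  txt <- tolower(paste(raw, collapse = " "))
  txt <- gsub("[^a-z]+", " ", txt)
  tokens <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  tokens <- tokens[nchar(tokens) >= 2]
  if (length(tokens) == 0) return(character(0))
  porter_stem(tokens)
}

#' Append adjacent-pair bigram tokens
#'
#' Every pair of adjacent (already stemmed) unigrams is joined with `"_"`
#' and appended as an additional single token, so a sequence of `n >= 1`
#' unigrams yields `2n - 1` tokens. Bigrams carry local word-order
#' information into an otherwise order-free bag of words.
#'
#' @param tokens character vector of stemmed unigrams.
#' @return character vector: the unigrams followed by their bigram tokens.
#' @examples
#' add_bigrams(c("random", "control", "trial"))
#' @export
add_bigrams <- function(tokens) {
  n <- length(tokens)
  if (n < 2) return(tokens)
  c(tokens, paste(tokens[-n], tokens[-1], sep = "_"))
}

#' Build a term-frequency document-term matrix
#'
#' Concatenates title and abstract of each document, tokenises with
#' [preprocess_text()], adds bigrams with [add_bigrams()], and counts token
#' occurrences into a sparse documents-by-tokens matrix. The vocabulary is
#' the sorted set of distinct tokens across the corpus; entries are raw term
#' frequencies (TF).
#'
#' @param corpus a [screen_corpus].
#' @param bigrams logical; include adjacent-pair bigram tokens (default TRUE).
#' @return an object of class `screen_dtm`: a list with elements `weights`
#'   (a [Matrix::dgCMatrix] with documents as rows and tokens as columns),
#'   `weighting` (`"tf"`), and `labels` (factor aligned to the rows).
#' @export
build_dtm <- function(corpus, bigrams = TRUE) {
  stopifnot(inherits(corpus, "screen_corpus"))
  texts <- paste(corpus$title, corpus$abstract)
  token_lists <- lapply(texts, function(tx) {
    tk <- preprocess_text(tx)
    if (bigrams) add_bigrams(tk) else tk
  })
  all_tokens <- unlist(token_lists, use.names = FALSE)
  if (length(all_tokens) == 0) {
    stop("corpus yields no tokens after preprocessing", call. = FALSE)
  }
  vocab <- sort(unique(all_tokens))
  i <- rep.int(seq_along(token_lists),
               vapply(token_lists, length, integer(1)))
  j <- match(all_tokens, vocab)
  weights <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(nrow(corpus), length(vocab)),
    dimnames = list(corpus$doc_id, vocab)
  )
  new_screen_dtm(weights, weighting = "tf", labels = as_label(corpus$label))
}

# Internal constructor; callers guarantee alignment of labels to rows.
new_screen_dtm <- function(weights, weighting, labels) {
  stopifnot(nrow(weights) == length(labels))
  structure(
    list(weights = weights, weighting = weighting, labels = labels),
    class = "screen_dtm"
  )
}

#' @export
print.screen_dtm <- function(x, ...) {
  st <- dtm_stats(x)
  cat(sprintf(
    "<screen_dtm> %d documents x %d tokens (%s weights), sparsity %.4f\n",
    st$n_documents, st$n_tokens, toupper(x$weighting), st$sparsity))
  cat("  labels:", sum(x$labels == "positive"), "positive,",
      sum(x$labels == "negative"), "negative\n")
  invisible(x)
}

#' @export
dim.screen_dtm <- function(x) dim(x$weights)

# Row subset of a DTM keeping labels aligned.
dtm_rows <- function(dtm, idx) {
  new_screen_dtm(dtm$weights[idx, , drop = FALSE], dtm$weighting,
                 dtm$labels[idx])
}

#' Summary statistics of a document-term matrix
#'
#' Reports the dimensions, zero / non-zero cell counts and the sparsity
#' (fraction of zero cells) of a DTM — the characteristics by which
#' screening corpora are usually described (sparsity is typically about
#' 99%).
#'
#' @param dtm a `screen_dtm`, or any matrix-like object.
#' @return a data frame with one row: `n_documents`, `n_tokens`,
#'   `n_nonzero`, `n_zero`, `sparsity`.
#' @export
dtm_stats <- function(dtm) {
  m <- if (inherits(dtm, "screen_dtm")) dtm$weights else dtm
  n_doc <- nrow(m)
  n_tok <- ncol(m)
  total <- as.numeric(n_doc) * as.numeric(n_tok)
  nnz <- as.numeric(Matrix::nnzero(m))
  data.frame(
    n_documents = n_doc, n_tokens = n_tok,
    n_nonzero = nnz, n_zero = total - nnz,
    sparsity = if (total > 0) (total - nnz) / total else NA_real_
  )
}

#' Export / import a vocabulary as plain text
#'
#' One token per line, order preserved. Used to carry a fitted feature space
#' across processes (e.g. for aligning an external test set).
#'
#' @param vocabulary character vector of tokens.
#' @param path file path.
#' @return `write_vocabulary()` returns `path` invisibly; `read_vocabulary()`
#'   returns the character vector.
#' @export
write_vocabulary <- function(vocabulary, path) {
  writeLines(vocabulary, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) readLines(path, encoding = "UTF-8")
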