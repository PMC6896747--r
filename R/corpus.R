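# Labeled citation corpora: construction, validation, reading and writing.

#' Construct a labeled citation corpus
#'
#' A corpus holds the screening records of one systematic review: one row per
#' citation with its title, abstract and binary relevance label ("positive" =
#' included in the review, "negative" = irrelevant). Positives are typically
#' outnumbered by negatives at 20:1 or worse, which is the imbalance the
#' evaluation pipeline is about.
#'
#' @param doc_id character vector of unique document identifiers.
#' @param review_id single review identifier (all documents must share it).
#' @param title,abstract character vectors of free text; abstracts may be
#'   empty strings (records without abstracts contribute title tokens only).
#' @param label vector of `"positive"`/`"negative"` labels.
#' @return an object of class `screen_corpus`: a data frame with columns
#'   `doc_id`, `review_id`, `title`, `abstract`, `label` and attributes
#'   `review_id`, `n_pos`, `n_neg`.
#' @seealso [read_corpus()], [subsample_negatives()], [generate_corpus()]
#' @export
screen_corpus <- function(doc_id, review_id, title, abstract, label) {
  df <- data.frame(
    doc_id = as.character(doc_id),
    review_id = as.character(review_id),
    title = as.character(title),
    abstract = as.character(abstract),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  validate_corpus(df)
}

#' @rdname screen_corpus
#' @param x a data frame with the corpus columns.
#' @export
validate_corpus <- function(x) {
  required <- c("doc_id", "review_id", "title", "abstract", "label")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$doc_id)) {
    dup <- unique(x$doc_id[duplicated(x$doc_id)])
    stop("duplicate doc_id value(s): ", paste(head(dup, 3), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(x$review_id)) > 1) {
    stop("a corpus must contain a single review_id; found: ",
         paste(unique(x$review_id), collapse = ", "),
         " (use read_corpora() for multi-review files)", call. = FALSE)
  }
  lab <- as_label(x$label)
  n_pos <- sum(lab == "positive")
  n_neg <- sum(lab == "negative")
  if (n_pos < 1 || n_neg < 1) {
    stop("corpus must contain at least one positive and one negative ",
         "document (got ", n_pos, " positive, ", n_neg, " negative)",
         call. = FALSE)
  }
  structure(
    x[, required],
    class = c("screen_corpus", "data.frame"),
    review_id = x$review_id[1], n_pos = n_pos, n_neg = n_neg
  )
}

#' @export
print.screen_corpus <- function(x, ...) {
  cat("<screen_corpus> review", attr(x, "review_id"), "-",
      nrow(x), "documents:", attr(x, "n_pos"), "positive,",
      attr(x, "n_neg"), "negative",
      sprintf("(1:%.1f)\n", attr(x, "n_neg") / attr(x, "n_pos")))
  invisible(x)
}

#' Number of positive / negative documents in a corpus
#' @param corpus a `screen_corpus`.
#' @return integer count.
#' @export
n_pos <- function(corpus) attr(corpus, "n_pos")

#' @rdname n_pos
#' @export
n_neg <- function(corpus) attr(corpus, "n_neg")

#' Read and write citation corpora
#'
#' The canonical on-disk format is a delimited table (CSV) with header
#' `doc_id,review_id,title,abstract,label`, UTF-8 encoded, labels written as
#' the literals `"positive"`/`"negative"`. A structured-text dialect (JSON
#' lines, one record per line with the same field names) is accepted as an
#' alternative. Document order is preserved exactly on a write/read
#' round-trip.
#'
#' @param path file path.
#' @param format `"csv"` (delimited table) or `"jsonl"` (JSON lines);
#'   `"auto"` infers from the file extension (`.jsonl`/`.ndjson` vs anything
#'   else).
#' @return `read_corpus()` returns a validated [screen_corpus] (the file must
#'   contain a single review); `read_corpora()` returns a named list of
#'   corpora, one per review, for multi-review files; `write_corpus()`
#'   returns `path` invisibly.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  df <- .read_corpus_table(path, match.arg(format))
  validate_corpus(df)
}

#' @rdname read_corpus
#' @export
read_corpora <- function(path, format = c("auto", "csv", "jsonl")) {
  df <- .read_corpus_table(path, match.arg(format))
  if (!"review_id" %in% names(df)) stop("missing column: review_id", call. = FALSE)
  out <- lapply(split(df, factor(df$review_id, levels = unique(df$review_id))),
                validate_corpus)
  out[unique(df$review_id)]
}

.read_corpus_table <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
  }
  if (format == "jsonl") {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  }
  required <- c("doc_id", "review_id", "title", "abstract", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("corpus file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in required) df[[col]] <- as.character(df[[col]])
  df
}

#' @rdname read_corpus
#' @param corpus a [screen_corpus] (or plain data frame with the corpus
#'   columns) to write.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
  }
  df <- as.data.frame(corpus)[, c("doc_id", "review_id", "title", "abstract", "label")]
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE)
  } else {
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Cap the number of negatives relative to positives
#'
#' Downsamples the negative class to at most `negatives_per_positive`
#' negatives per positive, drawing a uniform random subset without
#' replacement. All positives are kept, as is the original document order of
#' the retained records. This reproduces the corpus-construction rule of
#' screening studies that retain a 1:20 positive:negative ratio when the
#' search returns more off-topic records than that.
#'
#' @param corpus a [screen_corpus].
#' @param negatives_per_positive positive number; the cap on
#'   negatives/positives (default 20).
#' @param seed integer seed making the subset reproducible.
#' @return a [screen_corpus] with `n_pos` unchanged and
#'   `min(n_neg, n_pos * negatives_per_positive)` negatives.
#' @export
subsample_negatives <- function(corpus, negatives_per_positive = 20, seed = 1L) {
  if (!is.numeric(negatives_per_positive) || negatives_per_positive <= 0) {
    stop("negatives_per_positive must be a positive number", call. = FALSE)
  }
  lab <- as_label(corpus$label)
  neg_idx <- which(lab == "negative")
  target <- min(length(neg_idx), floor(n_pos(corpus) * negatives_per_positive))
  if (target >= length(neg_idx)) return(corpus)
  keep_neg <- with_seed(seed, sample(neg_idx, target))
  keep <- sort(c(which(lab == "positive"), keep_neg))
  validate_corpus(as.data.frame(corpus)[keep, , drop = FALSE])
}
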