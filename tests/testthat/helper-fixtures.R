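# Shared fixtures and independent oracles used across test files.

# Tiny hand-built corpus: 2 positives among 8 documents, distinct texts.
tiny_corpus <- function() {
  screen_corpus(
    doc_id = sprintf("d%02d", 1:8),
    review_id = "tiny",
    title = c("apple banana apple", "banana cherry", "cherry date fig",
              "grape apple", "banana banana fig", "date grape cherry",
              "fig grape", "apple cherry date"),
    abstract = c("", "melon melon", "", "kiwi", "", "melon kiwi", "", ""),
    label = c("positive", "positive", rep("negative", 6))
  )
}

# Separable corpus: positive vocabulary disjoint from negative vocabulary.
separable_corpus <- function(n_pos = 10, n_neg = 40, seed = 1) {
  spec <- synthetic_spec("sep", n_pos = n_pos, n_neg = n_neg,
                         vocab_background = 200, vocab_topic = 40,
                         separation = 1, title_length_mean = 6,
                         abstract_length_mean = 30, seed = seed)
  generate_corpus(spec)
}

# Brute-force all-pairs AUC oracle (ties count one half).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Brute-force TF-IDF oracle: entry = count * ln(N / df), computed entrywise
# on a dense matrix restricted to a given vocabulary.
tfidf_bruteforce <- function(tf_dense, vocabulary) {
  n <- nrow(tf_dense)
  out <- matrix(0, n, length(vocabulary),
                dimnames = list(rownames(tf_dense), vocabulary))
  for (j in seq_along(vocabulary)) {
    tok <- vocabulary[j]
    if (!tok %in% colnames(tf_dense)) next
    cnt <- tf_dense[, tok]
    df <- sum(cnt > 0)
    if (df == 0) next
    out[, j] <- cnt * log(n / df)
  }
  out
}

# Direct textbook inverse-variance fixed-effect pooling.
pool_bruteforce <- function(delta, variance) {
  w <- 1 / variance
  est <- sum(w * delta) / sum(w)
  se <- sqrt(1 / sum(w))
  list(est = est, se = se, lo = est - 1.96 * se, hi = est + 1.96 * se)
}

# Build a screen_dtm directly from a dense matrix (for unit tests).
dtm_from_dense <- function(m, labels, weighting = "tf") {
  citescreen:::new_screen_dtm(
    methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                "CsparseMatrix"),
    weighting = weighting,
    labels = factor(labels, levels = c("negative", "positive"))
  )
}
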