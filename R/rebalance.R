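# Random under-/oversampling of training rows to a target minority share.

#' Specify an imbalance-handling method
#'
#' @param method `"none"`, `"rus"` (random undersampling: discard random
#'   majority rows) or `"ros"` (random oversampling: duplicate random
#'   minority rows with replacement).
#' @param minority_share target minority share of the resampled training
#'   set, in (0, 0.5]: `0.50` for a 50:50 ratio, `0.35` for 35:65. Ignored
#'   when `method = "none"`.
#' @param seed optional integer seed; may be left `NULL` and supplied at
#'   resampling time (the evaluation grid derives per-cell seeds itself).
#' @return an object of class `balancing_spec`.
#' @examples
#' balancing_spec("rus", 0.35)
#' @export
balancing_spec <- function(method = c("none", "rus", "ros"),
                           minority_share = 0.5, seed = NULL) {
  method <- match.arg(method)
  if (method != "none") {
    if (!is.numeric(minority_share) || length(minority_share) != 1 ||
        minority_share <= 0 || minority_share > 0.5) {
      stop("minority_share must be in (0, 0.5]", call. = FALSE)
    }
  }
  structure(
    list(method = method,
         minority_share = if (method == "none") NA_real_ else minority_share,
         seed = seed),
    class = "balancing_spec"
  )
}

#' @export
print.balancing_spec <- function(x, ...) {
  cat("<balancing_spec>", balancing_label(x), "\n")
  invisible(x)
}

#' Human-readable label of a balancing spec ("none", "RUS-35:65", ...)
#' @param spec a [balancing_spec].
#' @return character scalar.
#' @export
balancing_label <- function(spec) {
  if (spec$method == "none") return("none")
  sprintf("%s-%d:%d", toupper(spec$method),
          round(100 * spec$minority_share),
          round(100 * (1 - spec$minority_share)))
}

# Identify minority/majority classes; ties resolve to positive = minority,
# matching the screening setting where positives are the rare class.
.min_maj <- function(labels) {
  labels <- as_label(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present for resampling", call. = FALSE)
  }
  n_by <- table(labels)
  minority <- if (n_by[["positive"]] <= n_by[["negative"]]) "positive" else "negative"
  list(minority = which(labels == minority),
       majority = which(labels != minority))
}

#' Random undersampling of the majority class
#'
#' Keeps every minority row and a uniform random subset (without
#' replacement) of the majority rows of size
#' `floor(n_min * (1 - s) / s)` with `s = minority_share`, capped at the
#' available majority count. The floor guarantees the achieved minority
#' share is at least `s` (up to the cap). Row order of the retained rows is
#' preserved.
#'
#' @param rows feature rows: a matrix, `Matrix` sparse matrix or
#'   `screen_dtm`.
#' @param labels binary label vector aligned to the rows (ignored and taken
#'   from `rows$labels` when `rows` is a `screen_dtm`).
#' @param spec a [balancing_spec] with `method = "rus"`.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a list with `rows`, `labels` and `idx` (the retained input row
#'   indices).
#' @export
random_undersample <- function(rows, labels = NULL, spec, seed = spec$seed) {
  stopifnot(spec$method == "rus")
  labels <- .resample_labels(rows, labels)
  cls <- .min_maj(labels)
  s <- spec$minority_share
  n_min <- length(cls$minority)
  target_maj <- min(length(cls$majority), floor(n_min * (1 - s) / s))
  keep_maj <- with_seed(seed, sample(cls$majority, target_maj))
  idx <- sort(c(cls$minority, keep_maj))
  .resample_result(rows, labels, idx)
}

#' Random oversampling of the minority class
#'
#' Keeps every original row and appends minority rows drawn uniformly with
#' replacement until the minority count reaches
#' `ceiling(n_maj * s / (1 - s))` with `s = minority_share` (never below the
#' original minority count; the ceiling guarantees the achieved minority
#' share is at least `s`). The majority class is untouched.
#'
#' @inheritParams random_undersample
#' @param spec a [balancing_spec] with `method = "ros"`.
#' @return a list with `rows`, `labels` and `idx` (input row indices, the
#'   originals followed by the duplicated minority indices).
#' @export
random_oversample <- function(rows, labels = NULL, spec, seed = spec$seed) {
  stopifnot(spec$method == "ros")
  labels <- .resample_labels(rows, labels)
  cls <- .min_maj(labels)
  s <- spec$minority_share
  n_min <- length(cls$minority)
  target_min <- max(n_min, ceiling(length(cls$majority) * s / (1 - s)))
  extra <- with_seed(seed,
    sample(cls$minority, target_min - n_min, replace = TRUE))
  idx <- c(seq_along(labels), extra)
  .resample_result(rows, labels, idx)
}

#' Apply a balancing spec to training rows
#'
#' Dispatches to [random_undersample()] / [random_oversample()] or returns
#' the input unchanged for `method = "none"`.
#'
#' @inheritParams random_undersample
#' @param spec a [balancing_spec].
#' @return a list with `rows`, `labels`, `idx`.
#' @export
rebalance <- function(rows, labels = NULL, spec, seed = spec$seed) {
  switch(spec$method,
    none = {
      labels <- .resample_labels(rows, labels)
      .resample_result(rows, labels, seq_along(labels))
    },
    rus = random_undersample(rows, labels, spec, seed),
    ros = random_oversample(rows, labels, spec, seed)
  )
}

.resample_labels <- function(rows, labels) {
  if (inherits(rows, "screen_dtm")) as_label(rows$labels) else as_label(labels)
}

.resample_result <- function(rows, labels, idx) {
  out_rows <- if (inherits(rows, "screen_dtm")) {
    dtm_rows(rows, idx)
  } else {
    rows[idx, , drop = FALSE]
  }
  list(rows = out_rows, labels = labels[idx], idx = idx)
}
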