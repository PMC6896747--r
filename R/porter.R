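# Classic Porter (1980) suffix-stripping stemmer.
#
# Implemented from the original algorithm definition: a word is [C](VC)^m[V];
# each step strips or rewrites the longest matching suffix subject to a
# condition on the measure m of the remaining stem. Words of one or two
# letters are returned unchanged, as in the reference implementation.
# Within steps 2-4 the first matching suffix gates the rewrite: if its
# condition fails no shorter suffix is tried (reference behaviour).

# TRUE if position i of letter vector `w` holds a consonant.
.pt_cons <- function(w, i) {
  ch <- w[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_cons(w, i - 1L))
  }
  TRUE
}

.pt_flags <- function(w) vapply(seq_along(w), function(i) .pt_cons(w, i), logical(1))

# Measure m: number of vowel->consonant transitions in [C](VC)^m[V].
.pt_measure <- function(w) {
  if (length(w) == 0L) return(0L)
  f <- .pt_flags(w)
  m <- 0L
  prev_vowel <- FALSE
  for (cons in f) {
    if (cons && prev_vowel) m <- m + 1L
    prev_vowel <- !cons
  }
  m
}

.pt_has_vowel <- function(w) length(w) > 0L && any(!.pt_flags(w))

.pt_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && .pt_cons(w, n)
}

# consonant-vowel-consonant ending where the final consonant is not w, x or y
.pt_cvc <- function(w) {
  n <- length(w)
  if (n < 3L) return(FALSE)
  .pt_cons(w, n) && !.pt_cons(w, n - 1L) && .pt_cons(w, n - 2L) &&
    !(w[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(w, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1]]
  n <- length(w)
  k <- length(s)
  n >= k && identical(w[(n - k + 1L):n], s)
}

.pt_chop <- function(w, k) if (k >= length(w)) character(0) else w[seq_len(length(w) - k)]

.step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"),
  c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"),
  c("abli", "able"), c("alli", "al"), c("entli", "ent"), c("eli", "e"),
  c("ousli", "ous"),
  c("ization", "ize"), c("ation", "ate"), c("ator", "ate"),
  c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"),
  c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

.step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"),
  c("iciti", "ic"), c("ical", "ic"), c("ful", ""), c("ness", "")
)

.step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant",
  "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
  "ous", "ive", "ize"
)

.porter_word <- function(word) {
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  if (length(w) <= 2L) return(word)

  # Step 1a: plurals
  n <- length(w)
  if (w[n] == "s") {
    if (.pt_ends(w, "sses")) w <- .pt_chop(w, 2L)
    else if (.pt_ends(w, "ies")) w <- c(.pt_chop(w, 3L), "i")
    else if (!.pt_ends(w, "ss") && n > 1L) w <- .pt_chop(w, 1L)
  }

  # Step 1b: -eed / -ed / -ing
  cleanup <- FALSE
  if (.pt_ends(w, "eed")) {
    if (.pt_measure(.pt_chop(w, 3L)) > 0L) w <- .pt_chop(w, 1L)
  } else if (.pt_ends(w, "ed") && .pt_has_vowel(.pt_chop(w, 2L))) {
    w <- .pt_chop(w, 2L); cleanup <- TRUE
  } else if (.pt_ends(w, "ing") && .pt_has_vowel(.pt_chop(w, 3L))) {
    w <- .pt_chop(w, 3L); cleanup <- TRUE
  }
  if (cleanup) {
    n <- length(w)
    if (n >= 2L && paste(w[(n - 1L):n], collapse = "") %in% c("at", "bl", "iz")) {
      w <- c(w, "e")
    } else if (.pt_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- .pt_chop(w, 1L)
    } else if (.pt_measure(w) == 1L && .pt_cvc(w)) {
      w <- c(w, "e")
    }
  }

  # Step 1c: y -> i after a vowel-containing stem
  if (length(w) > 1L && w[length(w)] == "y" && .pt_has_vowel(.pt_chop(w, 1L))) {
    w[length(w)] <- "i"
  }

  # Step 2: double-suffix reductions (m > 0)
  for (rule in .step2_rules) {
    if (.pt_ends(w, rule[1])) {
      stem <- .pt_chop(w, nchar(rule[1]))
      if (.pt_measure(stem) > 0L) {
        w <- c(stem, strsplit(rule[2], "", fixed = TRUE)[[1]])
      }
      break
    }
  }

  # Step 3: -ic-, -full, -ness etc. (m > 0)
  for (rule in .step3_rules) {
    if (.pt_ends(w, rule[1])) {
      stem <- .pt_chop(w, nchar(rule[1]))
      if (.pt_measure(stem) > 0L) {
        w <- c(stem, strsplit(rule[2], "", fixed = TRUE)[[1]])
      }
      break
    }
  }

  # Step 4: strip remaining suffix when m > 1
  for (sfx in .step4_suffixes) {
    if (.pt_ends(w, sfx)) {
      stem <- .pt_chop(w, nchar(sfx))
      ok <- .pt_measure(stem) > 1L
      if (ok && sfx == "ion") {
        ok <- length(stem) > 0L && stem[length(stem)] %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # Step 5a: final -e
  if (length(w) > 1L && w[length(w)] == "e") {
    stem <- .pt_chop(w, 1L)
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) w <- stem
  }

  # Step 5b: -ll -> -l when m > 1
  if (.pt_measure(w) > 1L && .pt_double_cons(w) && w[length(w)] == "l") {
    w <- .pt_chop(w, 1L)
  }

  paste(w, collapse = "")
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter (1980)
#' suffix-stripping algorithm, the de-facto reference stemmer in text-mining
#' pipelines. Input is assumed to be lowercase alphabetic tokens (as produced
#' by [preprocess_text()]); words of one or two letters are returned
#' unchanged.
#'
#' @param words character vector of lowercase alphabetic words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("randomized", "controlled", "trials"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  uw <- unique(words)
  stems <- vapply(uw, .porter_word, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}
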