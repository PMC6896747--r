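# Internal helpers: deterministic seed derivation and scoped RNG use.

# Polynomial string hash modulo the Mersenne prime 2^31 - 1. All arithmetic
# stays below 2^52 so it is exact in doubles and identical across platforms.
.hash_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

# Derive a reproducible child seed from a parent seed and a label path.
# Used so that every cell of the evaluation grid (review x learner x
# balancing), every fold and every draw gets an independent, stable stream.
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(x) paste(format(x), collapse = "|"),
                  character(1))
  .hash_string(paste(c(format(seed), parts), collapse = "\r"))
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

.label_levels <- c("negative", "positive")

# Coerce a label vector to the canonical factor, validating values.
as_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), .label_levels)
  if (length(bad) > 0) {
    stop("invalid label value(s): ", paste(bad, collapse = ", "),
         " (expected \"positive\"/\"negative\")", call. = FALSE)
  }
  factor(x, levels = .label_levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
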