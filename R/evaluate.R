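# Cross-validated evaluation of (learner x balancing) strategies with
# per-fold TF-IDF fitting, training-only resampling and random
# hyperparameter search.

#' Area under the ROC curve (Mann-Whitney estimate)
#'
#' Computes AUC-ROC as the probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, with ties counted one
#' half — the Mann-Whitney / Wilcoxon form, computed from ranks.
#'
#' @param scores numeric vector of continuous classifier scores (higher =
#'   more positive).
#' @param labels binary `"positive"`/`"negative"` vector aligned to scores.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_roc(c(0.9, 0.8, 0.4, 0.3),
#'         c("positive", "negative", "positive", "negative"))
#' @export
auc_roc <- function(scores, labels) {
  labels <- as_label(labels)
  pos <- labels == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified fold assignment
#'
#' Assigns every row to one of `k_folds` folds, stratified by class: within
#' each class the fold sizes differ by at most one. Stratification
#' guarantees each held-out fold contains both classes even with very few
#' positives, keeping fold AUCs defined.
#'
#' @param labels binary label vector.
#' @param k_folds number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold numbers in `1:k_folds`.
#' @export
make_folds <- function(labels, k_folds = 5, seed = 1L) {
  labels <- as_label(labels)
  counts <- table(labels)
  if (any(counts < k_folds)) {
    stop("each class needs at least k_folds = ", k_folds,
         " members (got ", paste(counts, collapse = "/"), ")", call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(sample.int(k_folds), length(idx))
    }
  })
  folds
}

#' Default balancing strategies of the evaluation grid
#'
#' The five imbalance treatments compared by the pipeline: no balancing,
#' random undersampling and oversampling each at 50:50 and 35:65
#' minority:majority ratios. Together with the four learners these define
#' the 20 modelling strategies.
#'
#' @return named list of [balancing_spec] objects.
#' @export
default_balancing_specs <- function() {
  specs <- list(
    balancing_spec("none"),
    balancing_spec("rus", 0.50),
    balancing_spec("rus", 0.35),
    balancing_spec("ros", 0.50),
    balancing_spec("ros", 0.35)
  )
  names(specs) <- vapply(specs, balancing_label, character(1))
  specs
}

# Per-fold leakage-safe preparation: TF-IDF fitted on the training rows of
# each fold only, held-out rows aligned to the fitted vocabulary. Shared by
# all cells that use the same fold assignment.
.prepare_folds <- function(dtm, folds, retain_fraction) {
  lapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f)
    te <- which(folds == f)
    model <- fit_tfidf(dtm_rows(dtm, tr), retain_fraction)
    list(
      train = apply_tfidf(model, dtm_rows(dtm, tr)),
      test = apply_tfidf(model, dtm_rows(dtm, te)),
      test_idx = te
    )
  })
}

# Core CV loop over prepared folds for one (learner, balancing) cell.
# `draws` can be injected (tests); by default they are sampled from the
# documented ranges under a seed derived from `seed`.
.cv_core <- function(fold_data, learner, balancing, n_draws, seed,
                     num_trees = 500L, draws = NULL) {
  k <- length(fold_data)
  balanced <- lapply(seq_len(k), function(f) {
    rebalance(fold_data[[f]]$train, spec = balancing,
              seed = derive_seed(seed, "balance", f))
  })
  feature_count <- min(vapply(balanced, function(b) ncol(b$rows$weights),
                              numeric(1)))
  train_size <- min(vapply(balanced, function(b) length(b$labels),
                           numeric(1)))
  if (is.null(draws)) {
    draws <- sample_hyperparameters(learner, n_draws, feature_count,
                                    train_size, derive_seed(seed, "draws"))
  }
  n_draws <- length(draws)
  # densify once per fold for learners that need dense input, instead of
  # once per draw (glmnet works on the sparse matrix directly)
  dense <- learner != "glmnet"
  x_tr <- lapply(balanced, function(b)
    if (dense) as.matrix(b$rows$weights) else b$rows$weights)
  x_te <- lapply(fold_data, function(f)
    if (dense) as.matrix(f$test$weights) else f$test$weights)
  failures <- character(0)
  warned <- character(0)
  aucs <- matrix(NA_real_, nrow = n_draws, ncol = k)
  for (d in seq_len(n_draws)) {
    for (f in seq_len(k)) {
      res <- tryCatch(
        withCallingHandlers(
          {
            scores <- fit_score(
              draws[[d]], x_tr[[f]], balanced[[f]]$labels, x_te[[f]],
              seed = derive_seed(seed, "fit", d, f), num_trees = num_trees)
            auc_roc(scores, fold_data[[f]]$test$labels)
          },
          # learner warnings (e.g. glmnet on very few positives) are cell
          # diagnostics, not conditions the caller can act on
          warning = function(w) {
            warned <<- c(warned, conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        ),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures,
                      sprintf("draw %d fold %d: %s", d, f, conditionMessage(res)))
      } else {
        aucs[d, f] <- res
      }
    }
  }
  draw_means <- rowMeans(aucs)  # NA if any fold of the draw failed
  if (all(is.na(draw_means))) {
    return(structure(
      list(fold_aucs = rep(NA_real_, k), mean_auc = NA_real_,
           sd_auc = NA_real_, n_folds = k, chosen_draw = NULL,
           draw_mean_aucs = draw_means, status = "failed",
           failures = failures, warnings = unique(warned),
           learner = learner, balancing = balancing),
      class = "cv_result"
    ))
  }
  chosen <- which.max(draw_means)  # first maximum wins ties
  structure(
    list(
      fold_aucs = aucs[chosen, ], mean_auc = mean(aucs[chosen, ]),
      sd_auc = sd(aucs[chosen, ]), n_folds = k,
      chosen_draw = draws[[chosen]], draw_mean_aucs = draw_means,
      status = "ok", failures = failures, warnings = unique(warned),
      learner = learner, balancing = balancing
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$learner, "/", balancing_label(x$balancing),
      "-", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  mean AUC %.4f (sd %.4f) over %d folds\n",
                x$mean_auc, x$sd_auc, x$n_folds))
    cat("  fold AUCs:", paste(sprintf("%.4f", x$fold_aucs), collapse = " "),
        "\n")
  } else {
    cat("  all hyperparameter draws failed; first cause:\n   ",
        x$failures[1], "\n")
  }
  invisible(x)
}

#' Cross-validate one modelling strategy on one review
#'
#' Runs stratified k-fold cross-validation of a (learner, balancing)
#' strategy on a review corpus. Within each fold the TF-IDF weighting and
#' top-fraction token selection are fitted on the training rows only, the
#' held-out rows are aligned to the fitted feature space, and the balancing
#' method is applied to the (already weighted) training rows only — the
#' held-out fold is never resampled or used for fitting weights. Each of
#' `n_draws` random hyperparameter settings is trained on every fold; the
#' draw with the best mean fold AUC is selected (first draw wins ties) and
#' its fold AUCs are returned.
#'
#' A learner that errors on a fold invalidates that draw; if every draw
#' fails the result carries `status = "failed"` with the captured causes,
#' and is excluded from downstream meta-analysis rather than imputed.
#'
#' @param corpus a [screen_corpus].
#' @param learner one of [screen_learners()].
#' @param balancing a [balancing_spec] (default none).
#' @param k_folds folds (default 5).
#' @param n_draws random hyperparameter draws (default 10).
#' @param retain_fraction TF-IDF token-retention fraction (default 0.04).
#' @param seed integer seed; folds, resamples, draws and stochastic learners
#'   all derive from it.
#' @param folds optional precomputed fold assignment (from [make_folds()]);
#'   lets several strategies share identical held-out folds.
#' @param dtm optional precomputed TF [build_dtm()] result for `corpus`.
#' @param num_trees trees for the random-forest learner (default 500).
#' @return an object of class `cv_result`: fold AUCs of the chosen draw,
#'   their mean and standard deviation, the chosen hyperparameters, the
#'   per-draw mean AUCs, a status flag and any captured failures.
#' @export
cross_validate_strategy <- function(corpus, learner,
                                    balancing = balancing_spec("none"),
                                    k_folds = 5, n_draws = 10,
                                    retain_fraction = 0.04, seed = 1L,
                                    folds = NULL, dtm = NULL,
                                    num_trees = 500L) {
  learner <- match.arg(learner, .learners)
  if (is.null(dtm)) dtm <- build_dtm(corpus)
  if (is.null(folds)) {
    folds <- make_folds(dtm$labels, k_folds, derive_seed(seed, "folds"))
  }
  fold_data <- .prepare_folds(dtm, folds, retain_fraction)
  out <- .cv_core(fold_data, learner, balancing, n_draws, seed, num_trees)
  out$folds <- folds
  out
}

#' Run the full strategy grid over several reviews
#'
#' Evaluates every (review x learner x balancing) cell: by default 4
#' learners and 5 balancing treatments, i.e. the 20 modelling strategies,
#' on each review corpus. Within a review all cells share the same fold
#' assignment (derived from `master_seed` and the review id), so held-out
#' folds are bit-identical across balancing methods and delta-AUCs compare
#' like with like. Each cell gets its own deterministic seed derived from
#' `(master_seed, review, learner, balancing)`, making any single cell
#' reproducible in isolation. Failed cells are recorded, never dropped.
#'
#' @param corpora list of [screen_corpus] objects (one per review).
#' @param learners character vector of learners (default all four).
#' @param balancing_specs named list of [balancing_spec] (default the five
#'   standard treatments).
#' @inheritParams cross_validate_strategy
#' @param master_seed integer master seed for the whole grid.
#' @param verbose print progress lines.
#' @return an object of class `strategy_grid`: list of per-cell results
#'   (each with `review_id`, `learner`, `balancing`, `cv`), plus the grid
#'   configuration. See [as.data.frame.strategy_grid()],
#'   [compute_deltas()], [forest_grid()].
#' @export
run_grid <- function(corpora, learners = screen_learners(),
                     balancing_specs = default_balancing_specs(),
                     k_folds = 5, n_draws = 10, retain_fraction = 0.04,
                     master_seed = 1L, num_trees = 500L, verbose = FALSE) {
  if (length(corpora) < 1) stop("need at least one corpus", call. = FALSE)
  if (inherits(corpora, "screen_corpus")) corpora <- list(corpora)
  results <- list()
  for (corpus in corpora) {
    review <- attr(corpus, "review_id")
    dtm <- build_dtm(corpus)
    folds <- make_folds(dtm$labels, k_folds,
                        derive_seed(master_seed, "folds", review))
    fold_data <- .prepare_folds(dtm, folds, retain_fraction)
    for (learner in learners) {
      for (spec in balancing_specs) {
        cell_seed <- derive_seed(master_seed, review, learner,
                                 balancing_label(spec))
        cv <- .cv_core(fold_data, learner, spec, n_draws, cell_seed,
                       num_trees)
        cv$folds <- folds
        if (verbose) {
          cat(sprintf("%s | %-6s | %-9s : %s%s\n", review, learner,
                      balancing_label(spec), cv$status,
                      if (cv$status == "ok")
                        sprintf(" (mean AUC %.4f)", cv$mean_auc) else ""))
        }
        results[[length(results) + 1L]] <- list(
          review_id = review, learner = learner, balancing = spec, cv = cv)
      }
    }
  }
  structure(
    list(results = results,
         reviews = vapply(corpora, attr, character(1), "review_id"),
         learners = learners,
         balancing = vapply(balancing_specs, balancing_label, character(1)),
         k_folds = k_folds, n_draws = n_draws,
         retain_fraction = retain_fraction, master_seed = master_seed),
    class = "strategy_grid"
  )
}

#' @export
print.strategy_grid <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<strategy_grid>", length(x$results), "cells:",
      length(x$reviews), "reviews x", length(x$learners), "learners x",
      length(x$balancing), "balancing specs\n")
  cat("  failed cells:", sum(df$status == "failed"), "\n")
  invisible(x)
}

#' Tabulate grid results
#'
#' One row per (review, learner, balancing) cell with the cross-validated
#' AUC summary — the machine-readable analogue of a per-review results
#' table.
#'
#' @param x a `strategy_grid` from [run_grid()].
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data frame with columns `review_id`, `learner`, `method`,
#'   `minority_share`, `fold_aucs` (semicolon-joined), `mean_auc`,
#'   `sd_auc`, `status`.
#' @export
as.data.frame.strategy_grid <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rows <- lapply(x$results, function(r) {
    data.frame(
      review_id = r$review_id,
      learner = r$learner,
      method = balancing_label(r$balancing),
      minority_share = r$balancing$minority_share,
      fold_aucs = paste(sprintf("%.6f", r$cv$fold_aucs), collapse = ";"),
      mean_auc = r$cv$mean_auc,
      sd_auc = r$cv$sd_auc,
      status = r$cv$status,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
summary.strategy_grid <- function(object, ...) {
  df <- as.data.frame(object)
  ok <- df[df$status == "ok", ]
  tab <- tapply(ok$mean_auc, list(ok$learner, ok$method), mean)
  cat("Mean cross-validated AUC by learner and balancing method\n")
  cat("(averaged over", length(object$reviews), "reviews; failed cells",
      "excluded)\n\n")
  print(round(tab, 4))
  invisible(tab)
}

#' Write grid results as a delimited table
#' @param grid a `strategy_grid`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_strategy_results <- function(grid, path) {
  write.csv(as.data.frame(grid), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
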