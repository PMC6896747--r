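test_that("auc_roc matches hand-computed and degenerate cases", {
  expect_equal(
    auc_roc(c(0.9, 0.8, 0.4, 0.3),
            c("positive", "negative", "positive", "negative")),
    0.75)
  expect_equal(auc_roc(c(5, 4, 3, 1, 2),
                       c("positive", "positive", rep("negative", 3))), 1)
  expect_equal(auc_roc(rep(1, 6), rep(c("positive", "negative"), 3)), 0.5)
  # reversed scores give the complement
  expect_equal(auc_roc(c(0.1, 0.2, 0.9, 0.8),
                       c("positive", "positive", "negative", "negative")), 0)
  expect_error(auc_roc(1:3, rep("positive", 3)), "both classes")
  expect_error(auc_roc(1:3, c("positive", "negative")), "equal length")
})

test_that("auc_roc equals the all-pairs brute-force oracle with ties", {
  for (i in 1:300) {
    set.seed(i)
    n <- sample(4:20, 1)
    labels <- c("positive", "negative",
                sample(c("positive", "negative"), n - 2, replace = TRUE))
    # discrete scores force frequent ties
    scores <- sample(1:5, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
    expect_equal(auc_roc(scores, labels), auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auc_roc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- rnorm(60)
  labels <- rep(c("positive", "negative"), c(15, 45))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_roc(scores, labels), ref, tolerance = 1e-12)
})

test_that("make_folds stratifies both classes to within one member", {
  labels <- rep(c("positive", "negative"), c(10, 190))
  f <- make_folds(labels, 5, seed = 2)
  expect_equal(unname(table(f[labels == "positive"])), rep(2L, 5),
               ignore_attr = TRUE)
  expect_equal(unname(table(f[labels == "negative"])), rep(38L, 5),
               ignore_attr = TRUE)

  labels <- rep(c("positive", "negative"), c(7, 23))
  f <- make_folds(labels, 5, seed = 2)
  expect_equal(sort(as.vector(table(f[labels == "positive"]))),
               c(1L, 1L, 1L, 2L, 2L))

  expect_identical(make_folds(labels, 5, seed = 3),
                   make_folds(labels, 5, seed = 3))
  expect_false(identical(make_folds(labels, 5, seed = 3),
                         make_folds(labels, 5, seed = 4)))
  expect_error(make_folds(rep(c("positive", "negative"), c(3, 50)), 5),
               "at least k_folds")
})

test_that("cross-validation reaches AUC 1 on a fully separated corpus", {
  corp <- separable_corpus(n_pos = 10, n_neg = 45, seed = 21)
  dtm <- build_dtm(corp)
  for (learner in c("svm", "rf", "glmnet")) {
    cv <- cross_validate_strategy(corp, learner, balancing_spec("none"),
                                  n_draws = 3, seed = 31, dtm = dtm,
                                  num_trees = 100)
    expect_equal(cv$status, "ok")
    expect_equal(cv$mean_auc, 1, info = learner)
    expect_equal(cv$n_folds, 5)
    expect_length(cv$fold_aucs, 5)
  }
})

test_that("permuted labels yield chance-level AUC on a large null corpus", {
  spec <- synthetic_spec("null", n_pos = 30, n_neg = 270, separation = 0,
                         seed = 77)
  corp <- generate_corpus(spec)
  cv <- cross_validate_strategy(corp, "glmnet", balancing_spec("none"),
                                n_draws = 3, seed = 13)
  expect_equal(cv$status, "ok")
  expect_gte(cv$mean_auc, 0.35)
  expect_lte(cv$mean_auc, 0.65)
})

test_that("held-out folds are identical across balancing methods", {
  corp <- separable_corpus(n_pos = 10, n_neg = 45, seed = 9)
  dtm <- build_dtm(corp)
  folds <- make_folds(dtm$labels, 5, seed = 41)
  cvs <- lapply(list(balancing_spec("none"), balancing_spec("rus", 0.5),
                     balancing_spec("ros", 0.35)),
                function(sp) cross_validate_strategy(
                  corp, "glmnet", sp, n_draws = 2, seed = 55,
                  folds = folds, dtm = dtm))
  expect_identical(cvs[[1]]$folds, cvs[[2]]$folds)
  expect_identical(cvs[[1]]$folds, cvs[[3]]$folds)
})

test_that("chosen draw maximises mean fold AUC with first-draw tie-break", {
  corp <- separable_corpus(n_pos = 10, n_neg = 40, seed = 14)
  cv <- cross_validate_strategy(corp, "glmnet", n_draws = 4, seed = 19)
  expect_equal(cv$status, "ok")
  best <- max(cv$draw_mean_aucs, na.rm = TRUE)
  expect_equal(cv$mean_auc, best)
  # ties (several draws at the max) must resolve to the earliest draw
  first_at_max <- which(cv$draw_mean_aucs == best)[1]
  expect_equal(which.max(cv$draw_mean_aucs), first_at_max)
})

test_that("learner failures are captured as failed cells, not errors", {
  corp <- separable_corpus(n_pos = 6, n_neg = 20, seed = 3)
  dtm <- build_dtm(corp)
  fd <- citescreen:::.prepare_folds(dtm, make_folds(dtm$labels, 5, 1), 0.5)

  # a k-NN neighbourhood larger than every training fold errors on every
  # draw: the cell must come back failed with the causes captured
  cv <- citescreen:::.cv_core(
    fd, "knn", balancing_spec("none"), n_draws = 1, seed = 1,
    draws = list(list(learner = "knn", k = 10000)))
  expect_s3_class(cv, "cv_result")
  expect_equal(cv$status, "failed")
  expect_true(is.na(cv$mean_auc))
  expect_length(cv$failures, 5)  # one per fold
  expect_match(cv$failures[1], "not smaller than")

  # a partial failure (one bad draw among good ones) still yields an ok
  # cell scored on the surviving draws
  cv <- citescreen:::.cv_core(
    fd, "knn", balancing_spec("none"), n_draws = 2, seed = 1,
    draws = list(list(learner = "knn", k = 10000),
                 list(learner = "knn", k = 3)))
  expect_equal(cv$status, "ok")
  expect_true(is.na(cv$draw_mean_aucs[1]))
  expect_false(is.na(cv$mean_auc))
})

test_that("run_grid enumerates review x learner x balancing cells", {
  corpora <- lapply(c(4, 6), function(s)
    separable_corpus(n_pos = 8, n_neg = 32, seed = s))
  attr(corpora[[1]], "review_id") <- "r1"
  attr(corpora[[2]], "review_id") <- "r2"
  corpora[[1]]$review_id <- "r1"
  corpora[[2]]$review_id <- "r2"
  grid <- run_grid(corpora, learners = c("glmnet", "svm"),
                   n_draws = 2, master_seed = 5, num_trees = 50)
  df <- as.data.frame(grid)
  expect_equal(nrow(df), 2 * 2 * 5)
  expect_equal(sort(unique(df$method)),
               sort(c("none", "RUS-50:50", "RUS-35:65",
                      "ROS-50:50", "ROS-35:65")))
  # one result per cell, none dropped
  expect_equal(anyDuplicated(df[, c("review_id", "learner", "method")]), 0)
  # grid-level fold sharing: same review, same folds in every cell
  folds_r1 <- lapply(Filter(function(r) r$review_id == "r1", grid$results),
                     function(r) r$cv$folds)
  expect_true(all(vapply(folds_r1, identical, logical(1), folds_r1[[1]])))
})

test_that("strategy results table writes and re-reads", {
  corp <- separable_corpus(n_pos = 8, n_neg = 32, seed = 4)
  grid <- run_grid(list(corp), learners = "glmnet", n_draws = 2,
                   master_seed = 3, num_trees = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_strategy_results(grid, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 5)
  expect_true(all(c("review_id", "learner", "method", "mean_auc",
                    "sd_auc", "status") %in% names(back)))
})
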