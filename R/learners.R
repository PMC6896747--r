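# Pluggable classifier interface. The four families (SVM, k-NN, RF,
# elastic-net GLM) delegate their solvers to established implementations
# (e1071, class, ranger, glmnet); each must return a continuous
# positive-class score for held-out rows.

.learners <- c("svm", "knn", "rf", "glmnet")

#' Supported classifier families
#' @return character vector: `"svm"`, `"knn"`, `"rf"`, `"glmnet"`.
#' @export
screen_learners <- function() .learners

#' Draw random hyperparameter settings for a learner
#'
#' Random search over the documented ranges, one draw per setting:
#' * `svm`: cost `C` log-uniform on \[1e-2, 1e2\] (linear kernel);
#' * `knn`: neighbourhood size `k` uniform integer on
#'   \[1, min(30, train_size - 1)\];
#' * `rf`: `mtry` uniform integer on
#'   \[1, max(2, round(2 * sqrt(feature_count)))\], capped at
#'   `feature_count`;
#' * `glmnet`: `lambda` log-uniform on \[1e-4, 1\] and `alpha` uniform on
#'   \[0, 1\].
#'
#' @param learner one of [screen_learners()].
#' @param n_draws number of random draws (default 10).
#' @param feature_count number of features available to the learner.
#' @param train_size number of training rows (after any resampling).
#' @param seed integer seed; same seed reproduces the same draws.
#' @return a list of `n_draws` named parameter lists, each with a `learner`
#'   element.
#' @export
sample_hyperparameters <- function(learner, n_draws = 10, feature_count,
                                   train_size, seed = 1L) {
  learner <- match.arg(learner, .learners)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (learner == "knn" && train_size < 2) {
    stop("k-NN requires at least 2 training rows", call. = FALSE)
  }
  if (feature_count < 1) stop("feature_count must be >= 1", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      switch(learner,
        svm = list(learner = "svm", C = 10^runif(1, -2, 2)),
        knn = list(learner = "knn",
                   k = sample.int(min(30L, train_size - 1L), 1)),
        rf = list(learner = "rf",
                  mtry = sample.int(
                    min(feature_count,
                        max(2L, as.integer(round(2 * sqrt(feature_count))))),
                    1)),
        glmnet = list(learner = "glmnet",
                      lambda = 10^runif(1, -4, 0),
                      alpha = runif(1))
      )
    })
  })
}

# Train one learner on (x_train, y_train) and return continuous
# positive-class scores for x_test. x_* are sparse dgCMatrix; learners that
# need dense input convert internally. Deterministic given `seed`.
fit_score <- function(params, x_train, y_train, x_test, seed = 1L,
                      num_trees = 500L) {
  y_train <- as_label(y_train)
  switch(params$learner,
    svm = .fit_svm(params, x_train, y_train, x_test),
    knn = .fit_knn(params, x_train, y_train, x_test, seed),
    rf = .fit_rf(params, x_train, y_train, x_test, seed, num_trees),
    glmnet = .fit_glmnet(params, x_train, y_train, x_test),
    stop("unknown learner: ", params$learner, call. = FALSE)
  )
}

.fit_svm <- function(params, x_train, y_train, x_test) {
  fit <- e1071::svm(x = as.matrix(x_train), y = y_train,
                    kernel = "linear", cost = params$C,
                    scale = FALSE, probability = FALSE)
  pred <- stats::predict(fit, as.matrix(x_test), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # decision values are oriented towards the class named first in the
  # "A/B" column label; flip if that class is "negative"
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (identical(first, "positive")) dv[, 1] else -dv[, 1]
}

.fit_knn <- function(params, x_train, y_train, x_test, seed) {
  k <- params$k
  if (k >= nrow(x_train)) {
    stop("k-NN neighbourhood (k = ", k, ") not smaller than training set (",
         nrow(x_train), ")", call. = FALSE)
  }
  pred <- with_seed(seed,
    class::knn(train = as.matrix(x_train), test = as.matrix(x_test),
               cl = y_train, k = k, prob = TRUE))
  p_win <- attr(pred, "prob")
  ifelse(pred == "positive", p_win, 1 - p_win)
}

.fit_rf <- function(params, x_train, y_train, x_test, seed, num_trees) {
  fit <- ranger::ranger(
    x = as.matrix(x_train), y = y_train,
    num.trees = num_trees,
    mtry = min(params$mtry, ncol(x_train)),
    probability = TRUE,
    seed = as.integer(seed %% 2147483647),
    num.threads = 1
  )
  stats::predict(fit, as.matrix(x_test),
                 num.threads = 1)$predictions[, "positive"]
}

.fit_glmnet <- function(params, x_train, y_train, x_test) {
  # fit the full regularisation path (glmnet's warm starts need it to
  # converge reliably), then read off the solution at the drawn lambda;
  # lambdas below the path floor take the least-regularised endpoint
  fit <- glmnet::glmnet(x = x_train, y = y_train, family = "binomial",
                        alpha = params$alpha, nlambda = 50)
  as.numeric(stats::predict(fit, newx = x_test, type = "response",
                            s = params$lambda))
}
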