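mk_cv <- function(mean, sd, k = 5, status = "ok") {
  structure(list(fold_aucs = rep(mean, k), mean_auc = mean, sd_auc = sd,
                 n_folds = k, status = status),
            class = "cv_result")
}

test_that("delta_auc computes the closed-form difference and interval", {
  # identical results: delta 0, interval centred at 0
  d <- delta_auc(mk_cv(0.9, 0.02), mk_cv(0.9, 0.02))
  expect_equal(d$delta, 0)
  expect_equal(d$ci_low, -d$ci_high)

  # hand-computed case: var = (0.0004 + 0.0004)/5 = 1.6e-4
  d <- delta_auc(mk_cv(0.95, 0.02), mk_cv(0.90, 0.02))
  expect_equal(d$delta, 0.05)
  expect_equal(d$variance, 1.6e-4)
  expect_equal(d$ci_low, 0.05 - 1.96 * sqrt(1.6e-4))
  expect_equal(d$ci_high, 0.05 + 1.96 * sqrt(1.6e-4))

  # zero CV dispersion hits the variance floor
  d <- delta_auc(mk_cv(1, 0), mk_cv(1, 0), var_floor = 1e-6)
  expect_equal(d$variance, 1e-6)
  expect_equal(d$ci_high - d$ci_low, 2 * 1.96 * 1e-3)

  expect_error(delta_auc(mk_cv(1, 0, status = "failed"), mk_cv(1, 0)),
               "successful")
  expect_error(delta_auc(mk_cv(1, 0, k = 5), mk_cv(1, 0, k = 10)),
               "fold counts")
})

test_that("fixed-effect pooling matches closed forms and is order-invariant", {
  # single study: pooled equals the study
  p <- pool_fixed_effect(0.1, 0.01)
  expect_equal(p$pooled_delta, 0.1)
  expect_equal(p$pooled_se, 0.1)

  # two studies, equal variances: midpoint, se = sqrt(v/2)
  p <- pool_fixed_effect(c(0.1, 0.3), c(0.01, 0.01))
  expect_equal(p$pooled_delta, 0.2)
  expect_equal(p$pooled_se, sqrt(0.005))

  # equal variances reduce to the unweighted mean
  set.seed(1)
  d <- runif(8, -0.2, 0.2)
  expect_equal(pool_fixed_effect(d, rep(0.02, 8))$pooled_delta, mean(d))

  # order invariance
  v <- c(0.01, 0.04, 0.02)
  e <- c(0.05, -0.1, 0.2)
  p1 <- pool_fixed_effect(e, v)
  p2 <- pool_fixed_effect(rev(e), rev(v))
  expect_equal(p1$pooled_delta, p2$pooled_delta)
  expect_equal(p1$pooled_se, p2$pooled_se)

  expect_error(pool_fixed_effect(numeric(0), numeric(0)), "at least one")
  expect_error(pool_fixed_effect(c(0.1, 0.2), c(0.01, 0)), "positive")
  # weights normalise to one and pooled stays inside the effect range
  expect_equal(sum(p1$weights), 1)
  expect_gte(p1$pooled_delta, min(e))
  expect_lte(p1$pooled_delta, max(e))
})

test_that("pooling matches the brute-force and metafor oracles", {
  for (i in 1:30) {
    set.seed(i)
    k <- sample(2:14, 1)
    d <- runif(k, -0.4, 0.4)
    v <- runif(k, 1e-4, 0.05)
    p <- pool_fixed_effect(d, v)
    o <- pool_bruteforce(d, v)
    expect_lt(abs(p$pooled_delta - o$est), 1e-10)
    expect_lt(abs(p$pooled_se - o$se), 1e-10)
    expect_lt(abs(p$ci_low - o$lo), 1e-10)
  }
  skip_if_not_installed("metafor")
  set.seed(99)
  d <- runif(10, -0.3, 0.3)
  v <- runif(10, 1e-4, 0.04)
  fit <- metafor::rma(yi = d, vi = v, method = "FE")
  p <- pool_fixed_effect(d, v)
  expect_equal(p$pooled_delta, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(p$pooled_se, as.numeric(fit$se), tolerance = 1e-10)
})

test_that("scaling all variances rescales the interval, not the estimate", {
  set.seed(5)
  d <- runif(6, -0.2, 0.2)
  v <- runif(6, 0.001, 0.02)
  a <- pool_fixed_effect(d, v)
  b <- pool_fixed_effect(d, v / 4)
  expect_equal(a$pooled_delta, b$pooled_delta)
  expect_equal((a$ci_high - a$ci_low) / (b$ci_high - b$ci_low), 2,
               tolerance = 1e-12)
})

test_that("compute_deltas excludes failed cells and keys on review+learner", {
  grid <- list(results = list(
    list(review_id = "r1", learner = "svm", balancing = balancing_spec("none"),
         cv = mk_cv(0.90, 0.02)),
    list(review_id = "r1", learner = "svm",
         balancing = balancing_spec("rus", 0.5), cv = mk_cv(0.95, 0.02)),
    list(review_id = "r1", learner = "svm",
         balancing = balancing_spec("ros", 0.5),
         cv = mk_cv(NA, NA, status = "failed")),
    list(review_id = "r2", learner = "svm", balancing = balancing_spec("none"),
         cv = mk_cv(NA, NA, status = "failed")),
    list(review_id = "r2", learner = "svm",
         balancing = balancing_spec("rus", 0.5), cv = mk_cv(0.99, 0.01))))
  class(grid) <- "strategy_grid"
  deltas <- compute_deltas(grid)
  # r1 RUS survives; r1 ROS failed; r2 baseline failed so r2 RUS excluded
  expect_equal(nrow(deltas), 1)
  expect_equal(deltas$review_id, "r1")
  expect_equal(deltas$delta, 0.05)
})

test_that("forest_grid builds one panel per learner x balanced method", {
  set.seed(8)
  reviews <- sprintf("r%d", 1:3)
  rows <- expand.grid(review_id = reviews,
                      learner = c("svm", "rf", "knn", "glmnet"),
                      method = c("ROS-50:50", "ROS-35:65",
                                 "RUS-50:50", "RUS-35:65"),
                      stringsAsFactors = FALSE)
  rows$delta <- runif(nrow(rows), -0.1, 0.1)
  rows$variance <- runif(nrow(rows), 1e-4, 1e-2)
  rows$ci_low <- rows$delta - 1.96 * sqrt(rows$variance)
  rows$ci_high <- rows$delta + 1.96 * sqrt(rows$variance)
  fg <- forest_grid(rows)
  expect_equal(length(fg$panels), 16)
  expect_equal(length(fg$learners), 4)
  expect_equal(length(fg$methods), 4)
  one <- fg$panels[["svm / ROS-50:50"]]
  expect_equal(nrow(one$deltas), 3)
  expect_s3_class(one$pooled, "pooled_estimate")

  # single learner: one panel per method
  fg1 <- forest_grid(rows[rows$learner == "svm", ])
  expect_equal(length(fg1$panels), 4)

  # a review missing from one stratum is absent from that panel only
  rows2 <- rows[!(rows$review_id == "r2" & rows$learner == "svm" &
                    rows$method == "RUS-50:50"), ]
  fg2 <- forest_grid(rows2)
  expect_equal(nrow(fg2$panels[["svm / RUS-50:50"]]$deltas), 2)
  expect_equal(nrow(fg2$panels[["svm / ROS-50:50"]]$deltas), 3)

  # rendering runs without error
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path, width = 1200, height = 900)
  expect_no_error(plot(fg))
  grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("meta tables write as delimited text", {
  deltas <- data.frame(review_id = c("r1", "r2"), learner = "svm",
                       method = "RUS-50:50", delta = c(0.02, -0.01),
                       variance = c(1e-3, 2e-3),
                       ci_low = c(0, -0.1), ci_high = c(0.08, 0.08))
  pooled <- pool_deltas(deltas)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$n_reviews, 2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_meta_tables(deltas, pooled, p1, p2)
  expect_equal(nrow(read.csv(p1)), 2)
  expect_equal(read.csv(p2)$n_reviews, 2)
})
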