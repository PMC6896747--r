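# Delta-AUCs and fixed-effect inverse-variance pooling across reviews.

#' Within-review AUC difference between a balanced strategy and none
#'
#' `delta = mean_auc(balanced) - mean_auc(none)`. The sampling variance
#' treats the two cross-validated means as independent,
#' `var = (sd_balanced^2 + sd_none^2) / k`, and is floored at `var_floor`
#' (cells where every fold reaches AUC 1 have zero CV standard deviation,
#' which would give such cells infinite weight in the pooled model). The
#' 95% confidence interval is the normal interval
#' `delta +/- 1.96 * sqrt(var)`.
#'
#' @param balanced,none `cv_result` objects with `status = "ok"` and equal
#'   `n_folds`.
#' @param var_floor minimum variance (default `1e-6`).
#' @return a list of class `delta_auc` with `delta`, `variance`, `ci_low`,
#'   `ci_high`.
#' @export
delta_auc <- function(balanced, none, var_floor = 1e-6) {
  if (balanced$status != "ok" || none$status != "ok") {
    stop("delta_auc() requires two successful cv_results", call. = FALSE)
  }
  if (balanced$n_folds != none$n_folds) {
    stop("cv_results have different fold counts", call. = FALSE)
  }
  k <- balanced$n_folds
  delta <- balanced$mean_auc - none$mean_auc
  variance <- max(var_floor, (balanced$sd_auc^2 + none$sd_auc^2) / k)
  half <- 1.96 * sqrt(variance)
  structure(
    list(delta = delta, variance = variance,
         ci_low = delta - half, ci_high = delta + half),
    class = "delta_auc"
  )
}

#' Per-review delta-AUCs of every balanced strategy in a grid
#'
#' For each (review, learner, balanced spec) cell with a successful fit
#' whose same-review `none` baseline also succeeded, computes
#' [delta_auc()]. Cells where either side failed are excluded (recorded
#' nowhere downstream, mirroring how failed runs are reported as missing
#' rather than imputed).
#'
#' @param grid a `strategy_grid` from [run_grid()].
#' @param var_floor minimum per-review variance (default `1e-6`).
#' @return data frame with columns `review_id`, `learner`, `method`,
#'   `delta`, `variance`, `ci_low`, `ci_high`.
#' @export
compute_deltas <- function(grid, var_floor = 1e-6) {
  key <- function(r) paste(r$review_id, r$learner, sep = "\r")
  none <- list()
  for (r in grid$results) {
    if (r$balancing$method == "none") none[[key(r)]] <- r$cv
  }
  rows <- list()
  for (r in grid$results) {
    if (r$balancing$method == "none") next
    base <- none[[key(r)]]
    if (is.null(base) || base$status != "ok" || r$cv$status != "ok") next
    d <- delta_auc(r$cv, base, var_floor)
    rows[[length(rows) + 1L]] <- data.frame(
      review_id = r$review_id, learner = r$learner,
      method = balancing_label(r$balancing),
      delta = d$delta, variance = d$variance,
      ci_low = d$ci_low, ci_high = d$ci_high,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(review_id = character(0), learner = character(0),
                      method = character(0), delta = numeric(0),
                      variance = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Fixed-effect inverse-variance pooling
#'
#' Pools per-review effects under the fixed-effect model: weights
#' `w_i = 1 / variance_i`, pooled effect `sum(w_i * delta_i) / sum(w_i)`,
#' pooled standard error `sqrt(1 / sum(w_i))`, 95% normal (z) interval.
#'
#' @param delta numeric vector of per-review effects (or a data frame with
#'   `delta` and `variance` columns, e.g. a subset of [compute_deltas()]
#'   output).
#' @param variance numeric vector of their sampling variances (ignored when
#'   `delta` is a data frame).
#' @return a list of class `pooled_estimate`: `pooled_delta`, `pooled_se`,
#'   `ci_low`, `ci_high`, `n_reviews`, `weights` (normalised to sum to 1).
#' @export
pool_fixed_effect <- function(delta, variance = NULL) {
  if (is.data.frame(delta)) {
    variance <- delta$variance
    delta <- delta$delta
  }
  if (length(delta) == 0) {
    stop("pool_fixed_effect() needs at least one effect", call. = FALSE)
  }
  if (length(delta) != length(variance)) {
    stop("delta and variance must have equal length", call. = FALSE)
  }
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stop("variances must be positive and finite", call. = FALSE)
  }
  w <- 1 / variance
  pooled <- sum(w * delta) / sum(w)
  se <- sqrt(1 / sum(w))
  structure(
    list(pooled_delta = pooled, pooled_se = se,
         ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
         n_reviews = length(delta), weights = w / sum(w)),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> delta %.4f [%.4f, %.4f] (SE %.4f, %d reviews)\n",
    x$pooled_delta, x$ci_low, x$ci_high, x$pooled_se, x$n_reviews))
  invisible(x)
}

#' Pool delta-AUCs by learner and balancing method
#'
#' Applies [pool_fixed_effect()] within each (learner, method) stratum of a
#' [compute_deltas()] table.
#'
#' @param deltas data frame from [compute_deltas()].
#' @return data frame of class `pooled_deltas` with one row per stratum:
#'   `learner`, `method`, `pooled_delta`, `pooled_se`, `ci_low`, `ci_high`,
#'   `n_reviews`.
#' @export
pool_deltas <- function(deltas) {
  groups <- split(deltas, list(deltas$learner, deltas$method), drop = TRUE)
  rows <- lapply(groups, function(g) {
    p <- pool_fixed_effect(g)
    data.frame(learner = g$learner[1], method = g$method[1],
               pooled_delta = p$pooled_delta, pooled_se = p$pooled_se,
               ci_low = p$ci_low, ci_high = p$ci_high,
               n_reviews = p$n_reviews, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$learner, out$method), ]
  rownames(out) <- NULL
  class(out) <- c("pooled_deltas", "data.frame")
  out
}

#' Forest-plot grid of delta-AUCs
#'
#' Arranges per-review delta-AUCs and their pooled fixed-effect summaries
#' into one panel per (learner, balanced method): 4 learners x 4 balanced
#' strategies gives the standard 16-panel grid. The data table is the
#' tested surface; [plot.forest_grid()] renders it.
#'
#' @param grid a `strategy_grid` from [run_grid()] (or a precomputed
#'   [compute_deltas()] data frame).
#' @param var_floor passed to [compute_deltas()] when `grid` is a
#'   `strategy_grid`.
#' @return object of class `forest_grid`: list with `panels` (named list,
#'   one element per learner x method containing `deltas` and `pooled`),
#'   `learners`, `methods`.
#' @export
forest_grid <- function(grid, var_floor = 1e-6) {
  deltas <- if (inherits(grid, "strategy_grid")) {
    compute_deltas(grid, var_floor)
  } else {
    grid
  }
  learners <- sort(unique(deltas$learner))
  methods <- sort(unique(deltas$method))
  panels <- list()
  for (ln in learners) {
    for (mt in methods) {
      d <- deltas[deltas$learner == ln & deltas$method == mt, , drop = FALSE]
      if (nrow(d) == 0) next
      panels[[paste(ln, mt, sep = " / ")]] <- list(
        learner = ln, method = mt, deltas = d,
        pooled = pool_fixed_effect(d)
      )
    }
  }
  structure(list(panels = panels, learners = learners, methods = methods),
            class = "forest_grid")
}

#' @export
print.forest_grid <- function(x, ...) {
  cat("<forest_grid>", length(x$panels), "panels (",
      length(x$learners), "learners x", length(x$methods), "methods )\n")
  for (p in x$panels) {
    cat(sprintf("  %-18s pooled %+0.4f [%+0.4f, %+0.4f] (%d reviews)\n",
                paste(p$learner, p$method, sep = " / "),
                p$pooled$pooled_delta, p$pooled$ci_low, p$pooled$ci_high,
                p$pooled$n_reviews))
  }
  invisible(x)
}

#' Render a forest-plot grid
#'
#' Base-graphics forest plots, learners as rows and balancing methods as
#' columns; per-review effects as points with 95% CI whiskers and the
#' pooled fixed-effect estimate as a diamond at the bottom of each panel.
#'
#' @param x a `forest_grid`.
#' @param xlim optional shared x-axis limits.
#' @param ... further arguments (ignored).
#' @return `x`, invisibly.
#' @export
plot.forest_grid <- function(x, xlim = NULL, ...) {
  if (length(x$panels) == 0) {
    stop("forest grid has no panels", call. = FALSE)
  }
  if (is.null(xlim)) {
    lo <- min(vapply(x$panels, function(p) min(p$deltas$ci_low), numeric(1)))
    hi <- max(vapply(x$panels, function(p) max(p$deltas$ci_high), numeric(1)))
    xlim <- range(c(lo, hi, 0))
  }
  old <- graphics::par(mfrow = c(length(x$learners), length(x$methods)),
                       mar = c(2.5, 4.5, 1.5, 0.5), cex = 0.6)
  on.exit(graphics::par(old))
  for (ln in x$learners) {
    for (mt in x$methods) {
      p <- x$panels[[paste(ln, mt, sep = " / ")]]
      if (is.null(p)) {
        graphics::plot.new()
        next
      }
      d <- p$deltas
      n <- nrow(d)
      ys <- rev(seq_len(n)) + 1
      graphics::plot(NA, xlim = xlim, ylim = c(0, n + 2),
                     xlab = "", ylab = "", yaxt = "n",
                     main = paste(ln, mt, sep = " / "))
      graphics::abline(v = 0, lty = 3, col = "grey50")
      graphics::segments(d$ci_low, ys, d$ci_high, ys)
      graphics::points(d$delta, ys, pch = 15)
      graphics::axis(2, at = ys, labels = d$review_id, las = 1,
                     cex.axis = 0.8)
      pe <- p$pooled
      graphics::polygon(
        c(pe$ci_low, pe$pooled_delta, pe$ci_high, pe$pooled_delta),
        c(0.5, 0.8, 0.5, 0.2), col = "firebrick", border = NA)
    }
  }
  invisible(x)
}

#' Write delta and pooled tables as delimited text
#' @param deltas data frame from [compute_deltas()].
#' @param pooled data frame from [pool_deltas()].
#' @param path_deltas,path_pooled CSV file paths.
#' @return invisibly, a list of the two paths.
#' @export
write_meta_tables <- function(deltas, pooled, path_deltas, path_pooled) {
  write.csv(deltas, path_deltas, row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(as.data.frame(pooled), path_pooled, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(list(deltas = path_deltas, pooled = path_pooled))
}
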