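# Stage one: stagewise least-squares boosted regression trees over the
# categorical predictors age group, gender and period, with the screening
# summaries used to pick the hierarchical model structure.

#' Fit boosted regression trees to pooled log-concentrations
#'
#' Stagewise least-squares boosting: starting from the training mean, each
#' regression tree is fitted to the residuals of the current ensemble and
#' added with weight \code{shrinkage}.  The data are split 50/50 into
#' training and test halves, stratified by design cell so that small cells
#' appear in both halves; boosting stops early when the held-out deviance
#' has not improved for \code{patience} consecutive trees (the ensemble is
#' truncated at the best held-out iteration), or when a tree finds no
#' residual structure left to split.
#'
#' @param data Pooled data frame (see \code{\link{simulate_pools}} or
#'   \code{\link{read_pooled_table}}); the response is
#'   \code{log_concentration}.
#' @param shrinkage Learning rate in (0, 1].
#' @param max_trees Maximum number of boosting iterations.
#' @param tree_depth Maximum tree depth; depth 3 admits two-way (and
#'   three-way) interactions, depth 1 (stumps) forces an additive fit.
#' @param split_seed Integer seed controlling the stratified train/test
#'   split (the only randomness in the fit).
#' @param patience Early-stopping patience in trees.
#' @return An object of class \code{"brt_fit"}.
#' @seealso \code{\link{relative_importance}},
#'   \code{\link{interaction_strength}}, \code{\link{partial_dependence}},
#'   \code{\link{brt_rmse}}
#' @export
fit_brt <- function(data, shrinkage = 0.01, max_trees = 5000L,
                    tree_depth = 3L, split_seed = 1L, patience = 50L) {
  data <- as_pooled_data(data)
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 observations to fit")
  if (!(shrinkage > 0 && shrinkage <= 1)) stop("shrinkage must be in (0, 1]")
  X <- cbind(as.integer(data$age_group), as.integer(data$gender), data$t)
  y <- data$log_concentration

  # stratified 50/50 split; the leftover pool of odd cells alternates sides
  # so the two halves differ by at most one observation overall
  cell <- (data$t - 1L) * 10L + (as.integer(data$gender) - 1L) * 5L +
    as.integer(data$age_group)
  train <- logical(n)
  toggle <- TRUE
  with_seed(split_seed, {
    for (cl in sort(unique(cell))) {
      ids <- which(cell == cl)
      ids <- ids[sample.int(length(ids))]
      k <- length(ids) %/% 2L
      if (length(ids) %% 2L == 1L) {
        if (toggle) k <- k + 1L
        toggle <- !toggle
      }
      train[ids[seq_len(k)]] <- TRUE
    }
  })
  tr <- which(train)
  te <- which(!train)
  if (length(tr) == 0L || length(te) == 0L) {
    stop("train/test split left one half empty; need at least 2 observations")
  }

  init <- mean(y[tr])
  F_tr <- rep(init, length(tr))
  F_te <- rep(init, length(te))
  trees <- vector("list", max_trees)
  split_vars <- vector("list", max_trees)
  split_imps <- vector("list", max_trees)
  loss <- numeric(max_trees)
  test_loss <- numeric(max_trees)
  best_iter <- 0L
  best_test <- mean((y[te] - F_te)^2)
  since_best <- 0L
  grown <- 0L
  resid <- numeric(n) # full-length so trees index it by data row
  for (m in seq_len(max_trees)) {
    resid[tr] <- y[tr] - F_tr
    acc <- new.env(parent = emptyenv())
    acc$var <- integer(0)
    acc$imp <- numeric(0)
    tree <- grow_tree(resid, X, tr, tree_depth, acc)
    if (length(acc$var) == 0L) break # nothing left to fit
    F_tr <- F_tr + shrinkage * predict_tree(tree, X, tr)
    F_te <- F_te + shrinkage * predict_tree(tree, X, te)
    grown <- m
    trees[[m]] <- tree
    split_vars[[m]] <- acc$var
    split_imps[[m]] <- acc$imp
    loss[m] <- mean((y[tr] - F_tr)^2)
    test_loss[m] <- mean((y[te] - F_te)^2)
    if (test_loss[m] < best_test) {
      best_test <- test_loss[m]
      best_iter <- m
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (since_best >= patience) break
  }
  keep <- seq_len(best_iter)
  structure(
    list(
      init = init,
      trees = trees[keep],
      split_vars = split_vars[keep],
      split_imps = split_imps[keep],
      n_trees = best_iter,
      trees_grown = grown,
      shrinkage = shrinkage,
      tree_depth = as.integer(tree_depth),
      train_indices = tr,
      test_indices = te,
      loss_trace = loss[seq_len(grown)],
      test_trace = test_loss[seq_len(grown)],
      data = data,
      X = X,
      y = y,
      split_seed = split_seed
    ),
    class = "brt_fit"
  )
}

# Ensemble predictions over the full 5 x 2 x 5 grid of design cells.
grid_predictions <- function(fit) {
  grid <- as.matrix(expand.grid(a = 1:5, g = 1:2, t = 1:5))
  pred <- rep(fit$init, nrow(grid))
  rows <- seq_len(nrow(grid))
  for (tree in fit$trees) {
    pred <- pred + fit$shrinkage * predict_tree(tree, grid, rows)
  }
  array(pred, dim = c(5L, 2L, 5L))
}

#' @export
predict.brt_fit <- function(object, newdata = NULL, ...) {
  P <- grid_predictions(object)
  nd <- if (is.null(newdata)) object$data else as_pooled_data(newdata)
  unname(P[cbind(as.integer(nd$age_group), as.integer(nd$gender), nd$t)])
}

#' Relative importance of the predictors in a boosted-tree fit
#'
#' Sums the squared-error improvement of every split, per predictor, over
#' all trees in the ensemble, and rescales so the importances add to 100.
#' Larger values indicate a stronger influence on the log-concentration.
#'
#' @param fit A \code{\link{fit_brt}} object with at least one split.
#' @return Named numeric vector (age_group, gender, period) summing to 100.
#' @export
relative_importance <- function(fit) {
  stopifnot(inherits(fit, "brt_fit"))
  imp <- numeric(3L)
  for (m in seq_len(fit$n_trees)) {
    v <- fit$split_vars[[m]]
    im <- fit$split_imps[[m]]
    for (j in seq_along(v)) imp[v[j]] <- imp[v[j]] + im[j]
  }
  if (sum(imp) <= 0) {
    stop("relative importance is undefined for a fit with no splits")
  }
  imp <- imp / max(1L, fit$n_trees)
  out <- 100 * imp / sum(imp)
  names(out) <- .PREDICTORS
  out
}

#' Interaction strength of a predictor pair
#'
#' Measures how far the ensemble's joint effect of a predictor pair departs
#' from additivity: ensemble predictions are formed on the full grid of the
#' pair's level combinations (marginalising the remaining predictor over the
#' empirical training distribution), an additive main-effects linear model is
#' fitted to the grid predictions weighted by the pair's training frequency,
#' and the weighted residual variance is returned.  Purely additive
#' ensembles (e.g. stumps) score exactly zero.
#'
#' @param fit A \code{\link{fit_brt}} object.
#' @param pair Character vector of two distinct predictors from
#'   \code{c("age_group", "gender", "period")}.
#' @return A single non-negative number.
#' @export
interaction_strength <- function(fit, pair) {
  stopifnot(inherits(fit, "brt_fit"))
  vi <- match(pair, .PREDICTORS)
  if (length(vi) != 2L || anyNA(vi) || vi[1] == vi[2]) {
    stop("pair must name two distinct predictors among: ",
         paste(.PREDICTORS, collapse = ", "))
  }
  other <- setdiff(1:3, vi)
  P <- grid_predictions(fit)
  Xtr <- fit$X[fit$train_indices, , drop = FALSE]
  w_other <- tabulate(Xtr[, other], .NLEV[[other]])
  w_other <- w_other / sum(w_other)
  Pp <- aperm(P, c(vi, other))
  k1 <- dim(Pp)[1]
  k2 <- dim(Pp)[2]
  G2 <- apply(Pp, c(1, 2), function(z) sum(z * w_other))
  W2 <- matrix(0, k1, k2)
  tb <- table(factor(Xtr[, vi[1]], levels = 1:k1),
              factor(Xtr[, vi[2]], levels = 1:k2))
  W2[] <- as.numeric(tb)
  df <- data.frame(
    p = as.vector(G2),
    f1 = factor(rep(seq_len(k1), k2)),
    f2 = factor(rep(seq_len(k2), each = k1)),
    w = as.vector(W2)
  )
  df <- droplevels(df[df$w > 0, , drop = FALSE])
  terms <- c(if (nlevels(df$f1) > 1) "f1", if (nlevels(df$f2) > 1) "f2")
  form <- stats::reformulate(if (length(terms)) terms else "1", response = "p")
  lmfit <- stats::lm(form, data = df, weights = df$w)
  max(0, sum(df$w * stats::residuals(lmfit)^2) / sum(df$w))
}

#' All pairwise interaction strengths
#'
#' @param fit A \code{\link{fit_brt}} object.
#' @return Named numeric vector over the three unordered predictor pairs.
#' @export
interaction_table <- function(fit) {
  pairs <- utils::combn(.PREDICTORS, 2, simplify = FALSE)
  out <- vapply(pairs, function(p) interaction_strength(fit, p), 0)
  names(out) <- vapply(pairs, paste, "", collapse = ":")
  out
}

#' Partial dependence (marginal effect) of one predictor
#'
#' Per level of \code{predictor}, the average ensemble prediction with the
#' other predictors marginalised over the empirical training distribution,
#' centred so the training-weighted mean effect is zero.  Effects above zero
#' indicate higher log-concentrations than the overall expectation.
#'
#' @param fit A \code{\link{fit_brt}} object.
#' @param predictor One of \code{"age_group"}, \code{"gender"},
#'   \code{"period"}.
#' @return Data frame with columns \code{level}, \code{effect} and
#'   \code{weight} (the training share of the level).
#' @export
partial_dependence <- function(fit, predictor) {
  stopifnot(inherits(fit, "brt_fit"))
  v <- match(predictor, .PREDICTORS)
  if (is.na(v)) stop("unknown predictor: ", predictor)
  other <- setdiff(1:3, v)
  P <- grid_predictions(fit)
  Xtr <- fit$X[fit$train_indices, , drop = FALSE]
  k1 <- .NLEV[[other[1]]]
  k2 <- .NLEV[[other[2]]]
  W <- matrix(0, k1, k2)
  tb <- table(factor(Xtr[, other[1]], levels = 1:k1),
              factor(Xtr[, other[2]], levels = 1:k2))
  W[] <- as.numeric(tb)
  W <- W / sum(W)
  Pp <- aperm(P, c(v, other))
  pd <- apply(Pp, 1, function(z) sum(z * W))
  wl <- tabulate(Xtr[, v], .NLEV[[v]])
  wl <- wl / sum(wl)
  pd <- pd - sum(pd * wl)
  data.frame(level = design_levels()[[predictor]], effect = pd, weight = wl,
             stringsAsFactors = FALSE)
}

#' Root mean squared error of a boosted-tree fit
#'
#' \code{sqrt(mean((y - yhat)^2))} of the ensemble over the training or the
#' held-out half of the data, on the log-concentration scale.
#'
#' @param fit A \code{\link{fit_brt}} object.
#' @param subset \code{"test"} (default) or \code{"train"}.
#' @return A single non-negative number.
#' @export
brt_rmse <- function(fit, subset = c("test", "train")) {
  stopifnot(inherits(fit, "brt_fit"))
  subset <- match.arg(subset)
  idx <- if (subset == "train") fit$train_indices else fit$test_indices
  if (length(idx) == 0L) stop("the ", subset, " subset is empty")
  P <- grid_predictions(fit)
  pred <- P[cbind(fit$X[idx, 1], fit$X[idx, 2], fit$X[idx, 3])]
  sqrt(mean((fit$y[idx] - pred)^2))
}

#' @export
print.brt_fit <- function(x, ...) {
  cat("Boosted regression trees on pooled log-concentrations\n")
  cat(sprintf("  %d trees kept (of %d grown), depth %d, shrinkage %g\n",
              x$n_trees, x$trees_grown, x$tree_depth, x$shrinkage))
  cat(sprintf("  train/test: %d/%d observations (stratified split, seed %s)\n",
              length(x$train_indices), length(x$test_indices),
              format(x$split_seed)))
  if (x$n_trees > 0L) {
    cat(sprintf("  held-out RMSE: %.4f\n", brt_rmse(x, "test")))
  } else {
    cat("  constant fit (no splits)\n")
  }
  invisible(x)
}

#' @export
summary.brt_fit <- function(object, ...) {
  out <- list(
    n_trees = object$n_trees,
    rmse_train = brt_rmse(object, "train"),
    rmse_test = brt_rmse(object, "test"),
    importance = if (object$n_trees > 0L) relative_importance(object) else NULL,
    interactions = if (object$n_trees > 0L) interaction_table(object) else NULL
  )
  class(out) <- "summary.brt_fit"
  out
}

#' @export
print.summary.brt_fit <- function(x, ...) {
  cat(sprintf("BRT ensemble: %d trees; RMSE train %.4f / test %.4f\n",
              x$n_trees, x$rmse_train, x$rmse_test))
  if (!is.null(x$importance)) {
    cat("Relative importance (sums to 100):\n")
    print(round(x$importance, 2))
    cat("Interaction strength (residual variance of additive grid model):\n")
    print(signif(x$interactions, 4))
  }
  invisible(x)
}

#' @export
plot.brt_fit <- function(x, ...) {
  if (x$trees_grown == 0L) {
    stop("nothing to plot: no trees were grown")
  }
  it <- seq_len(x$trees_grown)
  graphics::plot(it, x$loss_trace, type = "l", xlab = "boosting iteration",
                 ylab = "mean squared error", ylim = range(c(x$loss_trace, x$test_trace)),
                 ...)
  graphics::lines(it, x$test_trace, lty = 2)
  graphics::abline(v = x$n_trees, col = "grey60")
  graphics::legend("topright", c("train", "held-out"), lty = c(1, 2), bty = "n")
  invisible(x)
}
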