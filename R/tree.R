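# Internal regression trees over the three categorical design predictors
# (age group, gender, period).  Splits are binary level-subset partitions,
# found by exact enumeration (at most 5 levels per predictor), scored by
# the least-squares improvement criterion.

.NLEV <- c(age_group = 5L, gender = 2L, period = 5L)

# All level subsets that can go left, per number of levels k: a k x m logical
# matrix; level 1 is always on the left (subset/complement symmetry) and the
# full set is excluded.
.SUBSETS <- lapply(1:5, function(k) {
  if (k < 2) return(NULL)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k - 1), KEEP.OUT.ATTRS = FALSE)
  m <- rbind(TRUE, t(as.matrix(combos)))
  m[, colSums(m) < k, drop = FALSE]
})

# Best single split of the rows `idx` (response y over the full data, design
# matrix X of integer level codes).  Returns NULL when no split reduces the
# sum of squares, else list(var, left, improvement) where `improvement` is
# the SSE reduction.
node_best_split <- function(y, X, idx) {
  n <- length(idx)
  if (n < 2L) return(NULL)
  yv <- y[idx]
  S <- sum(yv)
  base <- S * S / n
  best <- NULL
  best_imp <- 1e-12
  for (v in seq_along(.NLEV)) {
    k <- .NLEV[[v]]
    lv <- X[idx, v]
    cnt <- tabulate(lv, k)
    if (sum(cnt > 0L) < 2L) next
    sm <- numeric(k)
    sums <- rowsum(yv, lv)
    sm[as.integer(rownames(sums))] <- sums
    M <- .SUBSETS[[k]]
    nL <- colSums(cnt * M)
    sL <- colSums(sm * M)
    ok <- nL > 0 & nL < n
    if (!any(ok)) next
    imp <- sL[ok]^2 / nL[ok] + (S - sL[ok])^2 / (n - nL[ok]) - base
    j <- which.max(imp)
    if (imp[j] > best_imp) {
      best_imp <- imp[j]
      left <- which(M[, which(ok)[j]])
      best <- list(var = v, left = left, improvement = unname(imp[j]))
    }
  }
  best
}

# Grow one regression tree to depth `depth`; split improvements are
# accumulated in the environment `acc` ($var, $imp).
grow_tree <- function(y, X, idx, depth, acc) {
  if (depth <= 0L || length(idx) < 2L) {
    return(list(leaf = TRUE, value = mean(y[idx])))
  }
  sp <- node_best_split(y, X, idx)
  if (is.null(sp)) {
    return(list(leaf = TRUE, value = mean(y[idx])))
  }
  acc$var <- c(acc$var, sp$var)
  acc$imp <- c(acc$imp, sp$improvement)
  goleft <- X[idx, sp$var] %in% sp$left
  list(
    leaf = FALSE, var = sp$var, left = sp$left,
    l = grow_tree(y, X, idx[goleft], depth - 1L, acc),
    r = grow_tree(y, X, idx[!goleft], depth - 1L, acc)
  )
}

# Predictions of a single tree for rows `idx` of X.
predict_tree <- function(tree, X, idx) {
  out <- numeric(length(idx))
  rec <- function(node, pos) {
    if (node$leaf) {
      out[pos] <<- node$value
      return(invisible(NULL))
    }
    gl <- X[idx[pos], node$var] %in% node$left
    if (any(gl)) rec(node$l, pos[gl])
    if (any(!gl)) rec(node$r, pos[!gl])
  }
  if (length(idx)) rec(tree, seq_along(idx))
  out
}
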