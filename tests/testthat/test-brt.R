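test_that("a constant response yields a constant ensemble with no splits", {
  d <- grid_data(rep(2.5, 50))
  fit <- fit_brt(d, shrinkage = 0.1, max_trees = 100, split_seed = 1)
  expect_equal(fit$n_trees, 0L)
  expect_equal(unique(predict(fit)), 2.5)
  expect_error(relative_importance(fit), "no splits")
})

test_that("a noiseless age signal is recovered to numerical precision", {
  p <- hier_params(2, sigma = 0,
                   alpha_ag = matrix(rep(c(4, 3.5, 3, 2.5, 2), 2), 5, 2))
  d <- simulate_pools(make_design(4), p, seed = 1)
  fit <- fit_brt(d, shrinkage = 0.3, max_trees = 300, split_seed = 2)
  expect_lte(brt_rmse(fit, "test"), 1e-6)
  expect_lte(brt_rmse(fit, "train"), 1e-6)
  imp <- relative_importance(fit)
  expect_equal(unname(imp["age_group"]), 100)
  expect_equal(sum(imp), 100, tolerance = 1e-9)
})

test_that("training deviance is non-increasing and the fit is reproducible", {
  d <- simulate_pools(make_design(3), params_spec3(), seed = 9)
  fit <- fit_brt(d, shrinkage = 0.05, max_trees = 400, split_seed = 3)
  expect_gt(fit$n_trees, 0L)
  expect_true(all(diff(fit$loss_trace) <= 1e-12))
  fit2 <- fit_brt(d, shrinkage = 0.05, max_trees = 400, split_seed = 3)
  expect_identical(predict(fit), predict(fit2))
  expect_identical(fit$train_indices, fit2$train_indices)
})

test_that("the 50/50 split is stratified and balanced", {
  d <- simulate_pools(default_design(), params_spec1(), seed = 2)
  fit <- fit_brt(d, max_trees = 1, split_seed = 5)
  expect_lte(abs(length(fit$train_indices) - length(fit$test_indices)), 1L)
  cellcode <- interaction(d$age_group, d$gender, d$period, drop = TRUE)
  for (cl in levels(cellcode)) {
    ids <- which(cellcode == cl)
    ntr <- sum(ids %in% fit$train_indices)
    expect_lte(abs(ntr - (length(ids) - ntr)), 1L)
  }
})

test_that("importances sum to 100 on noisy fits across seeds", {
  for (s in 1:5) {
    d <- simulate_pools(make_design(3), params_spec3(sigma = 0.4), seed = 20 + s)
    fit <- fit_brt(d, shrinkage = 0.05, max_trees = 500, split_seed = s)
    if (fit$n_trees > 0L) {
      expect_equal(sum(relative_importance(fit)), 100, tolerance = 1e-9)
    }
  }
})

test_that("stump ensembles have zero interaction strength for every pair", {
  d <- simulate_pools(make_design(4), params_spec3(sigma = 0.3), seed = 7)
  fit <- fit_brt(d, shrinkage = 0.1, max_trees = 300, tree_depth = 1,
                 split_seed = 1)
  expect_gt(fit$n_trees, 0L)
  expect_true(all(interaction_table(fit) <= 1e-12))
})

test_that("purely additive noiseless signals score (near) zero interaction", {
  B <- outer(c(4, 3.5, 3, 2.8, 2.5), rep(1, 5)) +
    outer(rep(1, 5), c(0, -0.1, -0.2, -0.3, -0.4))
  p <- hier_params(1, sigma = 0, beta_at = B)
  d <- simulate_pools(make_design(4), p, seed = 3)
  fit <- fit_brt(d, shrinkage = 0.3, max_trees = 400, split_seed = 2)
  # greedy trees stall once the residual is a pure interaction pattern no
  # single split can reduce; that leftover is far below the noise floor
  expect_lte(brt_rmse(fit, "test"), 1e-4)
  expect_true(all(interaction_table(fit) <= 1e-6))
})

test_that("a planted age-by-period interaction attains the top strength", {
  p <- hier_params(1, sigma = 0.3, beta_at = diverging_beta())
  wins <- 0L
  for (s in 1:5) {
    d <- simulate_pools(make_design(4), p, seed = 500 + s)
    fit <- fit_brt(d, shrinkage = 0.05, max_trees = 1500, split_seed = s)
    it <- interaction_table(fit)
    if (names(which.max(it)) == "age_group:period") wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("partial dependence is centred and tracks a planted monotone effect", {
  p <- hier_params(2, sigma = 0,
                   alpha_ag = matrix(rep(c(4, 3.5, 3, 2.5, 2), 2), 5, 2))
  d <- simulate_pools(make_design(4), p, seed = 1)
  fit <- fit_brt(d, shrinkage = 0.3, max_trees = 300, split_seed = 2)
  for (v in c("age_group", "gender", "period")) {
    pd <- partial_dependence(fit, v)
    expect_equal(sum(pd$effect * pd$weight), 0, tolerance = 1e-9)
  }
  pd_age <- partial_dependence(fit, "age_group")
  expect_true(all(diff(pd_age$effect) < 0)) # decreasing planted age effect
  expect_error(partial_dependence(fit, "bmi"), "unknown predictor")
})

test_that("fit validation rejects degenerate inputs", {
  d <- simulate_pools(make_design(2), params_spec1(), seed = 1)
  expect_error(fit_brt(d, shrinkage = 0), "shrinkage")
  expect_error(fit_brt(d, shrinkage = 1.5), "shrinkage")
  expect_error(fit_brt(d[0, ]), "at least 2")
  expect_error(interaction_strength(fit_brt(d, max_trees = 5),
                                    c("age_group", "weight")), "distinct predictors")
})
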