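test_that("trajectories collapse to points under a degenerate posterior", {
  B <- diverging_beta()
  d <- grid_data(rep(3, 50))
  f <- degenerate_fit(theta_spec1(B), d, spec = 1L)
  tr <- trajectories(f)
  expect_equal(tr$lwr, tr$mean, tolerance = 1e-12)
  expect_equal(tr$upr, tr$mean, tolerance = 1e-12)
  a <- as.integer(tr$age_group)
  expect_equal(tr$mean, B[cbind(a, tr$t)], tolerance = 1e-12)
})

test_that("spec-1 trajectories are identical across genders", {
  d <- simulate_pools(make_design(3), params_spec1(), seed = 15)
  f <- fit_hier(d, model = 1, iter = 400, burnin = 400, seed = 2)
  tr <- trajectories(f)
  m <- tr[tr$gender == "male", c("mean", "lwr", "upr")]
  fe <- tr[tr$gender == "female", c("mean", "lwr", "upr")]
  expect_equal(m, fe, ignore_attr = TRUE)
})

test_that("percent change reproduces exact ratios under degenerate draws", {
  B <- matrix(3, 5, 5)
  B[2, 5] <- 3 + log(2) # a doubling for age group 2
  f <- degenerate_fit(theta_spec1(B), grid_data(rep(3, 50)), spec = 1L)
  flat <- percent_change(f, "5-15", "2002/03", "2012/13")
  expect_equal(flat$percent_change, 0, tolerance = 1e-12)
  expect_equal(flat$lwr, 0, tolerance = 1e-12)
  expect_equal(flat$upr, 0, tolerance = 1e-12)
  dbl <- percent_change(f, "16-30", "2002/03", "2012/13")
  expect_equal(dbl$percent_change, 100, tolerance = 1e-9)
})

test_that("percent change is invariant to a constant shift of all cell means", {
  d <- simulate_pools(make_design(3), params_spec1(), seed = 25)
  f <- fit_hier(d, model = 1, iter = 300, burnin = 300, seed = 3)
  f_shift <- f
  shift_cols <- grep("^beta", colnames(f$draws[[1]]))
  f_shift$draws <- lapply(f$draws, function(m) {
    m[, shift_cols] <- m[, shift_cols] + 5
    m
  })
  pc <- percent_change(f, "31-45", "2002/03", "2012/13")
  pc_s <- percent_change(f_shift, "31-45", "2002/03", "2012/13")
  expect_equal(attr(pc, "draws"), attr(pc_s, "draws"), tolerance = 1e-9)
})

test_that("draw-wise overall change composes the consecutive steps exactly", {
  d <- simulate_pools(default_design(), params_spec1(), seed = 35)
  f <- fit_hier(d, model = 1, iter = 500, burnin = 500, seed = 4)
  lv <- design_levels()
  for (ag in c("5-15", ">60")) {
    overall <- attr(percent_change(f, ag, lv$period[1], lv$period[5]), "draws")
    steps <- lapply(1:4, function(tt) {
      attr(percent_change(f, ag, lv$period[tt], lv$period[tt + 1]), "draws")
    })
    composed <- Reduce(`*`, lapply(steps, function(s) 1 + s / 100))
    expect_equal(1 + overall / 100, composed, tolerance = 1e-9)
  }
})

test_that("consecutive changes enumerate every adjacent period pair in order", {
  B <- matrix(3, 5, 5)
  f <- degenerate_fit(theta_spec1(B), grid_data(rep(3, 50)), spec = 1L)
  cc <- consecutive_changes(f)
  expect_equal(nrow(cc), 20L)
  expect_equal(unique(cc$percent_change), 0)
  first_age <- cc$comparison[cc$age_group == "5-15"]
  expect_equal(first_age, c("2002/03 → 2006/07", "2006/07 → 2008/09",
                            "2008/09 → 2010/11", "2010/11 → 2012/13"))
})

test_that("model 2 refuses temporal change analyses with the documented error", {
  d <- simulate_pools(make_design(2), params_spec2(), seed = 45)
  f <- fit_hier(d, model = 2, iter = 200, burnin = 200, seed = 5)
  expect_error(percent_change(f, "5-15", "2002/03", "2012/13"),
               class = "pooltrend_time_not_in_model")
  expect_error(consecutive_changes(f), class = "pooltrend_time_not_in_model")
  expect_error(cohort_changes(f), class = "pooltrend_time_not_in_model")
})

test_that("cohort extrapolation tracks a planted pure-aging process", {
  # cell means constant along cohorts: B[a+1, 5] = B[a, 1]
  glin <- function(x) 2 + 0.5 * x
  B <- outer(1:5, 1:5, function(a, t) glin(a - (t - 1) / 4))
  p <- hier_params(1, sigma = 0.1, beta_at = B)
  d <- simulate_pools(make_design(6), p, seed = 55)
  f <- fit_hier(d, model = 1, iter = 1500, burnin = 1500, seed = 6)
  coh <- cohort_changes(f)
  expect_equal(nrow(coh), 4L)
  same_age <- vapply(design_levels()$age_group, function(ag) {
    percent_change(f, ag, "2002/03", "2012/13")$percent_change
  }, 0)
  # same-age decline is approximately 100*(exp(-0.5)-1) = -39%; cohorts flat
  expect_true(all(same_age < -25))
  expect_true(all(abs(coh$percent_change) < 15))
  expect_true(all(coh$lwr <= 0 & coh$upr >= 0))
})

test_that("cohort changes with exactly identical cell means are all zero", {
  f <- degenerate_fit(theta_spec1(matrix(2, 5, 5)), grid_data(rep(2, 50)),
                      spec = 1L)
  coh <- cohort_changes(f)
  expect_equal(coh$percent_change, rep(0, 4), tolerance = 1e-12)
})

test_that("sensitivity subsampling reduces only the target cell", {
  d <- simulate_pools(default_design(), params_spec2(), seed = 65)
  red <- sensitivity_subsample(d, seed = 2, models = integer(0))$data
  in_cell <- function(x) x$age_group == "5-15" & x$period == "2006/07"
  expect_equal(sum(in_cell(red) & red$gender == "male"), 4L)
  expect_equal(sum(in_cell(red) & red$gender == "female"), 4L)
  expect_equal(nrow(red), nrow(d) - (15 - 4) - (17 - 4))
  expect_identical(red[!in_cell(red), "log_concentration"],
                   d[!in_cell(d), "log_concentration"])
  # keeping the whole cell reproduces the input
  full <- sensitivity_subsample(d, n_keep_per_gender = 15L, seed = 2,
                                models = integer(0))$data
  expect_equal(sum(in_cell(full)), 15 + 15)
  expect_error(sensitivity_subsample(d, n_keep_per_gender = 40L, seed = 2,
                                     models = integer(0)), "fewer than")
})

test_that("subsampling a homogeneous cell barely moves the posterior", {
  # homogeneous cell values (zero observation noise): dropping pools leaves
  # the cell information unchanged, so the posterior barely moves
  d <- simulate_pools(default_design(),
                      hier_params(2, sigma = 0, alpha_ag = matrix(3, 5, 2)),
                      seed = 75)
  sens <- sensitivity_subsample(d, seed = 3, models = 2L, chains = 2L,
                                iter = 800L, burnin = 800L)
  shift <- abs(sens$comparison$mean_full - sens$comparison$mean_reduced)
  expect_true(all(shift < sens$comparison$sd_full))
})
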