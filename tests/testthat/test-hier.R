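test_that("model catalogues count and name every parameter of each structure", {
  m1 <- build_model(1)
  expect_equal(nrow(m1$parameters), 5 + 25 + 2) # beta0, beta, sigma, omega
  expect_equal(sum(m1$parameters$role == "temporal"), 25)
  m1g <- build_model(1, include_gender = TRUE)
  expect_equal(nrow(m1g$parameters), 34)
  m2 <- build_model(2)
  expect_equal(nrow(m2$parameters), 10 + 5 + 2) # alpha, delta_a, sigma, phi
  m3 <- build_model(3)
  expect_equal(nrow(m3$parameters), 45)
  # spec 3 = spec 1 temporal block plus the age-by-gender block
  expect_true(all(m1$parameters$name %in% c(m3$parameters$name, "omega")))
  expect_true(all(c("alpha[1,1]", "delta_g[2]", "phi") %in% m3$parameters$name))
  expect_error(build_model(4), "1, 2 or 3")
  expect_error(build_model(1, n_age = 0), ">= 1")
})

test_that("log_lik matches the closed-form normal density", {
  m <- build_model(2)
  d <- grid_data(rep(0, 50))[1, , drop = FALSE]
  d$concentration <- exp(3) # one observation with y = 3
  theta <- theta_spec2(alpha = matrix(3, 5, 2), sigma = 1)
  expect_equal(log_lik(m, theta, d), -0.5 * log(2 * pi), tolerance = 1e-12)
  # translation invariance of the residual
  d2 <- d
  d2$concentration <- exp(3 + 7)
  theta2 <- theta_spec2(alpha = matrix(3 + 7, 5, 2), sigma = 1)
  expect_equal(log_lik(m, theta2, d2), log_lik(m, theta, d), tolerance = 1e-12)
  # sigma at the boundary with a nonzero residual
  theta0 <- theta_spec2(alpha = matrix(2, 5, 2), sigma = 0)
  expect_identical(log_lik(m, theta0, d), -Inf)
})

test_that("log_joint is -Inf outside the prior support and finite inside", {
  m <- build_model(2)
  d <- grid_data(rnorm(50, 3, 0.3))
  ok <- theta_spec2(alpha = matrix(3, 5, 2), delta_a = rep(3, 5),
                    sigma = 0.5, phi = 0.4)
  expect_true(is.finite(log_joint(m, ok, d)))
  bad_hi <- ok; bad_hi[16] <- 150 # sigma beyond the uniform bound
  expect_identical(log_joint(m, bad_hi, d), -Inf)
  bad_lo <- ok; bad_lo[17] <- 0 # phi at the boundary
  expect_identical(log_joint(m, bad_lo, d), -Inf)
  expect_error(log_joint(m, ok[-1], d), "length")
})

test_that("log_joint agrees with an independently written density sum", {
  m <- build_model(2)
  set.seed(42)
  ylog <- rnorm(50, 3, 0.5)
  d <- grid_data(ylog)
  alpha <- matrix(seq(2.5, 3.5, length.out = 10), 5, 2)
  delta_a <- seq(2.6, 3.4, length.out = 5)
  sigma <- 0.5; phi <- 0.4
  theta <- theta_spec2(alpha, delta_a, sigma, phi)
  a <- rep(1:5, 10); g <- rep(rep(1:2, each = 5), 5) # grid order of grid_data
  expected <- sum(dnorm(ylog, alpha[cbind(a, g)], sigma, log = TRUE)) +
    sum(dnorm(as.vector(alpha), rep(delta_a, 2), phi, log = TRUE)) +
    sum(dnorm(delta_a, 0, 100, log = TRUE)) +
    2 * dunif(0.5, 0, 100, log = TRUE)
  expect_equal(log_joint(m, theta, d), expected, tolerance = 1e-10)
})

test_that("the sampler is deterministic given its seed", {
  d <- simulate_pools(make_design(2), params_spec2(), seed = 1)
  f1 <- fit_hier(d, model = 2, iter = 200, burnin = 200, seed = 99)
  f2 <- fit_hier(d, model = 2, iter = 200, burnin = 200, seed = 99)
  f3 <- fit_hier(d, model = 2, iter = 200, burnin = 200, seed = 100)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("scale draws respect the prior support and chains are clean", {
  d <- simulate_pools(default_design(), params_spec3(), seed = 5)
  f <- fit_hier(d, model = 3, iter = 500, burnin = 500, seed = 2)
  D <- do.call(rbind, f$draws)
  expect_true(all(is.finite(D)))
  for (sc in c("sigma", "omega", "phi")) {
    expect_true(all(D[, sc] > 0 & D[, sc] < 100))
  }
})

test_that("MCMC matches the conjugate normal-normal closed form", {
  # single design cell, scales pinned: the cell mean has a Gaussian
  # posterior with known moments (marginal prior var phi^2 + 10000)
  n <- 25L
  set.seed(8)
  d <- data.frame(
    age_group = "5-15", gender = "male", period = "2002/03",
    concentration = exp(rnorm(n, 3, 0.5)), pool_size = 100L,
    stringsAsFactors = FALSE
  )
  sigma <- 0.5; phi <- 2
  m <- build_model(2)
  fit <- sample_posterior(m, d, chains = 2, iter = 4000, burnin = 1000,
                          seed = 31, fixed = c(sigma = sigma, phi = phi))
  dd <- pooltrend:::as_pooled_data(d)
  v0 <- phi^2 + 10000
  prec <- n / sigma^2 + 1 / v0
  post_mean <- (sum(dd$log_concentration) / sigma^2) / prec
  post_sd <- 1 / sqrt(prec)
  draws <- unlist(lapply(fit$draws, function(x) x[, "alpha[1,1]"]))
  # Monte-Carlo se via batch means within chains
  bm <- unlist(lapply(fit$draws, function(x) {
    tapply(x[, "alpha[1,1]"], rep(1:20, each = nrow(x) / 20), mean)
  }))
  mcse <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse)
  expect_equal(sd(draws), post_sd, tolerance = 0.05)
  expect_true(all(fit$draws[[1]][, "sigma"] == sigma))
})

test_that("well-separated spec-2 parameters are recovered with coverage", {
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    alpha <- matrix(seq(1, 4.6, length.out = 10), 5, 2)
    d <- simulate_pools(default_design(),
                        hier_params(2, sigma = 0.3, alpha_ag = alpha),
                        seed = 600 + s)
    f <- fit_hier(d, model = 2, iter = 1500, burnin = 1500, seed = s)
    sm <- summary(f)
    rows <- grep("^alpha\\[", sm$parameter)
    truth <- as.vector(alpha)
    hits <- hits + sum(truth >= sm$lower[rows] & truth <= sm$upper[rows])
    total <- total + length(rows)
  }
  expect_gte(hits / total, 0.8)
})

test_that("the spec-1 posterior ignores gender labels entirely", {
  d <- simulate_pools(default_design(), params_spec1(), seed = 13)
  d_swapped <- d
  d_swapped$gender <- factor(
    ifelse(d$gender == "male", "female", "male"),
    levels = design_levels()$gender
  )
  f1 <- fit_hier(d, model = 1, iter = 300, burnin = 300, seed = 4)
  f2 <- fit_hier(d_swapped, model = 1, iter = 300, burnin = 300, seed = 4)
  expect_identical(f1$draws, f2$draws)
})

test_that("gelman_rubin flags non-mixing and passes iid chains", {
  fake <- function(ch1, ch2) {
    structure(list(draws = list(cbind(x = ch1), cbind(x = ch2))),
              class = "hier_fit")
  }
  set.seed(5)
  iid <- fake(rnorm(10000), rnorm(10000))
  gr <- gelman_rubin(iid)
  expect_gt(gr$psrf, 0.99)
  expect_lt(gr$psrf, 1.01)
  split <- fake(rnorm(500), rnorm(500) + 10)
  expect_gt(gelman_rubin(split)$psrf, 5)
  single <- structure(list(draws = list(cbind(x = rnorm(100)))),
                      class = "hier_fit")
  expect_error(gelman_rubin(single), "2 chains")
})

test_that("the PSRF agrees with coda's implementation", {
  set.seed(17)
  ch1 <- cbind(x = cumsum(rnorm(2000)) / 40 + rnorm(2000))
  ch2 <- cbind(x = cumsum(rnorm(2000)) / 40 + rnorm(2000) + 0.5)
  fake <- structure(list(draws = list(ch1, ch2)), class = "hier_fit")
  gr <- gelman_rubin(fake)
  ml <- coda::mcmc.list(coda::mcmc(ch1), coda::mcmc(ch2))
  cd <- coda::gelman.diag(ml, autoburnin = FALSE)
  expect_equal(gr$psrf, unname(cd$psrf[1, 1]), tolerance = 1e-8)
  expect_equal(gr$upper, unname(cd$psrf[1, 2]), tolerance = 1e-8)
})

test_that("a converged synthetic fit passes the PSRF threshold", {
  d <- simulate_pools(default_design(), params_spec1(), seed = 21)
  f <- fit_hier(d, model = 1, iter = 2000, burnin = 2000, seed = 6)
  expect_true(all(gelman_rubin(f)$psrf < 1.1))
})

test_that("the Gibbs sampler agrees with JAGS on a spec-2 fit", {
  d <- simulate_pools(default_design(), params_spec2(sigma = 0.3), seed = 41)
  mine <- fit_hier(d, model = 2, iter = 4000, burnin = 2000, seed = 3)
  model_str <- "
    model {
      for (i in 1:N) { y[i] ~ dnorm(alpha[a[i], g[i]], tau) }
      for (aa in 1:5) { for (gg in 1:2) { alpha[aa, gg] ~ dnorm(delta[aa], tauphi) } }
      for (aa in 1:5) { delta[aa] ~ dnorm(0, 1.0E-4) }
      sigma ~ dunif(0, 100); tau <- pow(sigma, -2)
      phi ~ dunif(0, 100); tauphi <- pow(phi, -2)
    }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = d$log_concentration, a = as.integer(d$age_group),
                g = as.integer(d$gender), N = nrow(d)),
    inits = list(
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)
    ),
    n.chains = 2, quiet = TRUE
  )
  update(jm, 2000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("alpha", "sigma"), 4000,
                            progress.bar = "none")
  jmean <- colMeans(as.matrix(js))
  alpha_mine <- coef(mine)[sprintf("alpha[%d,%d]", rep(1:5, 2), rep(1:2, each = 5))]
  alpha_jags <- jmean[sprintf("alpha[%d,%d]", rep(1:5, 2), rep(1:2, each = 5))]
  expect_equal(unname(alpha_mine), unname(alpha_jags), tolerance = 0.03)
  expect_equal(unname(coef(mine)["sigma"]), unname(jmean["sigma"]),
               tolerance = 0.03)
})

test_that("fit methods are mutually consistent", {
  d <- simulate_pools(make_design(3), params_spec3(), seed = 50)
  f <- fit_hier(d, model = 3, iter = 400, burnin = 400, seed = 1)
  expect_equal(residuals(f), d$log_concentration - fitted(f))
  pr <- predict(f)
  expect_equal(pr$fit, unname(fitted(f)))
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
  sims <- simulate(f, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(nrow(d), 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 2))
  expect_error(sample_posterior(build_model(2), d[0, ]), "no observations")
  expect_error(sample_posterior(build_model(2), d, fixed = c(alpha = 1)),
               "scale parameters")
})
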