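# Stage two: Bayesian hierarchical models for pooled log-concentrations,
# estimated by Gibbs sampling.
#
# Model 1:  y_agt ~ N(beta_at, sigma^2)
#           beta_at ~ N(beta_a(t-1), omega^2), beta_a0 ~ N(0, omega^2)
#           sigma, omega ~ U(0, 100)
#           (optionally y_agt ~ N(alpha_g + beta_at, sigma^2) with
#            alpha_g ~ N(0, 10000) when include_gender = TRUE)
# Model 2:  y_agt ~ N(alpha_ag, sigma^2), alpha_ag ~ N(delta_a, phi^2),
#           delta_a ~ N(0, 10000), sigma, phi ~ U(0, 100)
# Model 3:  y_agt ~ N(alpha_ag + beta_at, sigma^2),
#           alpha_ag ~ N(delta_g, phi^2), beta_at as in model 1,
#           delta_g ~ N(0, 10000), sigma, omega, phi ~ U(0, 100)
#
# Normal top-level priors are parameterised by variance 10000; uniform
# priors bound the standard deviations.

.PRIOR_VAR <- 10000
.SCALE_UPPER <- 100

#' Define a hierarchical model for pooled log-concentrations
#'
#' Builds the parameter and prior catalogue of one of the three model
#' structures (see \code{\link{fit_hier}} for the model equations).
#'
#' @param spec Integer 1, 2 or 3 selecting the mean structure.
#' @param n_age,n_gender,n_period Dimensions of the design grid.
#' @param include_gender Model 1 only: add a gender offset
#'   \code{alpha_g ~ N(0, 10000)} to the mean.  The default mean contains
#'   only the age-by-time random walk.
#' @return An object of class \code{"hier_model"} with the parameter
#'   catalogue (\code{$parameters}: name, role, lower, upper) and prior
#'   descriptions.
#' @export
build_model <- function(spec, n_age = 5L, n_gender = 2L, n_period = 5L,
                        include_gender = FALSE) {
  spec <- as.integer(spec)
  if (!isTRUE(spec %in% 1:3)) stop("model spec must be 1, 2 or 3")
  A <- as.integer(n_age); G <- as.integer(n_gender); Tn <- as.integer(n_period)
  if (A < 1L || G < 1L || Tn < 1L) stop("all dimensions must be >= 1")
  include_gender <- isTRUE(include_gender) && spec == 1L
  nm <- character(0); role <- character(0)
  add <- function(names, r) {
    nm <<- c(nm, names)
    role <<- c(role, rep(r, length(names)))
  }
  if (spec %in% c(1L, 3L)) {
    add(sprintf("beta0[%d]", seq_len(A)), "temporal_init")
    add(sprintf("beta[%d,%d]", rep(seq_len(A), Tn), rep(seq_len(Tn), each = A)),
        "temporal")
  }
  if (include_gender) add(sprintf("alpha_g[%d]", seq_len(G)), "gender_offset")
  if (spec %in% c(2L, 3L)) {
    add(sprintf("alpha[%d,%d]", rep(seq_len(A), G), rep(seq_len(G), each = A)),
        "age_gender")
  }
  if (spec == 2L) add(sprintf("delta_a[%d]", seq_len(A)), "age_mean")
  if (spec == 3L) add(sprintf("delta_g[%d]", seq_len(G)), "gender_mean")
  add("sigma", "scale")
  if (spec %in% c(1L, 3L)) add("omega", "scale")
  if (spec %in% c(2L, 3L)) add("phi", "scale")
  lower <- ifelse(role == "scale", 0, -Inf)
  upper <- ifelse(role == "scale", .SCALE_UPPER, Inf)
  priors <- c(
    if (spec %in% c(1L, 3L))
      c("beta[a,t] ~ N(beta[a,t-1], omega^2)", "beta0[a] ~ N(0, omega^2)"),
    if (include_gender) "alpha_g[g] ~ N(0, 10000)",
    if (spec == 2L) c("alpha[a,g] ~ N(delta_a[a], phi^2)", "delta_a[a] ~ N(0, 10000)"),
    if (spec == 3L) c("alpha[a,g] ~ N(delta_g[g], phi^2)", "delta_g[g] ~ N(0, 10000)"),
    "sigma ~ U(0, 100)",
    if (spec %in% c(1L, 3L)) "omega ~ U(0, 100)",
    if (spec %in% c(2L, 3L)) "phi ~ U(0, 100)"
  )
  structure(
    list(
      spec = spec, n_age = A, n_gender = G, n_period = Tn,
      include_gender = include_gender,
      parameters = data.frame(name = nm, role = role, lower = lower,
                              upper = upper, stringsAsFactors = FALSE),
      priors = priors
    ),
    class = "hier_model"
  )
}

#' @export
print.hier_model <- function(x, ...) {
  means <- c("beta[a,t]", "alpha_g[g] + beta[a,t]", "alpha[a,g]",
             "alpha[a,g] + beta[a,t]")
  mean_str <- switch(x$spec, if (x$include_gender) means[2] else means[1],
                     means[3], means[4])
  cat(sprintf("Hierarchical model %d: y[a,g,t] ~ N(%s, sigma^2)\n",
              x$spec, mean_str))
  cat(sprintf("  grid: %d age groups x %d genders x %d periods; %d parameters\n",
              x$n_age, x$n_gender, x$n_period, nrow(x$parameters)))
  cat("  priors:\n")
  for (p in x$priors) cat("    ", p, "\n", sep = "")
  invisible(x)
}

# Arrange a (named or catalogue-ordered) parameter vector into the model's
# blocks.
unpack_theta <- function(model, theta) {
  nm <- model$parameters$name
  if (!is.null(names(theta)) && !all(names(theta) == "")) {
    if (!all(nm %in% names(theta))) {
      stop("parameter vector is missing: ",
           paste(setdiff(nm, names(theta)), collapse = ", "))
    }
    theta <- theta[nm]
  } else if (length(theta) != length(nm)) {
    stop(sprintf("parameter vector has length %d but the model catalogue has %d entries",
                 length(theta), length(nm)))
  }
  A <- model$n_age; G <- model$n_gender; Tn <- model$n_period
  val <- function(keys) unname(theta[match(keys, nm)])
  out <- list(sigma = unname(theta[match("sigma", nm)]))
  if (model$spec %in% c(1L, 3L)) {
    out$beta0 <- val(sprintf("beta0[%d]", seq_len(A)))
    out$B <- matrix(val(sprintf("beta[%d,%d]", rep(seq_len(A), Tn),
                                rep(seq_len(Tn), each = A))), A, Tn)
    out$omega <- unname(theta[match("omega", nm)])
  }
  if (model$include_gender) {
    out$alpha_g <- val(sprintf("alpha_g[%d]", seq_len(G)))
  }
  if (model$spec %in% c(2L, 3L)) {
    out$alpha <- matrix(val(sprintf("alpha[%d,%d]", rep(seq_len(A), G),
                                    rep(seq_len(G), each = A))), A, G)
    out$phi <- unname(theta[match("phi", nm)])
  }
  if (model$spec == 2L) out$delta_a <- val(sprintf("delta_a[%d]", seq_len(A)))
  if (model$spec == 3L) out$delta_g <- val(sprintf("delta_g[%d]", seq_len(G)))
  out
}

# Mean of the log-concentration for observations with indices (a, g, t),
# given an unpacked parameter list.
mean_function <- function(model, p, a, g, t) {
  mu <- numeric(length(a))
  if (model$spec %in% c(1L, 3L)) mu <- mu + p$B[cbind(a, t)]
  if (model$include_gender) mu <- mu + p$alpha_g[g]
  if (model$spec %in% c(2L, 3L)) mu <- mu + p$alpha[cbind(a, g)]
  mu
}

#' Log-likelihood of pooled data under a hierarchical model
#'
#' Sum of normal log-densities of the observed log-concentrations around the
#' model's mean function with sd \code{sigma}.  Returns \code{-Inf} when
#' \code{sigma <= 0} (unless every residual is exactly zero).
#'
#' @param model A \code{\link{build_model}} object.
#' @param theta Parameter vector, named by or ordered as the model's
#'   catalogue.
#' @param data Pooled data frame.
#' @return A single number.
#' @export
log_lik <- function(model, theta, data) {
  data <- as_pooled_data(data)
  p <- unpack_theta(model, theta)
  a <- as.integer(data$age_group); g <- as.integer(data$gender); t <- data$t
  mu <- mean_function(model, p, a, g, t)
  r <- data$log_concentration - mu
  if (p$sigma <= 0) {
    return(if (all(r == 0)) Inf else -Inf)
  }
  sum(stats::dnorm(r, 0, p$sigma, log = TRUE))
}

#' Log joint density (likelihood plus priors)
#'
#' The unnormalised log posterior of a hierarchical model: the
#' \code{\link{log_lik}} term plus all log-priors, including the
#' random-walk chain terms.  Returns \code{-Inf} outside the prior support
#' (any scale parameter outside (0, 100)).
#'
#' @inheritParams log_lik
#' @return A single number.
#' @export
log_joint <- function(model, theta, data) {
  p <- unpack_theta(model, theta)
  scales <- c(p$sigma, p$omega, p$phi)
  if (any(scales <= 0 | scales >= .SCALE_UPPER)) return(-Inf)
  lp <- sum(stats::dunif(scales, 0, .SCALE_UPPER, log = TRUE))
  if (model$spec %in% c(1L, 3L)) {
    prev <- cbind(p$beta0, p$B[, -model$n_period, drop = FALSE])
    lp <- lp + sum(stats::dnorm(p$beta0, 0, p$omega, log = TRUE)) +
      sum(stats::dnorm(p$B, prev, p$omega, log = TRUE))
  }
  if (model$include_gender) {
    lp <- lp + sum(stats::dnorm(p$alpha_g, 0, sqrt(.PRIOR_VAR), log = TRUE))
  }
  if (model$spec == 2L) {
    lp <- lp + sum(stats::dnorm(p$alpha, matrix(p$delta_a, model$n_age,
                                                model$n_gender), p$phi, log = TRUE)) +
      sum(stats::dnorm(p$delta_a, 0, sqrt(.PRIOR_VAR), log = TRUE))
  }
  if (model$spec == 3L) {
    lp <- lp + sum(stats::dnorm(p$alpha, matrix(p$delta_g, model$n_age,
                                                model$n_gender, byrow = TRUE),
                                p$phi, log = TRUE)) +
      sum(stats::dnorm(p$delta_g, 0, sqrt(.PRIOR_VAR), log = TRUE))
  }
  ll <- log_lik(model, theta, data)
  ll + lp
}

#' Draw from the posterior of a hierarchical model by Gibbs sampling
#'
#' All mean parameters have conjugate normal full conditionals and are
#' updated in closed form; the scale parameters (uniform-prior standard
#' deviations) are updated exactly on the precision scale, where the full
#' conditional is a truncated Gamma.  Model 3 (and model 1 with a gender
#' offset) adds an ancillarity "sweep" move along the additive
#' level-vs-trend direction, which the priors only weakly identify, so the
#' chain mixes across that ridge.
#'
#' @param model A \code{\link{build_model}} object.
#' @param data Pooled data frame; design indices must fit the model's grid.
#' @param chains Number of chains (>= 2 recommended for diagnostics).
#' @param iter Post-burn-in iterations kept per chain.
#' @param burnin Burn-in iterations discarded per chain.
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @param seed Integer seed; identical inputs give identical draws.
#' @param fixed Optional named numeric vector pinning any of \code{sigma},
#'   \code{omega}, \code{phi} at known values (their updates are skipped).
#' @return An object of class \code{"hier_fit"}: the model, the data, and
#'   one draws matrix per chain (columns named by the parameter catalogue,
#'   post-burn-in only).
#' @export
sample_posterior <- function(model, data, chains = 2L, iter = 10000L,
                             burnin = 10000L, thin = 1L, seed = 1L,
                             fixed = NULL) {
  stopifnot(inherits(model, "hier_model"))
  data <- as_pooled_data(data)
  if (nrow(data) == 0L) stop("no observations to fit")
  if (iter < 1L || burnin < 0L) stop("iter must be >= 1 and burnin >= 0")
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), c("sigma", "omega", "phi"))
    if (length(bad)) stop("only scale parameters can be fixed, not: ",
                          paste(bad, collapse = ", "))
  }
  a <- as.integer(data$age_group); g <- as.integer(data$gender); t <- data$t
  A <- model$n_age; G <- model$n_gender; Tn <- model$n_period
  if (max(a) > A || max(g) > G || max(t) > Tn) {
    stop("data indices exceed the model's grid dimensions")
  }
  y <- data$log_concentration
  N <- length(y)
  code <- (t - 1L) * A * G + (g - 1L) * A + a
  n_agt <- array(tabulate(code, A * G * Tn), dim = c(A, G, Tn))
  sy <- numeric(A * G * Tn)
  sums <- rowsum(y, code)
  sy[as.integer(rownames(sums))] <- sums
  sum_y_agt <- array(sy, dim = c(A, G, Tn))
  n_at <- apply(n_agt, c(1, 3), sum)
  sum_y_at <- apply(sum_y_agt, c(1, 3), sum)
  n_ag <- apply(n_agt, c(1, 2), sum)
  sum_y_ag <- apply(sum_y_agt, c(1, 2), sum)
  n_g <- apply(n_agt, 2, sum)

  ybar <- mean(y)
  n_keep <- iter %/% thin
  par_names <- model$parameters$name

  run_chain <- function(chain_seed, mean_offset, scale_init) {
    set.seed(chain_seed)
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    sigma <- fixed["sigma"] %na% scale_init
    omega <- fixed["omega"] %na% scale_init
    phi <- fixed["phi"] %na% scale_init
    upd_sigma <- !("sigma" %in% names(fixed))
    upd_omega <- !("omega" %in% names(fixed))
    upd_phi <- !("phi" %in% names(fixed))
    B <- matrix(ybar + mean_offset, A, Tn)
    b0 <- rep(ybar + mean_offset, A)
    alpha_g <- rep(0, G)
    alpha <- matrix(if (model$spec == 3L) 0 else ybar + mean_offset, A, G)
    da <- rep(0, A)
    dg <- rep(0, G)
    total <- burnin + n_keep * thin
    kept <- 0L
    for (it in seq_len(total)) {
      if (model$spec == 1L) {
        if (model$include_gender) {
          prec_g <- n_g / sigma^2 + 1 / .PRIOR_VAR
          r_g <- vapply(seq_len(G),
                        function(gg) sum(sum_y_agt[, gg, ]) - sum(n_agt[, gg, ] * B),
                        0)
          alpha_g <- stats::rnorm(G, (r_g / sigma^2) / prec_g, 1 / sqrt(prec_g))
          C_at <- matrix(0, A, Tn)
          for (gg in seq_len(G)) C_at <- C_at + n_agt[, gg, ] * alpha_g[gg]
          r_at <- sum_y_at - C_at
        } else {
          r_at <- sum_y_at
        }
        upd <- update_rw(B, b0, r_at, n_at, sigma, omega, A, Tn)
        B <- upd$B; b0 <- upd$b0
        if (model$include_gender) {
          # sweep along the (alpha_g + beta) ridge
          prec_c <- A / omega^2 + G / .PRIOR_VAR
          mu_c <- (-sum(b0) / omega^2 + sum(alpha_g) / .PRIOR_VAR) / prec_c
          cs <- stats::rnorm(1L, mu_c, 1 / sqrt(prec_c))
          B <- B + cs; b0 <- b0 + cs; alpha_g <- alpha_g - cs
        }
        mu_obs <- B[cbind(a, t)] + if (model$include_gender) alpha_g[g] else 0
        if (upd_sigma) sigma <- draw_scale(sum((y - mu_obs)^2), N)
        if (upd_omega) {
          S <- sum(b0^2) + sum((B - cbind(b0, B[, -Tn, drop = FALSE]))^2)
          omega <- draw_scale(S, A + A * Tn)
        }
        state <- c(b0, as.vector(B),
                   if (model$include_gender) alpha_g, sigma, omega)
      } else if (model$spec == 2L) {
        prec <- n_ag / sigma^2 + 1 / phi^2
        mu <- (sum_y_ag / sigma^2 + matrix(da, A, G) / phi^2) / prec
        alpha <- matrix(stats::rnorm(A * G, mu, 1 / sqrt(prec)), A, G)
        prec_d <- G / phi^2 + 1 / .PRIOR_VAR
        da <- stats::rnorm(A, (rowSums(alpha) / phi^2) / prec_d, 1 / sqrt(prec_d))
        if (upd_sigma) {
          sigma <- draw_scale(sum((y - alpha[cbind(a, g)])^2), N)
        }
        if (upd_phi) {
          phi <- draw_scale(sum((alpha - da)^2), A * G)
        }
        state <- c(as.vector(alpha), da, sigma, phi)
      } else {
        CB <- matrix(0, A, G)
        for (tt in seq_len(Tn)) CB <- CB + n_agt[, , tt] * B[, tt]
        r_ag <- sum_y_ag - CB
        prec <- n_ag / sigma^2 + 1 / phi^2
        mu <- (r_ag / sigma^2 + matrix(dg, A, G, byrow = TRUE) / phi^2) / prec
        alpha <- matrix(stats::rnorm(A * G, mu, 1 / sqrt(prec)), A, G)
        C_at <- matrix(0, A, Tn)
        for (tt in seq_len(Tn)) C_at[, tt] <- rowSums(n_agt[, , tt] * alpha)
        r_at <- sum_y_at - C_at
        upd <- update_rw(B, b0, r_at, n_at, sigma, omega, A, Tn)
        B <- upd$B; b0 <- upd$b0
        prec_g <- A / phi^2 + 1 / .PRIOR_VAR
        dg <- stats::rnorm(G, (colSums(alpha) / phi^2) / prec_g, 1 / sqrt(prec_g))
        # per-age sweep along the (alpha + beta) ridge
        dgm <- matrix(dg, A, G, byrow = TRUE)
        prec_c <- 1 / omega^2 + G / phi^2
        mu_c <- (-b0 / omega^2 + rowSums(alpha - dgm) / phi^2) / prec_c
        cs <- stats::rnorm(A, mu_c, 1 / sqrt(prec_c))
        B <- B + cs; b0 <- b0 + cs; alpha <- alpha - cs
        mu_obs <- alpha[cbind(a, g)] + B[cbind(a, t)]
        if (upd_sigma) sigma <- draw_scale(sum((y - mu_obs)^2), N)
        if (upd_omega) {
          S <- sum(b0^2) + sum((B - cbind(b0, B[, -Tn, drop = FALSE]))^2)
          omega <- draw_scale(S, A + A * Tn)
        }
        if (upd_phi) {
          dgm <- matrix(dg, A, G, byrow = TRUE)
          phi <- draw_scale(sum((alpha - dgm)^2), A * G)
        }
        state <- c(b0, as.vector(B), as.vector(alpha), dg, sigma, omega, phi)
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- state
      }
    }
    draws
  }

  with_seed(seed, {
    chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
    offsets <- rep_len(c(0, 1, -1, 2, -2), chains)
    scale_inits <- rep_len(c(1, 5, 0.5, 2, 0.2), chains)
    draw_list <- lapply(seq_len(chains), function(cc) {
      run_chain(chain_seeds[cc], offsets[cc], scale_inits[cc])
    })
    structure(
      list(model = model, data = data, draws = draw_list,
           chains = as.integer(chains), iter = as.integer(iter),
           burnin = as.integer(burnin), thin = as.integer(thin),
           seed = seed, fixed = fixed),
      class = "hier_fit"
    )
  })
}

# Conjugate update of the age-specific random walk given residual totals
# r_at (A x Tn) and per-cell counts n_at.
update_rw <- function(B, b0, r_at, n_at, sigma, omega, A, Tn) {
  for (tt in seq_len(Tn)) {
    prev <- if (tt == 1L) b0 else B[, tt - 1L]
    if (tt < Tn) {
      prec <- n_at[, tt] / sigma^2 + 2 / omega^2
      mu <- (r_at[, tt] / sigma^2 + (prev + B[, tt + 1L]) / omega^2) / prec
    } else {
      prec <- n_at[, tt] / sigma^2 + 1 / omega^2
      mu <- (r_at[, tt] / sigma^2 + prev / omega^2) / prec
    }
    B[, tt] <- stats::rnorm(A, mu, 1 / sqrt(prec))
  }
  b0 <- stats::rnorm(A, B[, 1L] / 2, omega / sqrt(2))
  list(B = B, b0 = b0)
}

# `fixed["sigma"] %na% default`: use the fixed value when present.
`%na%` <- function(a, b) if (length(a) == 1L && !is.na(a)) unname(a) else b

#' Fit a hierarchical model to pooled data
#'
#' Convenience wrapper: builds the model for the canonical 5 x 2 x 5 design
#' grid and samples its posterior.  See \code{\link{build_model}} and
#' \code{\link{sample_posterior}}.
#'
#' @param data Pooled data frame.
#' @param model Integer 1, 2 or 3.
#' @param ... Passed to \code{\link{sample_posterior}} (\code{chains},
#'   \code{iter}, \code{burnin}, \code{thin}, \code{seed}, \code{fixed}).
#' @param include_gender Model 1 only: add a gender offset to the mean.
#' @return A \code{"hier_fit"} object.
#' @examples
#' p <- hier_params(2, sigma = 0.4, alpha_ag = matrix(seq(2, 4, length = 10), 5, 2))
#' d <- simulate_pools(default_design(), p, seed = 1)
#' f <- fit_hier(d, model = 2, iter = 500, burnin = 500, seed = 1)
#' coef(f)[c("sigma", "phi")]
#' @export
fit_hier <- function(data, model = 3L, include_gender = FALSE, ...) {
  m <- build_model(model, include_gender = include_gender)
  sample_posterior(m, data, ...)
}

# Stacked post-burn-in draws over all chains (S x P matrix).
posterior_matrix <- function(fit) {
  do.call(rbind, fit$draws)
}

# Draws of the model mean for cells (a, g, t): an S x n matrix.
mu_draws <- function(fit, a, g, t) {
  D <- posterior_matrix(fit)
  model <- fit$model
  M <- matrix(0, nrow(D), length(a))
  if (model$spec %in% c(1L, 3L)) {
    M <- M + D[, sprintf("beta[%d,%d]", a, t), drop = FALSE]
  }
  if (model$include_gender) {
    M <- M + D[, sprintf("alpha_g[%d]", g), drop = FALSE]
  }
  if (model$spec %in% c(2L, 3L)) {
    M <- M + D[, sprintf("alpha[%d,%d]", a, g), drop = FALSE]
  }
  unname(M)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter from the between- and
#' within-chain variances of the stored (post-burn-in) draws, with the
#' degrees-of-freedom-adjusted point estimate and 97.5% upper bound.
#' Values close to 1 indicate convergence; the package's working threshold
#' is 1.1.
#'
#' @param fit A \code{\link{sample_posterior}} fit with >= 2 chains.
#' @return Data frame with columns \code{parameter}, \code{psrf},
#'   \code{upper}.
#' @export
gelman_rubin <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  m <- length(fit$draws)
  if (m < 2L) stop("the Gelman-Rubin diagnostic needs at least 2 chains")
  n <- nrow(fit$draws[[1]])
  pars <- colnames(fit$draws[[1]])
  res <- t(vapply(pars, function(p) {
    xs <- vapply(fit$draws, function(d) d[, p], numeric(n))
    psrf_one(xs)
  }, c(psrf = 0, upper = 0)))
  data.frame(parameter = pars, psrf = res[, 1], upper = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

# PSRF for one parameter; xs is an n x m matrix (iterations x chains).
psrf_one <- function(xs) {
  n <- nrow(xs); m <- ncol(xs)
  S2 <- apply(xs, 2, stats::var)
  xbar <- colMeans(xs)
  W <- mean(S2)
  B <- n * stats::var(xbar)
  if (!is.finite(W) || W <= 0) return(c(psrf = NA_real_, upper = NA_real_))
  muhat <- mean(xbar)
  V <- (n - 1) * W / n + (1 + 1 / m) * B / n
  var_w <- stats::var(S2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(S2, xbar^2) - 2 * muhat * stats::cov(S2, xbar))
  var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
              2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
  df_V <- 2 * V^2 / var_V
  df_adj <- (df_V + 3) / (df_V + 1)
  R2_fixed <- (n - 1) / n
  R2_random <- (1 + 1 / m) * B / (n * W)
  psrf <- sqrt(df_adj * (R2_fixed + R2_random))
  upper <- if (is.finite(var_w) && var_w > 0) {
    sqrt(df_adj * (R2_fixed +
                     stats::qf(0.975, m - 1, 2 * W^2 / var_w) * R2_random))
  } else {
    NA_real_
  }
  c(psrf = psrf, upper = upper)
}
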