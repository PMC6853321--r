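# Model assessment: posterior predictive interval coverage, DIC and RMSE.

# Predictive draws for every fitted observation: the posterior draws of the
# cell mean plus observation noise, replicated so at least `min_draws`
# predictive samples back each observation's interval.
predictive_draws <- function(fit, seed = 1L, min_draws = 2000L) {
  nd <- fit$data
  M <- mu_draws(fit, as.integer(nd$age_group), as.integer(nd$gender), nd$t)
  sig <- posterior_matrix(fit)[, "sigma"]
  S <- nrow(M)
  K <- max(1L, ceiling(min_draws / S))
  with_seed(seed, {
    out <- matrix(NA_real_, S * K, ncol(M))
    for (k in seq_len(K)) {
      noise <- matrix(stats::rnorm(S * ncol(M), sd = rep(sig, ncol(M))), S, ncol(M))
      out[(k - 1L) * S + seq_len(S), ] <- M + noise
    }
    out
  })
}

#' Posterior predictive interval coverage
#'
#' For each fitted observation, forms the central (1 - alpha) posterior
#' predictive interval (cell-mean draws plus Normal(0, sigma) observation
#' noise, empirical quantiles over at least 2000 predictive draws) and
#' returns the percentage of observations falling inside their own
#' intervals.  An adequate model attains roughly 100 * (1 - alpha).
#'
#' @param fit A \code{\link{sample_posterior}} fit.
#' @param alpha Significance level in (0, 1); the study levels are 0.2, 0.1
#'   and 0.05.
#' @param seed Seed for the predictive noise.
#' @return Coverage percentage in [0, 100].
#' @export
pi_coverage <- function(fit, alpha = 0.2, seed = 1L) {
  stopifnot(inherits(fit, "hier_fit"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  P <- predictive_draws(fit, seed = seed)
  y <- fit$data$log_concentration
  qs <- apply(P, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  100 * mean(y >= qs[1, ] & y <= qs[2, ])
}

#' Deviance information criterion
#'
#' Conditional DIC of a fitted hierarchical model:
#' \code{d_bar} is the posterior mean of the deviance \code{-2 log p(y |
#' theta)} (likelihood conditioned on the lowest-level parameters),
#' \code{d_at_mean} the deviance at the posterior mean of all parameters,
#' \code{p_d = d_bar - d_at_mean} the effective number of parameters, and
#' \code{dic = d_at_mean + 2 p_d}.
#'
#' @param fit A \code{\link{sample_posterior}} fit.
#' @return List with \code{dic}, \code{p_d}, \code{d_bar},
#'   \code{d_at_mean}.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  nd <- fit$data
  y <- nd$log_concentration
  N <- length(y)
  M <- mu_draws(fit, as.integer(nd$age_group), as.integer(nd$gender), nd$t)
  D <- posterior_matrix(fit)
  sig <- D[, "sigma"]
  resid2 <- rowSums((matrix(y, nrow(M), N, byrow = TRUE) - M)^2)
  ll <- -0.5 * N * log(2 * pi) - N * log(sig) - resid2 / (2 * sig^2)
  d_bar <- mean(-2 * ll)
  theta_star <- colMeans(D)
  d_at_mean <- -2 * log_lik(fit$model, theta_star, nd)
  p_d <- d_bar - d_at_mean
  if (is.finite(p_d) && p_d < -1e-8) {
    warning(sprintf("negative effective number of parameters (p_d = %.3g); the chains may not have mixed", p_d))
  }
  list(dic = d_at_mean + 2 * p_d, p_d = p_d, d_bar = d_bar,
       d_at_mean = d_at_mean)
}

#' Root mean squared error of a hierarchical fit
#'
#' \code{sqrt(mean((y - yhat)^2))} with \code{yhat} the posterior-mean
#' fitted value of each observation, on the log-concentration scale.
#'
#' @param fit A \code{\link{sample_posterior}} fit.
#' @return A single non-negative number.
#' @export
model_rmse <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  if (nrow(fit$data) == 0L) stop("no observations")
  sqrt(mean(residuals(fit)^2))
}

#' Assemble the assessment report of one fit
#'
#' One row of the model-diagnostics table: predictive-interval coverage at
#' the three study levels, DIC with its components, RMSE, and the posterior
#' mean of sigma with a central 95% credible interval.
#'
#' @param fit A \code{\link{sample_posterior}} fit.
#' @param alphas Significance levels for the predictive intervals.
#' @param seed Seed for the predictive noise (shared across levels so the
#'   intervals nest).
#' @return An object of class \code{"hier_assessment"}.
#' @export
assess <- function(fit, alphas = c(0.2, 0.1, 0.05), seed = 1L) {
  stopifnot(inherits(fit, "hier_fit"))
  cov <- vapply(alphas, function(al) pi_coverage(fit, al, seed = seed), 0)
  names(cov) <- sprintf("%g%%", 100 * (1 - alphas))
  ic <- dic(fit)
  sig <- posterior_matrix(fit)[, "sigma"]
  structure(
    list(
      model = fit$model$spec,
      pi_coverage = cov,
      dic = ic$dic, p_d = ic$p_d, d_bar = ic$d_bar, d_at_mean = ic$d_at_mean,
      rmse = model_rmse(fit),
      sigma_mean = mean(sig),
      sigma_lower = unname(stats::quantile(sig, 0.025)),
      sigma_upper = unname(stats::quantile(sig, 0.975))
    ),
    class = "hier_assessment"
  )
}

#' @export
print.hier_assessment <- function(x, ...) {
  cat(sprintf("Model %d assessment\n", x$model))
  cat("  PI coverage:",
      paste(sprintf("%s: %.2f%%", names(x$pi_coverage), x$pi_coverage),
            collapse = ", "), "\n")
  cat(sprintf("  DIC %.2f (p_d %.2f, mean deviance %.2f)\n",
              x$dic, x$p_d, x$d_bar))
  cat(sprintf("  RMSE %.3f; sigma %.3g (%.3g, %.3g)\n",
              x$rmse, x$sigma_mean, x$sigma_lower, x$sigma_upper))
  invisible(x)
}

#' Rank assessed models
#'
#' Ranks assessment reports by DIC (smaller is better); RMSE and the
#' distance of the predictive-interval coverages from their nominal levels
#' are reported alongside, not aggregated.  Equal DICs share a rank and are
#' flagged as ties.
#'
#' @param reports List of \code{\link{assess}} objects (>= 2).
#' @return Data frame ordered by rank.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2L) stop("need at least two assessment reports")
  stopifnot(all(vapply(reports, inherits, TRUE, "hier_assessment")))
  dics <- vapply(reports, function(r) r$dic, 0)
  out <- data.frame(
    model = vapply(reports, function(r) r$model, 0L),
    dic = dics,
    rmse = vapply(reports, function(r) r$rmse, 0),
    pi_deviation = vapply(reports, function(r) {
      nominal <- as.numeric(sub("%", "", names(r$pi_coverage)))
      mean(abs(r$pi_coverage - nominal))
    }, 0),
    rank = rank(dics, ties.method = "min"),
    stringsAsFactors = FALSE
  )
  out$tie <- duplicated(out$dic) | duplicated(out$dic, fromLast = TRUE)
  out[order(out$rank), , drop = FALSE]
}
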