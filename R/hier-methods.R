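# Methods for fitted hierarchical models.

#' @export
print.hier_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("Posterior: %d chains x %d kept iterations (burn-in %d, thin %d), seed %s\n",
              x$chains, nrow(x$draws[[1]]), x$burnin, x$thin, format(x$seed)))
  cat(sprintf("Data: %d pooled observations\n", nrow(x$data)))
  invisible(x)
}

#' @export
coef.hier_fit <- function(object, ...) {
  colMeans(posterior_matrix(object))
}

#' Posterior summary of a hierarchical fit
#'
#' @param object A \code{\link{sample_posterior}} fit.
#' @param prob Central credible-interval probability.
#' @param ... Unused.
#' @return Data frame with posterior mean, sd, interval bounds and the
#'   Gelman-Rubin PSRF per parameter.
#' @export
summary.hier_fit <- function(object, prob = 0.95, ...) {
  D <- posterior_matrix(object)
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  qmat <- t(apply(D, 2, stats::quantile, probs = qs))
  out <- data.frame(
    parameter = colnames(D),
    mean = colMeans(D),
    sd = apply(D, 2, stats::sd),
    lower = qmat[, 1],
    upper = qmat[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (length(object$draws) >= 2L) {
    out$psrf <- gelman_rubin(object)$psrf
  }
  class(out) <- c("summary.hier_fit", "data.frame")
  attr(out, "prob") <- prob
  out
}

#' @export
print.summary.hier_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior summary (central %g%% intervals):\n",
              100 * attr(x, "prob")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Posterior mean (and interval) of the cell mean
#'
#' Evaluates the model's mean function per posterior draw at the design
#' cells of \code{newdata} (default: the fitted data) and summarises it.
#'
#' @param object A \code{"hier_fit"}.
#' @param newdata Data frame with \code{age_group}, \code{gender},
#'   \code{period} columns; defaults to the fitted data.
#' @param prob Central credible-interval probability.
#' @param ... Unused.
#' @return Data frame with \code{fit}, \code{lwr}, \code{upr} per row of
#'   \code{newdata}, on the log-concentration scale.
#' @export
predict.hier_fit <- function(object, newdata = NULL, prob = 0.95, ...) {
  nd <- if (is.null(newdata)) object$data else as_pooled_data(newdata)
  M <- mu_draws(object, as.integer(nd$age_group), as.integer(nd$gender), nd$t)
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  qmat <- apply(M, 2, stats::quantile, probs = qs)
  data.frame(fit = colMeans(M), lwr = qmat[1, ], upr = qmat[2, ])
}

#' @export
fitted.hier_fit <- function(object, ...) {
  nd <- object$data
  colMeans(mu_draws(object, as.integer(nd$age_group),
                    as.integer(nd$gender), nd$t))
}

#' @export
residuals.hier_fit <- function(object, ...) {
  object$data$log_concentration - fitted(object)
}

#' Posterior predictive datasets from a hierarchical fit
#'
#' Draws \code{nsim} replicated datasets at the fitted design: for each
#' replicate one posterior draw is selected and each observation is redrawn
#' from Normal(cell mean, sigma) under that draw.
#'
#' @param object A \code{"hier_fit"}.
#' @param nsim Number of replicated datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame with one column of simulated log-concentrations per
#'   replicate, rows aligned with the fitted data.
#' @export
simulate.hier_fit <- function(object, nsim = 1, seed = 1L, ...) {
  nd <- object$data
  M <- mu_draws(object, as.integer(nd$age_group), as.integer(nd$gender), nd$t)
  sig <- posterior_matrix(object)[, "sigma"]
  with_seed(seed, {
    pick <- sample.int(nrow(M), nsim, replace = nsim > nrow(M))
    out <- vapply(pick, function(s) {
      stats::rnorm(ncol(M), M[s, ], sig[s])
    }, numeric(ncol(M)))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Plot posterior trajectories of a hierarchical fit
#'
#' Posterior mean log-concentration per age group over the collection
#' periods with central 95% credible bands (one panel layout, one line per
#' age group; solid/dashed by gender when the model mean involves gender).
#'
#' @param x A \code{"hier_fit"}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.hier_fit <- function(x, ...) {
  tr <- trajectories(x)
  lv <- design_levels()
  has_gender <- x$model$spec %in% c(2L, 3L) || x$model$include_gender
  genders <- if (has_gender) lv$gender else lv$gender[1]
  cols <- grDevices::hcl.colors(length(lv$age_group), "Dark 3")
  ylim <- range(tr$lwr, tr$upr)
  graphics::plot(NA, xlim = c(1, length(lv$period)), ylim = ylim,
                 xaxt = "n", xlab = "collection period",
                 ylab = "posterior mean log-concentration", ...)
  graphics::axis(1, at = seq_along(lv$period), labels = lv$period)
  for (ai in seq_along(lv$age_group)) {
    for (gi in seq_along(genders)) {
      sub <- tr[tr$age_group == lv$age_group[ai] & tr$gender == genders[gi], ]
      graphics::polygon(c(sub$t, rev(sub$t)), c(sub$lwr, rev(sub$upr)),
                        col = grDevices::adjustcolor(cols[ai], alpha.f = 0.15),
                        border = NA)
      graphics::lines(sub$t, sub$mean, col = cols[ai], lty = gi)
    }
  }
  graphics::legend("topright", legend = lv$age_group, col = cols, lty = 1,
                   bty = "n", title = "age group")
  invisible(x)
}
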