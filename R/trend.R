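# Posterior trend summaries: trajectories, percent changes between
# collection periods, cohort extrapolation, and the subsampling
# sensitivity assessment.

stop_no_time <- function() {
  stop(errorCondition(
    paste("time is not in the model mean (model 2); temporal change",
          "analyses apply to models 1 and 3 only"),
    class = c("pooltrend_time_not_in_model", "error", "condition")
  ))
}

#' Posterior trajectories of cell means
#'
#' Posterior mean and central credible interval of the model's fitted
#' log-concentration for every (age group, gender, period) cell.  For model
#' 1 (no gender in the mean) both genders carry identical values.
#'
#' @param fit A \code{\link{sample_posterior}} fit.
#' @param prob Central credible-interval probability.
#' @return Data frame with one row per design cell: \code{age_group},
#'   \code{gender}, \code{period}, \code{t}, \code{mean}, \code{lwr},
#'   \code{upr}.
#' @export
trajectories <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "hier_fit"))
  lv <- design_levels()
  grid <- expand.grid(a = 1:5, g = 1:2, t = 1:5, KEEP.OUT.ATTRS = FALSE)
  M <- mu_draws(fit, grid$a, grid$g, grid$t)
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  qmat <- apply(M, 2, stats::quantile, probs = qs)
  data.frame(
    age_group = factor(lv$age_group[grid$a], levels = lv$age_group),
    gender = factor(lv$gender[grid$g], levels = lv$gender),
    period = factor(lv$period[grid$t], levels = lv$period),
    t = grid$t,
    mean = colMeans(M),
    lwr = qmat[1, ],
    upr = qmat[2, ],
    stringsAsFactors = FALSE
  )
}

# Draws of the log-scale cell mean used by the change analyses: the
# age-by-period trend for one age group.  alpha[a,g] cancels in
# within-age period contrasts, so gender does not enter; for cohort
# contrasts (different age groups) see cohort_changes().
change_mu_draws <- function(fit, a, t, gender = NULL) {
  if (fit$model$spec == 2L) stop_no_time()
  if (is.null(gender)) {
    if (fit$model$spec == 3L) {
      # average the cell means over genders, per draw, on the log scale
      (mu_draws(fit, a, rep(1L, length(a)), t) +
         mu_draws(fit, a, rep(2L, length(a)), t)) / 2
    } else {
      mu_draws(fit, a, rep(1L, length(a)), t)
    }
  } else {
    gi <- match(gender, design_levels()$gender)
    if (is.na(gi)) stop("unknown gender label: ", gender)
    mu_draws(fit, a, rep(gi, length(a)), t)
  }
}

summarise_change <- function(age_label, comparison, draws) {
  out <- data.frame(
    age_group = age_label,
    comparison = comparison,
    percent_change = mean(draws),
    lwr = unname(stats::quantile(draws, 0.025)),
    upr = unname(stats::quantile(draws, 0.975)),
    stringsAsFactors = FALSE
  )
  attr(out, "draws") <- draws
  class(out) <- c("change_summary", "data.frame")
  out
}

#' Percent change in concentration between two periods
#'
#' Draw-wise percent change of the modelled concentration of one age group
#' between two collection periods, computed on the natural-concentration
#' scale: \code{100 * (exp(m_to) - exp(m_from)) / exp(m_from)} per posterior
#' draw, then summarised by the posterior mean and central 95% interval.
#' Within an age group the age-by-gender level cancels in the ratio, so the
#' change is common to both genders.  Model 2 has no time term and raises a
#' \code{pooltrend_time_not_in_model} error.
#'
#' @param fit A \code{\link{sample_posterior}} fit of model 1 or 3.
#' @param age_group Age-group label, e.g. \code{"46-60"}.
#' @param from_period,to_period Period labels, e.g. \code{"2002/03"}.
#' @return A one-row \code{change_summary} data frame (with the draws in
#'   the \code{"draws"} attribute).
#' @export
percent_change <- function(fit, age_group, from_period, to_period) {
  stopifnot(inherits(fit, "hier_fit"))
  lv <- design_levels()
  a <- match(age_group, lv$age_group)
  t1 <- match(from_period, lv$period)
  t2 <- match(to_period, lv$period)
  if (is.na(a)) stop("unknown age group label: ", age_group)
  if (is.na(t1) || is.na(t2)) stop("unknown period label")
  M <- change_mu_draws(fit, c(a, a), c(t1, t2))
  pc <- 100 * (exp(M[, 2] - M[, 1]) - 1)
  summarise_change(age_group, paste(from_period, "→", to_period), pc)
}

#' Percent changes between consecutive collection periods
#'
#' \code{\link{percent_change}} applied to every adjacent period pair for
#' every age group (4 comparisons x 5 age groups), in study order.
#'
#' @param fit A \code{\link{sample_posterior}} fit of model 1 or 3.
#' @return Data frame of 20 change summaries; the per-row draws are kept in
#'   the \code{"draws"} attribute (a list).
#' @export
consecutive_changes <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  if (fit$model$spec == 2L) stop_no_time()
  lv <- design_levels()
  rows <- list()
  draws <- list()
  for (ag in lv$age_group) {
    for (tt in seq_len(length(lv$period) - 1L)) {
      cs <- percent_change(fit, ag, lv$period[tt], lv$period[tt + 1L])
      rows[[length(rows) + 1L]] <- cs
      draws[[length(draws) + 1L]] <- attr(cs, "draws")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  out
}

#' Cohort-extrapolated percent changes
#'
#' Compares each age group at the first collection period (2002/03) with the
#' adjacent older age group at the last period (2012/13), approximately
#' tracking a birth cohort as it ages through the 10-year study span: four
#' comparisons for five age groups.  For model 3 the age-by-gender level
#' does not cancel across age groups; by default the log-scale cell means
#' are averaged over genders per draw, or supply \code{gender} for a
#' gender-specific contrast.
#'
#' @param fit A \code{\link{sample_posterior}} fit of model 1 or 3.
#' @param gender Optional gender label (model 3).
#' @return Data frame of 4 change summaries (draws kept as for
#'   \code{\link{consecutive_changes}}).
#' @export
cohort_changes <- function(fit, gender = NULL) {
  stopifnot(inherits(fit, "hier_fit"))
  if (fit$model$spec == 2L) stop_no_time()
  lv <- design_levels()
  nA <- length(lv$age_group)
  t1 <- 1L
  t2 <- length(lv$period)
  rows <- list()
  draws <- list()
  for (a in seq_len(nA - 1L)) {
    M <- change_mu_draws(fit, c(a, a + 1L), c(t1, t2), gender = gender)
    pc <- 100 * (exp(M[, 2] - M[, 1]) - 1)
    cmp <- sprintf("%s @ %s → %s @ %s", lv$age_group[a], lv$period[t1],
                   lv$age_group[a + 1L], lv$period[t2])
    cs <- summarise_change(lv$age_group[a], cmp, pc)
    rows[[a]] <- cs
    draws[[a]] <- pc
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  out
}

#' Sensitivity of the posterior to the oversampled 2006/07 children's cell
#'
#' The 5-15 age group in 2006/07 holds far more pools than any other cell.
#' This procedure randomly retains \code{n_keep_per_gender} pools per gender
#' in that cell (all other cells untouched), refits the requested models on
#' the full and the reduced data, and pairs the posterior mean and sd of
#' every cell mean across the two fits.
#'
#' @param data Pooled data frame.
#' @param target_age,target_period Labels of the oversampled cell.
#' @param n_keep_per_gender Pools retained per gender in the target cell.
#' @param seed Seed for the subsampling and the refits.
#' @param models Model specs to refit (default all three).
#' @param chains,iter,burnin MCMC settings for the refits.
#' @return An object of class \code{"sensitivity_report"}: the reduced data
#'   (\code{$data}) and a comparison data frame (\code{$comparison}) with
#'   the full-data and reduced-data posterior mean and sd per model and
#'   design cell.
#' @export
sensitivity_subsample <- function(data, target_age = "5-15",
                                  target_period = "2006/07",
                                  n_keep_per_gender = 4L, seed = 1L,
                                  models = 1:3, chains = 2L, iter = 2000L,
                                  burnin = 2000L) {
  data <- as_pooled_data(data)
  in_cell <- data$age_group == target_age & data$period == target_period
  keep <- rep(TRUE, nrow(data))
  with_seed(seed, {
    for (gl in design_levels()$gender) {
      ids <- which(in_cell & data$gender == gl)
      if (length(ids) < n_keep_per_gender) {
        stop(sprintf("cell (%s, %s, %s) has %d pools, fewer than n_keep_per_gender = %d",
                     target_age, gl, target_period, length(ids),
                     n_keep_per_gender))
      }
      drop <- setdiff(ids, ids[sample.int(length(ids))][seq_len(n_keep_per_gender)])
      keep[drop] <- FALSE
    }
  })
  reduced <- data[keep, , drop = FALSE]
  rownames(reduced) <- NULL
  comparison <- NULL
  for (spec in models) {
    f_full <- fit_hier(data, model = spec, chains = chains, iter = iter,
                       burnin = burnin, seed = seed)
    f_red <- fit_hier(reduced, model = spec, chains = chains, iter = iter,
                      burnin = burnin, seed = seed)
    tr_full <- trajectories(f_full)
    tr_red <- trajectories(f_red)
    grid <- expand.grid(a = 1:5, g = 1:2, t = 1:5, KEEP.OUT.ATTRS = FALSE)
    M_full <- mu_draws(f_full, grid$a, grid$g, grid$t)
    M_red <- mu_draws(f_red, grid$a, grid$g, grid$t)
    cmp <- data.frame(
      model = spec,
      age_group = tr_full$age_group,
      gender = tr_full$gender,
      period = tr_full$period,
      mean_full = tr_full$mean,
      mean_reduced = tr_red$mean,
      sd_full = apply(M_full, 2, stats::sd),
      sd_reduced = apply(M_red, 2, stats::sd),
      stringsAsFactors = FALSE
    )
    comparison <- rbind(comparison, cmp)
  }
  structure(
    list(data = reduced, comparison = comparison,
         n_dropped = sum(!keep), seed = seed),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity subsampling: %d pools dropped (seed %s)\n",
              x$n_dropped, format(x$seed)))
  if (!is.null(x$comparison)) {
    d <- abs(x$comparison$mean_full - x$comparison$mean_reduced)
    cat(sprintf("  max |posterior-mean shift| = %.4f (median posterior sd %.4f)\n",
                max(d), stats::median(x$comparison$sd_full)))
  }
  invisible(x)
}
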