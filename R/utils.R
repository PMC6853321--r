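# Internal helpers shared across the package.

# Fixed factor levels of the pooled-serum study design.
.AGE_LEVELS <- c("5-15", "16-30", "31-45", "46-60", ">60")
.GENDER_LEVELS <- c("male", "female")
.PERIOD_LEVELS <- c("2002/03", "2006/07", "2008/09", "2010/11", "2012/13")
.PREDICTORS <- c("age_group", "gender", "period")

#' Factor levels of the pooled-sample design
#'
#' The fixed labels used throughout the package for the three design
#' factors: five age groups, two genders and five collection periods.
#' Periods map to the integer time index \code{t = 1..5} in the order given.
#'
#' @return Named list with character vectors \code{age_group},
#'   \code{gender} and \code{period}.
#' @export
design_levels <- function() {
  list(age_group = .AGE_LEVELS, gender = .GENDER_LEVELS, period = .PERIOD_LEVELS)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards.  All randomness in the package flows through this.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Draw a scale parameter s with conditional density
#   p(s) propto s^-n exp(-S / (2 s^2)),  0 < s < upper,
# i.e. the full conditional of a normal sd with n attached residual terms
# (residual sum of squares S) under a Uniform(0, upper) prior.  Sampled
# exactly on the precision scale, where the conditional is a Gamma
# truncated to tau > upper^-2.
draw_scale <- function(S, n, upper = 100) {
  shape <- (n - 1) / 2
  rate <- S / 2
  if (shape <= 0 || rate <= 0 || !is.finite(rate)) {
    # degenerate conditional (no residual information); fall back to the prior
    return(stats::runif(1L, 0, upper))
  }
  lo <- stats::pgamma(upper^-2, shape, rate)
  u <- stats::runif(1L, lo, 1)
  tau <- stats::qgamma(min(u, 1 - 1e-16), shape, rate)
  1 / sqrt(max(tau, upper^-2))
}

# Coerce the design-factor columns of a pooled data frame to the canonical
# factors and add t / log_concentration if absent.  Validates labels.
as_pooled_data <- function(data) {
  need <- c("age_group", "gender", "period")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("pooled data is missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in need) {
    lv <- design_levels()[[col]]
    vals <- as.character(data[[col]])
    bad <- which(!vals %in% lv)
    if (length(bad) > 0) {
      stop(sprintf("unknown %s label '%s' in row %d", col, vals[bad[1]], bad[1]))
    }
    data[[col]] <- factor(vals, levels = lv)
  }
  data$t <- as.integer(data$period)
  if (is.null(data$log_concentration)) {
    if (is.null(data$concentration)) {
      stop("pooled data needs a 'concentration' or 'log_concentration' column")
    }
    if (any(data$concentration <= 0)) {
      stop("concentrations must be positive")
    }
    data$log_concentration <- log(data$concentration)
  }
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a
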