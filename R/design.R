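# Study design: pools per (age group, gender, collection period) cell.

#' Default pooled-sampling design of the serum study
#'
#' Returns the published sampling design: five age groups by two genders by
#' five collection periods, with the unbalanced pool counts of the study
#' (many more pools for 5-15 year olds in 2006/07, where pooling was capped
#' at 30 individuals instead of the usual 100).  The 0-4 age group is not
#' part of the design because its 2002/03 samples are missing.
#'
#' @return A data frame with one row per design cell (50 rows) and columns
#'   \code{age_group}, \code{gender}, \code{period} (factors), \code{t}
#'   (integer period index), \code{n_pools} and \code{pool_size}.
#' @examples
#' d <- default_design()
#' sum(d$n_pools)  # 154 pools in total
#' @export
default_design <- function() {
  # pools per period, rows in age order, one matrix per gender
  male <- rbind(
    c(3, 15, 2, 4, 2),
    c(3, 2, 2, 4, 2),
    c(1, 2, 2, 4, 2),
    c(3, 2, 2, 4, 2),
    c(3, 2, 2, 4, 2)
  )
  female <- male
  female[1, 2] <- 17
  counts <- array(0L, dim = c(5L, 2L, 5L))
  counts[, 1L, ] <- male
  counts[, 2L, ] <- female
  d <- expand.grid(
    age_group = .AGE_LEVELS, gender = .GENDER_LEVELS, period = .PERIOD_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  d <- as_pooled_design(d)
  d$n_pools <- counts[cbind(as.integer(d$age_group), as.integer(d$gender), d$t)]
  d$pool_size <- ifelse(d$period == "2006/07", 30L, 100L)
  d
}

#' Balanced pooled-sampling designs
#'
#' A balanced analogue of \code{\link{default_design}} for simulation
#' studies: every one of the 50 design cells receives the same number of
#' pools and the same pool size.
#'
#' @param n_pools_per_cell Non-negative integer, pools per design cell.
#' @param pool_size Positive integer, individuals per pool.
#' @return A design data frame as in \code{\link{default_design}}.
#' @export
make_design <- function(n_pools_per_cell, pool_size = 100L) {
  if (length(n_pools_per_cell) != 1 || is.na(n_pools_per_cell) ||
      n_pools_per_cell < 0 || n_pools_per_cell != round(n_pools_per_cell)) {
    stop("n_pools_per_cell must be a single non-negative integer")
  }
  if (length(pool_size) != 1 || is.na(pool_size) || pool_size < 1 ||
      pool_size != round(pool_size)) {
    stop("pool_size must be a single positive integer")
  }
  d <- expand.grid(
    age_group = .AGE_LEVELS, gender = .GENDER_LEVELS, period = .PERIOD_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  d <- as_pooled_design(d)
  d$n_pools <- as.integer(n_pools_per_cell)
  d$pool_size <- as.integer(pool_size)
  d
}

as_pooled_design <- function(d) {
  d$age_group <- factor(d$age_group, levels = .AGE_LEVELS)
  d$gender <- factor(d$gender, levels = .GENDER_LEVELS)
  d$period <- factor(d$period, levels = .PERIOD_LEVELS)
  d$t <- as.integer(d$period)
  d <- d[order(d$age_group, d$gender, d$t), , drop = FALSE]
  rownames(d) <- NULL
  d
}
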