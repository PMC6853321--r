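# Generative parameter sets and the synthetic pooled-data simulator.

#' Generative parameters for the hierarchical models
#'
#' Bundles a true parameter set for one of the three hierarchical model
#' structures, for use by \code{\link{simulate_pools}}.  All concentrations
#' are handled on the natural-log scale (log ng/g lipid).
#'
#' Model structures (mean of the log-concentration of a pool in cell
#' \code{(a, g, t)}):
#' \itemize{
#'   \item Model 1: \code{beta[a,t]}, an age-specific random-walk trend
#'     (optionally plus a gender offset \code{alpha_g[g]} when supplied);
#'   \item Model 2: \code{alpha[a,g]}, an age-by-gender level with no time
#'     effect;
#'   \item Model 3: \code{alpha[a,g] + beta[a,t]}.
#' }
#' The temporal block may be given either as the random-walk inputs
#' (\code{beta0}, \code{omega}: \code{beta[a,t] ~ N(beta[a,t-1], omega^2)}
#' started at \code{beta[a,0] = beta0[a]}) or pinned exactly via a full
#' \code{beta_at} matrix.  Likewise the age-by-gender block may be given as
#' a full \code{alpha_ag} matrix or drawn as \code{N(delta_a[a], phi^2)}
#' (Model 2) / \code{N(delta_g[g], phi^2)} (Model 3).
#'
#' @param model Integer 1, 2 or 3.
#' @param sigma Observation sd on the log scale (>= 0).
#' @param beta0 Numeric length 5: initial level per age group (models 1, 3).
#' @param omega Random-walk innovation sd (>= 0; models 1, 3).
#' @param beta_at Optional 5 x 5 matrix (age x period) fixing the temporal
#'   effects instead of drawing the random walk.
#' @param alpha_ag Optional 5 x 2 matrix (age x gender) of age-by-gender
#'   levels (models 2, 3).
#' @param delta_a Numeric length 5: age means generating \code{alpha_ag}
#'   (model 2, used when \code{alpha_ag} is absent).
#' @param delta_g Numeric length 2: gender means generating \code{alpha_ag}
#'   (model 3, used when \code{alpha_ag} is absent).
#' @param phi Group-level sd generating \code{alpha_ag} (>= 0).
#' @param alpha_g Optional numeric length 2 gender offsets added to the
#'   model-1 mean.
#' @return An object of class \code{"hier_params"}.
#' @export
hier_params <- function(model, sigma, beta0 = NULL, omega = NULL,
                        beta_at = NULL, alpha_ag = NULL, delta_a = NULL,
                        delta_g = NULL, phi = NULL, alpha_g = NULL) {
  model <- as.integer(model)
  if (!isTRUE(model %in% 1:3)) stop("model must be 1, 2 or 3")
  if (length(sigma) != 1 || sigma < 0) stop("sigma must be a single value >= 0")
  chk_scale <- function(x, nm) {
    if (length(x) != 1 || x < 0) stop(nm, " must be a single value >= 0")
  }
  if (model %in% c(1L, 3L)) {
    if (is.null(beta_at)) {
      if (is.null(beta0) || is.null(omega)) {
        stop("models 1 and 3 need either beta_at or both beta0 and omega")
      }
      if (length(beta0) != 5) stop("beta0 must have length 5 (one per age group)")
      chk_scale(omega, "omega")
    } else {
      beta_at <- as.matrix(beta_at)
      if (!all(dim(beta_at) == c(5, 5))) stop("beta_at must be a 5 x 5 matrix")
    }
  }
  if (model == 2L || model == 3L) {
    if (is.null(alpha_ag)) {
      centre <- if (model == 2L) delta_a else delta_g
      want <- if (model == 2L) "delta_a" else "delta_g"
      if (is.null(centre) || is.null(phi)) {
        stop(sprintf("model %d needs either alpha_ag or both %s and phi",
                     model, want))
      }
      if (length(centre) != (if (model == 2L) 5 else 2)) {
        stop(want, " has the wrong length")
      }
      chk_scale(phi, "phi")
    } else {
      alpha_ag <- as.matrix(alpha_ag)
      if (!all(dim(alpha_ag) == c(5, 2))) stop("alpha_ag must be a 5 x 2 matrix")
    }
  }
  if (!is.null(alpha_g)) {
    if (model != 1L) stop("alpha_g applies to model 1 only")
    if (length(alpha_g) != 2) stop("alpha_g must have length 2")
  }
  structure(
    list(model = model, sigma = sigma, beta0 = beta0, omega = omega,
         beta_at = beta_at, alpha_ag = alpha_ag, delta_a = delta_a,
         delta_g = delta_g, phi = phi, alpha_g = alpha_g),
    class = "hier_params"
  )
}

# Draw (or pass through) the realized random effects of a parameter set.
# Called inside an already-seeded RNG context.
realize_params <- function(params) {
  A <- 5L; G <- 2L; Tn <- 5L
  B <- NULL; alpha <- NULL
  if (params$model %in% c(1L, 3L)) {
    if (!is.null(params$beta_at)) {
      B <- params$beta_at
    } else {
      B <- matrix(0, A, Tn)
      prev <- params$beta0
      for (tt in seq_len(Tn)) {
        B[, tt] <- stats::rnorm(A, prev, params$omega)
        prev <- B[, tt]
      }
    }
  }
  if (params$model %in% c(2L, 3L)) {
    if (!is.null(params$alpha_ag)) {
      alpha <- params$alpha_ag
    } else if (params$model == 2L) {
      alpha <- matrix(stats::rnorm(A * G, rep(params$delta_a, G), params$phi), A, G)
    } else {
      alpha <- matrix(stats::rnorm(A * G, rep(params$delta_g, each = A), params$phi), A, G)
    }
  }
  list(beta_at = B, alpha_ag = alpha, alpha_g = params$alpha_g)
}

#' Simulate a pooled-biomonitoring dataset
#'
#' Draws one pooled log-concentration per pool in \code{design} from the
#' generative structure selected by \code{params}: the log concentration of
#' a pool in cell \code{(a, g, t)} is Normal with the model mean (see
#' \code{\link{hier_params}}) and sd \code{sigma}.  Random effects that are
#' not pinned in \code{params} are drawn first (random walk forward from
#' \code{beta0}, \code{alpha_ag} around its group means) and recorded in the
#' \code{"params_realized"} attribute so simulation studies can test
#' parameter recovery against the realized truth.
#'
#' @param design A design data frame from \code{\link{default_design}} or
#'   \code{\link{make_design}}.
#' @param params A \code{\link{hier_params}} object.
#' @param seed Integer seed; identical (design, params, seed) triples give
#'   identical datasets.
#' @param ocp Label stored in the \code{ocp} column.
#' @param scale_by_pool_size If \code{TRUE}, the observation sd of a pool is
#'   \code{sigma / sqrt(pool_size)} instead of \code{sigma}.  The default
#'   models pool-level measurements directly, with no size scaling.
#' @return A data frame with one row per pool: \code{ocp}, \code{age_group},
#'   \code{gender}, \code{period}, \code{t}, \code{concentration},
#'   \code{log_concentration}, \code{pool_size}.
#' @examples
#' p <- hier_params(1, sigma = 0.3, beta0 = c(4, 3.5, 3, 2.5, 2), omega = 0.2)
#' head(simulate_pools(default_design(), p, seed = 1))
#' @export
simulate_pools <- function(design, params, seed, ocp = "synthetic",
                           scale_by_pool_size = FALSE) {
  stopifnot(inherits(params, "hier_params"))
  if (missing(seed)) stop("an explicit seed is required")
  design <- design[design$n_pools > 0, , drop = FALSE]
  with_seed(seed, {
    re <- realize_params(params)
    n <- design$n_pools
    a <- rep(as.integer(design$age_group), n)
    g <- rep(as.integer(design$gender), n)
    t <- rep(design$t, n)
    psz <- rep(design$pool_size, n)
    mu <- numeric(length(a))
    if (!is.null(re$beta_at)) mu <- mu + re$beta_at[cbind(a, t)]
    if (!is.null(re$alpha_ag)) mu <- mu + re$alpha_ag[cbind(a, g)]
    if (!is.null(re$alpha_g)) mu <- mu + re$alpha_g[g]
    sdv <- if (scale_by_pool_size) params$sigma / sqrt(psz) else rep(params$sigma, length(a))
    logy <- stats::rnorm(length(a), mu, sdv)
    out <- data.frame(
      ocp = ocp,
      age_group = factor(.AGE_LEVELS[a], levels = .AGE_LEVELS),
      gender = factor(.GENDER_LEVELS[g], levels = .GENDER_LEVELS),
      period = factor(.PERIOD_LEVELS[t], levels = .PERIOD_LEVELS),
      t = t,
      concentration = exp(logy),
      log_concentration = logy,
      pool_size = psz,
      stringsAsFactors = FALSE
    )
    attr(out, "gen_params") <- params
    attr(out, "params_realized") <- re
    attr(out, "seed") <- seed
    out
  })
}
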