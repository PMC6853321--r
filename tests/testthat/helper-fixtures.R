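# Shared generative settings and small constructors used across the tests.
# Values are the package's reference study conditions: log-scale levels in
# the 2-4 range (7-55 ng/g lipid), observation noise around 0.3.

params_spec1 <- function(sigma = 0.3, omega = 0.2,
                         beta0 = c(4, 3.5, 3, 2.8, 2.5), ...) {
  hier_params(1, sigma = sigma, beta0 = beta0, omega = omega, ...)
}

params_spec2 <- function(sigma = 0.3,
                         alpha_ag = matrix(seq(2, 4, length.out = 10), 5, 2)) {
  hier_params(2, sigma = sigma, alpha_ag = alpha_ag)
}

params_spec3 <- function(sigma = 0.3, omega = 0.2, phi = 0.3,
                         beta0 = c(4, 3.5, 3, 2.8, 2.5),
                         delta_g = c(3, 3.4)) {
  hier_params(3, sigma = sigma, beta0 = beta0, omega = omega,
              delta_g = delta_g, phi = phi)
}

# Age-specific trends that diverge over time: a strong age-by-period
# interaction for the screening experiments.
diverging_beta <- function() {
  outer(c(4, 3.6, 3.2, 3.0, 2.8), rep(1, 5)) +
    outer(c(-0.4, -0.2, 0, 0.1, 0.2), 0:4)
}

# A hand-built fit object with fully degenerate draws (every chain row
# identical), for closed-form checks of the assessment machinery.
degenerate_fit <- function(theta, data, spec = 2L, n = 50L, chains = 2L) {
  model <- build_model(spec)
  stopifnot(length(theta) == nrow(model$parameters))
  names(theta) <- model$parameters$name
  draws <- matrix(rep(theta, each = n), n, length(theta),
                  dimnames = list(NULL, names(theta)))
  structure(
    list(model = model, data = pooltrend:::as_pooled_data(data),
         draws = rep(list(draws), chains), chains = chains,
         iter = n, burnin = 0L, thin = 1L, seed = 0L, fixed = NULL),
    class = "hier_fit"
  )
}

# A one-pool-per-cell data frame with prescribed log concentrations over
# the full 5 x 2 x 5 grid (column-major in age, gender, period).
grid_data <- function(log_conc) {
  g <- expand.grid(age_group = design_levels()$age_group,
                   gender = design_levels()$gender,
                   period = design_levels()$period,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$concentration <- exp(log_conc)
  g$pool_size <- 100L
  g
}

# Parameter vector for a spec-2 model, column-major alpha then delta_a,
# sigma, phi.
theta_spec2 <- function(alpha, delta_a = rep(0, 5), sigma = 1, phi = 1) {
  c(as.vector(alpha), delta_a, sigma, phi)
}

# Parameter vector for a spec-1 model: beta0, column-major beta, sigma, omega.
theta_spec1 <- function(B, beta0 = B[, 1], sigma = 1, omega = 1) {
  c(beta0, as.vector(B), sigma, omega)
}
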