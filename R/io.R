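# Delimited-text readers/writers, pipeline configuration and the
# two-stage pipeline driver.

.TABLE_SCHEMA <- "pooltrend pooled-sample table v1"
.TABLE_COLS <- c("ocp", "age_group", "gender", "period",
                 "concentration_ng_g_lipid", "pool_n")

#' Write a pooled-sample table
#'
#' Tab-separated UTF-8 text with a header row and the schema recorded in a
#' comment line; concentrations are written at full precision so a
#' write/read round trip reproduces the values exactly.
#'
#' @param data Pooled data frame (as from \code{\link{simulate_pools}}).
#' @param path Output file path.
#' @param seed Optional generating seed recorded in a comment line.
#' @return \code{path}, invisibly.
#' @export
write_pooled_table <- function(data, path, seed = NULL) {
  data <- as_pooled_data(data)
  out <- data.frame(
    ocp = if (is.null(data$ocp)) "unknown" else as.character(data$ocp),
    age_group = as.character(data$age_group),
    gender = as.character(data$gender),
    period = as.character(data$period),
    concentration_ng_g_lipid = sprintf("%.17g", data$concentration),
    pool_n = if (is.null(data$pool_size)) NA_integer_ else data$pool_size,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", .TABLE_SCHEMA), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", format(seed)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pooled-sample table
#'
#' Reads and validates the tab-separated pooled-sample schema written by
#' \code{\link{write_pooled_table}}: required columns, known design labels,
#' parseable positive concentrations.  Errors name the offending data row.
#'
#' @param path Input file path.
#' @return A validated pooled data frame with canonical factors, the period
#'   index \code{t} and \code{log_concentration}.
#' @export
read_pooled_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("empty pooled-sample table: ", path)
  miss <- setdiff(.TABLE_COLS, names(raw))
  if (length(miss)) {
    stop("pooled-sample table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  conc <- suppressWarnings(as.numeric(raw$concentration_ng_g_lipid))
  bad <- which(is.na(conc))
  if (length(bad)) {
    stop(sprintf("row %d: unparseable concentration '%s'", bad[1],
                 raw$concentration_ng_g_lipid[bad[1]]))
  }
  bad <- which(conc <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: concentration must be positive, got %s", bad[1],
                 raw$concentration_ng_g_lipid[bad[1]]))
  }
  pool_n <- suppressWarnings(as.integer(raw$pool_n))
  out <- data.frame(
    ocp = raw$ocp,
    age_group = raw$age_group,
    gender = raw$gender,
    period = raw$period,
    concentration = conc,
    pool_size = pool_n,
    stringsAsFactors = FALSE
  )
  as_pooled_data(out)
}

write_result_table <- function(df, path, schema, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# pooltrend ", schema, " schema v1"), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", format(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration for \code{\link{run_pipeline}}.  Exactly one of
#' \code{input} (a pooled-sample table path) or \code{simulation} (a block
#' with \code{design}, \code{model}, \code{params}, \code{seed}) must be
#' present; \code{brt}, \code{mcmc} and \code{assessment} blocks override
#' the stage defaults; \code{output_dir} is required.
#'
#' @param path Path to the YAML file (or a pre-parsed list).
#' @return A validated \code{"pipeline_config"} list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulation'")
  }
  if (is.null(cfg$output_dir)) stop("config needs an 'output_dir'")
  if (has_sim) {
    sim <- cfg$simulation
    if (is.null(sim$seed)) stop("simulation block needs an explicit seed")
    if (is.null(sim$model)) stop("simulation block needs a model spec (1, 2 or 3)")
    if (is.null(sim$params)) stop("simulation block needs a params list")
  }
  cfg$brt <- utils::modifyList(
    list(shrinkage = 0.01, max_trees = 5000L, tree_depth = 3L, seed = 1L,
         patience = 50L),
    cfg$brt %||% list()
  )
  cfg$mcmc <- utils::modifyList(
    list(models = 1:3, chains = 2L, iterations = 10000L, burnin = 10000L,
         seed = 1L),
    cfg$mcmc %||% list()
  )
  cfg$assessment <- utils::modifyList(
    list(alphas = c(0.2, 0.1, 0.05)),
    cfg$assessment %||% list()
  )
  class(cfg) <- "pipeline_config"
  cfg
}

sim_params_from_config <- function(sim) {
  pl <- sim$params
  to_mat <- function(x, nr, nc) if (is.null(x)) NULL else matrix(unlist(x), nr, nc)
  hier_params(
    model = sim$model,
    sigma = pl$sigma,
    beta0 = unlist(pl$beta0),
    omega = pl$omega,
    beta_at = to_mat(pl$beta_at, 5, 5),
    alpha_ag = to_mat(pl$alpha_ag, 5, 2),
    delta_a = unlist(pl$delta_a),
    delta_g = unlist(pl$delta_g),
    phi = pl$phi,
    alpha_g = unlist(pl$alpha_g)
  )
}

#' Run the two-stage pipeline
#'
#' Executes simulate-or-read, boosted-tree screening, hierarchical model
#' fitting for every requested model, assessment and trend reporting, and
#' writes every artifact (tab-separated tables plus a JSON manifest
#' recording seeds and settings) under the configured output directory.
#' Model 2 has no time term, so its change table is written as an explicit
#' "not applicable" marker rather than silently skipped.
#'
#' @param config A \code{\link{read_pipeline_config}} object, a config list,
#'   or a path to a YAML config file.
#' @return Invisibly, a list with the fitted objects, assessments, ranking
#'   and the paths of all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- read_pipeline_config(config)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(...) file.path(config$output_dir, ...)
  paths <- character(0)
  note <- function(stage, msg) {
    message(sprintf("[pooltrend] %s: %s", stage, msg))
  }

  # --- data ------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    design <- if (identical(sim$design %||% "default", "default")) {
      default_design()
    } else {
      make_design(sim$design$n_pools_per_cell, sim$design$pool_size %||% 100L)
    }
    params <- sim_params_from_config(sim)
    data <- simulate_pools(design, params, seed = sim$seed,
                           ocp = sim$ocp %||% "synthetic")
    paths <- c(paths, data_table = write_pooled_table(
      data, out_path("data.tsv"), seed = sim$seed))
    note("simulate", sprintf("%d pools written (model %d, seed %s)",
                             nrow(data), sim$model, format(sim$seed)))
  } else {
    data <- read_pooled_table(config$input)
    note("read", sprintf("%d pools read from %s", nrow(data), config$input))
  }

  # --- screen ----------------------------------------------------------
  brt <- fit_brt(data, shrinkage = config$brt$shrinkage,
                 max_trees = config$brt$max_trees,
                 tree_depth = config$brt$tree_depth,
                 split_seed = config$brt$seed,
                 patience = config$brt$patience)
  seed_b <- config$brt$seed
  if (brt$n_trees > 0L) {
    imp <- relative_importance(brt)
    paths <- c(paths, importance = write_result_table(
      data.frame(predictor = names(imp), importance = imp),
      out_path("importance.tsv"), "importance", seed_b))
    it <- interaction_table(brt)
    paths <- c(paths, interactions = write_result_table(
      data.frame(pair = names(it), strength = it),
      out_path("interactions.tsv"), "interactions", seed_b))
    pd <- do.call(rbind, lapply(.PREDICTORS, function(v) {
      cbind(predictor = v, partial_dependence(brt, v))
    }))
    paths <- c(paths, partial_dependence = write_result_table(
      pd, out_path("partial_dependence.tsv"), "partial-dependence", seed_b))
  }
  note("screen", sprintf("%d trees kept; held-out RMSE %.4f",
                         brt$n_trees,
                         if (brt$n_trees > 0) brt_rmse(brt) else NA))

  # --- fit / assess / report -------------------------------------------
  fits <- list()
  assessments <- list()
  seed_m <- config$mcmc$seed
  for (spec in config$mcmc$models) {
    fit <- fit_hier(data, model = spec, chains = config$mcmc$chains,
                    iter = config$mcmc$iterations,
                    burnin = config$mcmc$burnin, seed = seed_m)
    fits[[as.character(spec)]] <- fit
    D <- posterior_matrix(fit)
    post <- data.frame(
      chain = rep(seq_along(fit$draws), each = nrow(fit$draws[[1]])),
      iteration = rep(seq_len(nrow(fit$draws[[1]])), length(fit$draws))
    )
    post <- cbind(post, as.data.frame(D))
    paths <- c(paths, stats::setNames(write_result_table(
      post, out_path(sprintf("posterior_model%d.tsv", spec)),
      "posterior-draws", seed_m), sprintf("posterior_%d", spec)))
    paths <- c(paths, stats::setNames(write_result_table(
      gelman_rubin(fit), out_path(sprintf("psrf_model%d.tsv", spec)),
      "psrf", seed_m), sprintf("psrf_%d", spec)))
    assessments[[as.character(spec)]] <- assess(
      fit, alphas = config$assessment$alphas, seed = seed_m)
    paths <- c(paths, stats::setNames(write_result_table(
      trajectories(fit), out_path(sprintf("trajectories_model%d.tsv", spec)),
      "trajectories", seed_m), sprintf("trajectories_%d", spec)))
    chg_path <- out_path(sprintf("changes_model%d.tsv", spec))
    if (spec == 2L) {
      con <- file(chg_path, "w", encoding = "UTF-8")
      writeLines(c("# pooltrend changes schema v1",
                   "# not applicable: time is not in the model 2 mean"), con)
      close(con)
    } else {
      lv <- design_levels()
      overall <- do.call(rbind, lapply(lv$age_group, function(ag) {
        percent_change(fit, ag, lv$period[1], lv$period[5])
      }))
      overall$kind <- "overall"
      consec <- consecutive_changes(fit)
      consec$kind <- "consecutive"
      cohort <- cohort_changes(fit)
      cohort$kind <- "cohort"
      write_result_table(rbind(overall, consec, cohort), chg_path,
                         "changes", seed_m)
    }
    paths <- c(paths, stats::setNames(chg_path, sprintf("changes_%d", spec)))
    note("fit", sprintf("model %d: DIC %.2f, RMSE %.3f", spec,
                        assessments[[as.character(spec)]]$dic,
                        assessments[[as.character(spec)]]$rmse))
  }

  ranking <- if (length(assessments) >= 2L) compare_models(assessments) else NULL
  if (length(assessments) > 0L) {
    assess_df <- do.call(rbind, lapply(assessments, function(a) {
      data.frame(model = a$model, t(a$pi_coverage), dic = a$dic, p_d = a$p_d,
                 rmse = a$rmse, sigma_mean = a$sigma_mean,
                 sigma_lower = a$sigma_lower, sigma_upper = a$sigma_upper,
                 check.names = FALSE)
    }))
    if (!is.null(ranking)) {
      assess_df$rank <- ranking$rank[match(assess_df$model, ranking$model)]
    }
    paths <- c(paths, assessment = write_result_table(
      assess_df, out_path("assessment.tsv"), "assessment", seed_m))
    note("assess", sprintf("models ranked by DIC: %s",
                           paste(if (is.null(ranking)) assess_df$model
                                 else ranking$model, collapse = " < ")))
  }

  manifest <- list(
    schema = "pooltrend manifest v1",
    config = unclass(config),
    artifacts = as.list(paths)
  )
  manifest_path <- out_path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, manifest = manifest_path)

  invisible(list(data = data, brt = brt, fits = fits,
                 assessments = assessments, ranking = ranking,
                 paths = paths))
}
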