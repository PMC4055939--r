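# End-to-end orchestration: a validated run configuration, the
# simulate -> sample -> summarize pipeline, and self-describing artifact
# output (draws table, result JSON, CEAC CSV, plane CSV, run log).

#' Build and validate a run configuration
#'
#' @param trial path to a trial CSV, or a [trial_data()] object.
#' @param evidence an `external_evidence` object, or `NULL` for a
#'   no-evidence run.
#' @param scheme `"rejection"`, `"importance"`, or `"none"`.
#' @param bootstrap `"bayesian"` or `"ordinary"`.
#' @param draws number of posterior draws M.
#' @param max_attempts rejection attempt budget (default `100 * draws`).
#' @param seed master seed.
#' @param comparison `c(reference, treatment)` arm labels.
#' @param lambda_grid willingness-to-pay grid for the CEAC.
#' @param level credible level.
#' @param impute_method within-replicate imputation method.
#' @param out_dir optional output directory for artifacts.
#' @return a `run_config` object.
#' @export
run_config <- function(trial, evidence = NULL,
                       scheme = c("rejection", "importance", "none"),
                       bootstrap = c("bayesian", "ordinary"),
                       draws = 10000, max_attempts = 100 * draws, seed = 1,
                       comparison, lambda_grid = seq(0, 500000, by = 5000),
                       level = 0.95, impute_method = "weighted_arm_mean",
                       out_dir = NULL) {
  scheme <- match.arg(scheme)
  bootstrap <- match.arg(bootstrap)
  if (is.character(trial)) trial <- read_trial(trial)
  stopifnot(inherits(trial, "trial_data"))
  if (!is.null(evidence)) stopifnot(inherits(evidence, "external_evidence"))
  if (draws < 1) .stop_mod("cli_config", "draws must be >= 1")
  if (level <= 0 || level >= 1) .stop_mod("cli_config", "level must be in (0,1)")
  if (length(comparison) != 2 || !all(comparison %in% arms(trial)))
    .stop_mod("cli_config", "comparison arms (%s) not present in trial",
              paste(comparison, collapse = ", "))
  structure(list(trial = trial, evidence = evidence, scheme = scheme,
                 bootstrap = bootstrap, draws = as.integer(draws),
                 max_attempts = max_attempts, seed = seed,
                 comparison = comparison, lambda_grid = lambda_grid,
                 level = level, impute_method = impute_method,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Schema (all keys optional unless noted): `trial` (CSV path, required
#' unless supplied separately), `comparison` (required, two arm labels),
#' `scheme`, `bootstrap`, `draws`, `max_attempts`, `seed`, `level`,
#' `lambda_max`, `lambda_step`, `impute_method`, `out_dir`, and an
#' `evidence` block with `parameter`, `point`, `ci_low`, `ci_high`,
#' `between_study_variance`, `ci_convention` (or `mu`/`sigma` directly, or
#' `flat: true`). Arguments passed to this function override file values.
#'
#' @param path JSON config path.
#' @param ... overrides forwarded to [run_config()].
#' @export
read_run_config <- function(path, ...) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- NULL
  if (!is.null(cfg$evidence)) {
    e <- cfg$evidence
    ev <- if (isTRUE(e$flat)) {
      flat_evidence(parameter = e$parameter %||% "log_RR")
    } else if (!is.null(e$mu)) {
      normal_evidence(e$mu, e$sigma, parameter = e$parameter %||% "log_RR")
    } else {
      pool_evidence(e$point, e$ci_low, e$ci_high,
                    between_study_variance = e$between_study_variance %||% 0,
                    ci_convention = e$ci_convention %||% "upper",
                    parameter = e$parameter %||% "log_RR")
    }
  }
  lambda_grid <- seq(0, cfg$lambda_max %||% 500000,
                     by = cfg$lambda_step %||% 5000)
  args <- list(trial = cfg$trial, evidence = ev,
               scheme = cfg$scheme %||% "rejection",
               bootstrap = cfg$bootstrap %||% "bayesian",
               draws = cfg$draws %||% 10000, seed = cfg$seed %||% 1,
               comparison = unlist(cfg$comparison),
               lambda_grid = lambda_grid, level = cfg$level %||% 0.95,
               impute_method = cfg$impute_method %||% "weighted_arm_mean",
               out_dir = cfg$out_dir)
  if (!is.null(cfg$max_attempts)) args$max_attempts <- cfg$max_attempts
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full analysis from a configuration
#'
#' Orchestrates sampling, CEA summarization and CEAC computation, and (if
#' `out_dir` is set) writes a self-describing artifact bundle:
#' `draws.csv` (one row per retained draw), `result.json` (arm summaries,
#' ICER, intervals, diagnostics), `ceac.csv`, `plane.csv`, and
#' `run_log.json` (config echo and diagnostics). Deterministic given the
#' seed.
#'
#' @param config a [run_config()] (or path to a JSON config file).
#' @return invisibly, a list with `sample`, `result`, `ceac`, and `paths`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  sample <- switch(config$scheme,
    none = bootstrap_sample(config$trial, config$draws, config$bootstrap,
                            config$comparison, config$seed,
                            config$impute_method),
    rejection = rejection_sample(config$trial, config$evidence %||% flat_evidence(),
                                 config$draws, config$bootstrap,
                                 config$comparison, config$seed,
                                 config$max_attempts, config$impute_method),
    importance = importance_sample(config$trial, config$evidence %||% flat_evidence(),
                                   config$draws, config$bootstrap,
                                   config$comparison, config$seed,
                                   config$impute_method))
  result <- cea_summary(sample, level = config$level)
  curve <- ceac(sample, config$lambda_grid)
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write.csv(cbind(sample$draws, weight = sample$normalized_weights),
              p("draws.csv"), row.names = FALSE)
    jsonlite::write_json(.result_json(result), p("result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    write.csv(as.data.frame(curve), p("ceac.csv"), row.names = FALSE)
    export_plane(sample, p("plane.csv"))
    log <- list(
      package = "ceaboot",
      version = as.character(utils::packageVersion("ceaboot")),
      config = list(scheme = config$scheme, bootstrap = config$bootstrap,
                    draws = config$draws, seed = config$seed,
                    comparison = config$comparison, level = config$level,
                    impute_method = config$impute_method,
                    max_attempts = config$max_attempts,
                    evidence = if (is.null(config$evidence)) NULL else
                      config$evidence[c("type", "mu", "sigma", "parameter")]),
      diagnostics = result$diagnostics)
    jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    paths <- vapply(c("draws.csv", "result.json", "ceac.csv", "plane.csv",
                      "run_log.json"), p, "")
  }
  invisible(list(sample = sample, result = result, ceac = curve,
                 paths = paths))
}

.result_json <- function(result) {
  list(arms = result$arms, delta = result$delta, icer = result$icer,
       level = result$level, interval_method = result$interval_method,
       comparison = result$comparison, scheme = result$scheme,
       bootstrap = result$bootstrap, diagnostics = result$diagnostics)
}

#' Read a synthetic-trial spec from a JSON file
#'
#' Keys mirror the arguments of [synth_trial_spec()].
#'
#' @param path JSON spec path.
#' @export
read_synth_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- s[intersect(names(s), names(formals(synth_trial_spec)))]
  do.call(synth_trial_spec, args)
}
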