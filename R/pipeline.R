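#' Default pipeline configuration
#'
#' A complete, desk-scale configuration for [run_pipeline()]: the
#' simulation-study parameter set, the standard two-treatment design, a
#' modest number of optimization starts and bootstrap replicates, and
#' explicit seeds for every stochastic stage. Any entry can be
#' overridden; [validate_config()] checks the result.
#'
#' @param ... named overrides applied on top of the defaults with
#'   [utils::modifyList()] semantics, e.g.
#'   `default_config(design = list(sigma_P = 0.01))`.
#' @return A nested list of class `pipeline_config` with blocks `params`,
#'   `design`, `inference` and `bootstrap`.
#' @export
default_config <- function(...) {
  cfg <- list(
    params = list(alpha_w = 7e-3, alpha_m = 2e-2, phi_w = 0.2,
                  phi_m = 2e-2, a = 3e-9, b = 0.1, B = 80, r = 1.4,
                  tau = 1.5, K = 1e9, delta = 0.8),
    design = list(treatments = c(epidemic = 0.01, endemic = 0.99),
                  replicates = 4L, t_min = 1, t_max = 60, t_step = 1,
                  sigma_P = 0.5, sigma_g = 0.5, sigma_q = 0.5,
                  mutant_share = 0.5, seed = 1L),
    inference = list(n_starts = 8L, seed = 1L,
                     prevalence_threshold = 0.95,
                     bounds = list()),
    bootstrap = list(n_boot = 20L, seed = 1L))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(ov)) cfg[[nm]] <- modifyList(cfg[[nm]], ov[[nm]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the blocks of
#'   [default_config()]; missing entries take their defaults.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design$treatments))
    raw$design$treatments <- unlist(raw$design$treatments)
  cfg <- do.call(default_config, raw)
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid config '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  cfg
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @param path file to write.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # named atomic vectors lose their names in YAML; store as a map
  cfg$design$treatments <- as.list(cfg$design$treatments)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks the schema and value ranges of every block and returns a
#' character vector of problems, each naming the offending key (empty
#' when the configuration is valid).
#'
#' @param config a `pipeline_config` (or conforming nested list).
#' @return Character vector of problem descriptions.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need_num <- function(block, key, lo = -Inf, hi = Inf) {
    v <- config[[block]][[key]]
    if (is.null(v) || !is.numeric(v) || any(!is.finite(v))) {
      problems <<- c(problems,
                     sprintf("%s.%s: missing or non-numeric", block, key))
    } else if (any(v < lo) || any(v > hi)) {
      problems <<- c(problems,
                     sprintf("%s.%s: outside [%g, %g]", block, key, lo, hi))
    }
  }
  for (b in c("params", "design", "inference", "bootstrap"))
    if (is.null(config[[b]]))
      problems <- c(problems, paste0(b, ": block missing"))
  if (length(problems)) return(problems)
  need_num("params", "alpha_w", 0)
  need_num("params", "alpha_m", 0)
  need_num("params", "phi_w", 0, 1)
  need_num("params", "phi_m", 0, 1)
  need_num("params", "a", 0)
  need_num("params", "b", 0, 1)
  need_num("params", "tau", 0)
  need_num("params", "B", 0)
  need_num("params", "r", 0)
  need_num("params", "K", 1e-12)
  need_num("params", "delta", 0)
  need_num("design", "treatments", 0, 1)
  if (!is.null(config$design$treatments) &&
      is.null(names(config$design$treatments)))
    problems <- c(problems, "design.treatments: must be named")
  need_num("design", "replicates", 1)
  need_num("design", "t_min", 1e-12)
  need_num("design", "t_max")
  need_num("design", "t_step", 1e-12)
  need_num("design", "sigma_P", 0)
  need_num("design", "sigma_g", 0)
  need_num("design", "sigma_q", 0)
  need_num("design", "mutant_share", 0, 1)
  need_num("design", "seed")
  need_num("inference", "n_starts", 1)
  need_num("inference", "seed")
  need_num("inference", "prevalence_threshold", 0, 1)
  need_num("bootstrap", "n_boot", 0)
  need_num("bootstrap", "seed")
  problems
}

config_params <- function(config) do.call(default_params, config$params)

config_design <- function(config) {
  d <- config$design
  design_spec(treatments = d$treatments, replicates = d$replicates,
              times = seq(d$t_min, d$t_max, by = d$t_step),
              sigma_P = d$sigma_P, sigma_g = d$sigma_g,
              sigma_q = d$sigma_q, mutant_share = d$mutant_share)
}

pipeline_log <- function(logfile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full estimation pipeline
#'
#' Executes, in order: synthetic-data generation, step-1 estimation of
#' the reactivation rates, the multi-start MLE of the remaining
#' parameters, and the Sieve bootstrap; writes every artifact to
#' `out_dir` as tidy CSV/JSON together with a run manifest recording the
#' seeds, resolved configuration, timings and artifact checksums (the
#' checksums are reproducible bit-for-bit given the same configuration).
#'
#' Estimating the lysogenization probabilities requires the transient of
#' an emerging epidemic, so the fit refuses to run when every configured
#' treatment starts at high prevalence; the reactivation-rate step alone
#' works on endemic data.
#'
#' @param config a `pipeline_config`, see [default_config()] /
#'   [read_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("synth", "alpha", "fit", "bootstrap")` to
#'   run (prefix order is enforced; later stages need earlier ones).
#' @return Invisibly, a list with the artifact paths and the in-memory
#'   results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("synth", "alpha", "fit", "bootstrap")) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  order_all <- c("synth", "alpha", "fit", "bootstrap")
  stages <- order_all[order_all %in% stages]
  if (!identical(stages, order_all[seq_along(stages)]))
    stop("'stages' must be a prefix of synth, alpha, fit, bootstrap",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  unlink(logfile)
  t_start <- Sys.time()
  timings <- list()
  artifacts <- list()
  results <- list()
  params <- config_params(config)
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    pipeline_log(logfile, "stage %s done in %.1f s", name,
                 timings[[name]])
    out
  }

  if ("synth" %in% stages) {
    results$dataset <- run_stage("synth", {
      generate_dataset(params, config_design(config),
                       seed = config$design$seed)
    })
    artifacts$dataset <- file.path(out_dir, "dataset.csv")
    write_dataset(results$dataset, artifacts$dataset)
  }
  if ("alpha" %in% stages) {
    results$alpha <- run_stage("alpha", {
      estimate_alphas(results$dataset,
                      config$inference$prevalence_threshold)
    })
    artifacts$alpha <- file.path(out_dir, "alpha_estimate.json")
    a <- results$alpha
    jsonlite::write_json(
      list(S_hat = a$S_hat, Q_hat = a$Q_hat, alpha_w = a$alpha_w,
           alpha_m = a$alpha_m, n_points = a$n_points, valid = a$valid),
      artifacts$alpha, auto_unbox = TRUE, digits = NA)
  }
  if ("fit" %in% stages) {
    if (all(config$design$treatments >= 0.5))
      stop("pipeline stage 'fit' refused: estimating the lysogenization ",
           "probabilities requires at least one treatment starting at ",
           "low prevalence (an emerging epidemic)", call. = FALSE)
    results$fit <- run_stage("fit", {
      fixed <- list(K = config$params$K, delta = config$params$delta,
                    B = config$params$B,
                    alpha_w = results$alpha$alpha_w,
                    alpha_m = results$alpha$alpha_m)
      bounds <- default_bounds(names(config$design$treatments),
                               overrides = config$inference$bounds)
      fit_mle(results$dataset, fixed,
              n_starts = config$inference$n_starts,
              seed = config$inference$seed, bounds = bounds)
    })
    artifacts$fit <- file.path(out_dir, "theta_estimate.json")
    f <- results$fit
    jsonlite::write_json(
      list(theta = f$theta, sigmas = as.list(f$sigmas), nll = f$nll,
           model = f$model,
           fixed = f$fixed, diagnostics = f$diagnostics),
      artifacts$fit, auto_unbox = TRUE, digits = NA)
    artifacts$fitted <- file.path(out_dir, "fitted_trajectory.csv")
    fitted <- deterministic_logits(
      theta_to_params(f$theta, f$fixed, f$model), results$dataset,
      treatments = setNames(
        vapply(names(config$design$treatments),
               function(tr) f$theta[[paste0("P0_", tr)]], numeric(1)),
        names(config$design$treatments)),
      mutant_share = f$theta$p0, model = f$model)
    write.csv(fitted, artifacts$fitted, row.names = FALSE)
  }
  if ("bootstrap" %in% stages) {
    results$bootstrap <- run_stage("bootstrap", {
      sieve_bootstrap(results$dataset, results$fit,
                      n_boot = config$bootstrap$n_boot,
                      seed = config$bootstrap$seed,
                      prevalence_threshold =
                        config$inference$prevalence_threshold)
    })
    artifacts$draws <- file.path(out_dir, "bootstrap_draws.csv")
    write.csv(results$bootstrap$draws, artifacts$draws, row.names = FALSE)
    artifacts$ci <- file.path(out_dir, "ci_table.csv")
    write.csv(results$bootstrap$ci, artifacts$ci, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(packageVersion("phagevo")),
    r_version = R.version.string,
    config = unclass(config),
    stages = stages,
    seeds = list(design = config$design$seed,
                 inference = config$inference$seed,
                 bootstrap = config$bootstrap$seed),
    timings_s = timings,
    total_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    checksums = as.list(tools::md5sum(unlist(artifacts))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  artifacts$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, artifacts$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pipeline_log(logfile, "pipeline complete (%.1f s)", manifest$total_s)
  invisible(list(artifacts = artifacts, results = results,
                 manifest = manifest))
}
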