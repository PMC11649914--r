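.KNOWN_STAGES <- c("simulate_ssme", "stoichiometry", "fit_decay", "fit_pka",
                   "fit_kobs", "langevin")
.STOCHASTIC_STAGES <- c("langevin")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with keys `stage`, `params`,
#' `inputs`, `output_dir` and `seed`. Unknown top-level keys are rejected
#' by name; stochastic stages require a seed; defaults are filled in and
#' the file's MD5 hash is recorded for provenance.
#'
#' @param path configuration file path.
#' @return Object of class `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("stage", "params", "inputs", "output_dir", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$stage)) stop("config is missing required key 'stage'", call. = FALSE)
  stage <- gsub("-", "_", cfg$stage)
  if (!stage %in% .KNOWN_STAGES) {
    stop("unknown stage '", cfg$stage, "'; known stages: ",
         paste(.KNOWN_STAGES, collapse = ", "), call. = FALSE)
  }
  if (stage %in% .STOCHASTIC_STAGES && is.null(cfg$seed)) {
    stop("stage '", stage, "' is stochastic and requires a seed", call. = FALSE)
  }
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed %% 1 != 0)) {
    stop("seed must be an integer", call. = FALSE)
  }
  structure(
    list(stage = stage,
         params = if (is.null(cfg$params)) list() else cfg$params,
         inputs = if (is.null(cfg$inputs)) list() else cfg$inputs,
         output_dir = if (is.null(cfg$output_dir)) "." else cfg$output_dir,
         seed = if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed),
         config_hash = unname(tools::md5sum(path))),
    class = "run_config"
  )
}

#' Read an SSME current trace from CSV
#'
#' Fixed dialect: header required, columns `time_s`, `current_nA` and
#' optionally `phase`; '.' decimal separator. Non-finite currents are
#' rejected with the offending line number.
#'
#' @param path CSV path.
#' @return A `"current_trace"` data frame.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "current_nA")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have a header with columns time_s, current_nA",
         call. = FALSE)
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$current_nA))
  if (length(bad)) {
    stop("malformed trace row(s) at line(s): ",
         paste(bad[seq_len(min(5, length(bad)))] + 1, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (is.null(df$phase)) df$phase <- "A"
  class(df) <- c("current_trace", "data.frame")
  df
}

#' Write an SSME current trace to CSV
#'
#' @param trace a `"current_trace"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace[, c("time_s", "current_nA", "phase")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write analysis results as JSON
#'
#' Results are written with version, seed and config-hash provenance
#' fields; numbers are not rounded and length-1 values are unboxed.
#'
#' @param path output path.
#' @param results named list of result fields.
#' @param seed seed used (or `NA`).
#' @param config_hash provenance hash (or `NA`).
#' @return `path`, invisibly.
#' @export
write_results_json <- function(path, results, seed = NA, config_hash = NA) {
  payload <- c(list(package = "symportkit",
                    version = as.character(utils::packageVersion("symportkit")),
                    seed = seed, config_hash = config_hash),
               results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run a configured analysis stage
#'
#' Executes the stage named in the configuration, writes its artifacts
#' into `output_dir`, and logs versions, seed and wall time. Identical
#' configuration and seed give identical numeric outputs.
#'
#' @param config a `"run_config"` from [load_config()].
#' @param dry_run if `TRUE`, print the execution plan and exit.
#' @return Named list of output file paths (invisibly); the `"result"`
#'   attribute holds the stage's in-memory result.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dry_run) {
    message("plan: stage=", config$stage, " output_dir=", config$output_dir,
            " seed=", config$seed)
    return(invisible(list()))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  p <- config$params
  outputs <- list()
  result <- NULL
  if (!is.na(config$seed)) set.seed(config$seed)
  if (config$stage == "simulate_ssme") {
    model <- build_dgot_cycle(if (is.null(p$rates)) list() else p$rates)
    na_cond <- solution_condition(p$pH_in %||% 7.3, p$pH_in %||% 7.3,
                                  p$gal_in %||% 0.5, p$gal_in %||% 0.5)
    a_cond <- solution_condition(p$pH_in %||% 7.3, p$pH_out %||% 7.6,
                                 p$gal_in %||% 0.5, p$gal_out %||% 2)
    phases <- list(protocol_phase("NA", p$na_s %||% 1, na_cond),
                   protocol_phase("A", p$a_s %||% 1, a_cond),
                   protocol_phase("NA", p$na_s %||% 1, na_cond))
    result <- simulate_ssme_protocol(model, phases, dt = p$dt %||% 1e-3)
    outputs$trace <- file.path(config$output_dir, "trace.csv")
    write_trace_csv(result, outputs$trace)
  } else if (config$stage == "stoichiometry") {
    ratios <- if (is.null(p$ratios)) seq(0, 4, by = 0.5) else unlist(p$ratios)
    result <- reversal_assay(ratios = ratios, dt = p$dt %||% 2e-3)
    outputs$results <- file.path(config$output_dir, "stoichiometry.json")
    write_results_json(outputs$results,
                       list(n_over_m = result$n_over_m,
                            points = result$points),
                       config$seed, config$config_hash)
  } else if (config$stage == "fit_decay") {
    tr <- read_trace_csv(config$inputs$trace)
    result <- fit_decay(tr, p$n_components %||% 1)
    outputs$results <- file.path(config$output_dir, "decay_fit.json")
    write_results_json(outputs$results,
                       list(amplitudes_nA = result$amplitudes_nA,
                            tau_s = result$tau_s, k_obs = result$k_obs,
                            residual_norm = result$residual_norm),
                       config$seed, config$config_hash)
  } else if (config$stage == "fit_pka") {
    df <- read.csv(config$inputs$points)
    result <- pka_fit(df$pH, df$current, p$mode %||% "acidic")
    outputs$results <- file.path(config$output_dir, "pka_fit.json")
    write_results_json(outputs$results,
                       list(pK = result$pK, I_max = result$I_max,
                            mode = result$mode,
                            se = as.list(result$se),
                            residual_norm = result$residual_norm),
                       config$seed, config$config_hash)
  } else if (config$stage == "fit_kobs") {
    df <- read.csv(config$inputs$points)
    result <- fit_induced_fit(df$gal_mM, df$kobs)
    outputs$results <- file.path(config$output_dir, "kobs_fit.json")
    write_results_json(outputs$results,
                       list(K_D = result$K_D, k_plus = result$k_plus,
                            k_minus = result$k_minus,
                            se = as.list(setNames(result$se,
                                                  c("K_D", "k_plus", "k_minus"))),
                            residual_norm = result$residual_norm),
                       config$seed, config$config_hash)
  } else if (config$stage == "langevin") {
    pot <- switch(p$potential %||% "double_well_1d",
                  harmonic = harmonic_1d(p$kappa %||% 1),
                  double_well_1d = double_well_1d(p$barrier %||% 10),
                  periodic_dihedral = periodic_dihedral(p$barrier %||% 8),
                  three_well_2d = three_well_2d(),
                  stop("unknown potential kind", call. = FALSE))
    lp <- langevin_params(n_steps = p$n_steps %||% 1e5,
                          dt = p$dt %||% 0.005, seed = config$seed)
    result <- langevin_sample(pot, lp)
    outputs$trajectory <- file.path(config$output_dir, "cv_trajectory.csv")
    df <- as.data.frame(unclass(result))
    names(df) <- paste0("cv", seq_len(ncol(df)))
    write.csv(df, outputs$trajectory, row.names = FALSE)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_path <- file.path(config$output_dir, "run.log")
  writeLines(c(sprintf("symportkit %s", utils::packageVersion("symportkit")),
               sprintf("stage: %s", config$stage),
               sprintf("seed: %s", config$seed),
               sprintf("config_hash: %s", config$config_hash),
               sprintf("wall_time_s: %.3f", elapsed)),
             log_path)
  outputs$log <- log_path
  message(sprintf("stage %s finished in %.2f s", config$stage, elapsed))
  structure(invisible(outputs), result = result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
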