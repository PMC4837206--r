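# Classed conditions so the CLI can map failures to exit codes.
validation_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ramanlayers_validation_error", "error")))
}

#' Build a run configuration
#'
#' The configuration driving [run_pipeline()].  Inputs per condition are
#' either phantom overrides (named list of [phantom_config()] arguments)
#' with a number of measurements, or a list of cube directories.  All
#' randomness flows from the single top-level seed through per-condition,
#' per-measurement derived seeds, so any measurement can be regenerated in
#' isolation.
#'
#' @param dialect `"fixed"` or `"unfixed"`; must be consistent across all
#'   inputs of a run.
#' @param control,metastasis Per-condition input: a list with either
#'   `phantom` (named list of phantom overrides, may be empty) and
#'   `n_measurements`, or `cubes` (character vector of cube directories).
#'   Defaults generate 6 control and 5 metastasis phantom measurements,
#'   the study design's measurement counts.
#' @param preprocess Named list of [preprocess_config()] overrides.
#' @param n_upper,signal_fraction_threshold Layer-assignment parameters.
#' @param alpha,variant,bonferroni Comparison parameters.
#' @param seed Top-level integer seed.
#' @param output_dir Run directory for results, log and config snapshot.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(dialect = c("fixed", "unfixed"),
                       control = list(phantom = list(), n_measurements = 6L),
                       metastasis = list(phantom = list(), n_measurements = 5L),
                       preprocess = list(),
                       n_upper = 1L, signal_fraction_threshold = 0.1,
                       alpha = 0.05, variant = "welch", bonferroni = FALSE,
                       seed = 1L, output_dir = NULL) {
  if (length(dialect) != 1L || !dialect %in% c("fixed", "unfixed"))
    validation_error("config must declare a single dialect ('fixed' or 'unfixed')")
  for (cond in list(control, metastasis)) {
    if (is.null(cond$cubes) && is.null(cond$phantom))
      validation_error("each condition needs either 'phantom' overrides or 'cubes'")
  }
  structure(list(dialect = dialect, control = control,
                 metastasis = metastasis, preprocess = preprocess,
                 n_upper = as.integer(n_upper),
                 signal_fraction_threshold = signal_fraction_threshold,
                 alpha = alpha, variant = variant, bonferroni = bonferroni,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) validation_error("config file '%s' not found", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$dialect))
    validation_error("config '%s' is missing the required 'dialect' key", path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

# Materialize the stacks of one condition (phantoms or cubes).
condition_stacks <- function(cfg, condition, cond_idx, log) {
  spec <- cfg[[condition]]
  if (!is.null(spec$cubes)) {
    log(sprintf("[%s] reading %d cubes", condition, length(spec$cubes)))
    stacks <- lapply(spec$cubes, read_cube)
    for (s in stacks) {
      if (s$dialect != cfg$dialect)
        validation_error("cube '%s' has dialect '%s' but the run declares '%s'",
                         s$sample_id, s$dialect, cfg$dialect)
    }
    return(lapply(stacks, function(s) list(stack = s, truth = NULL)))
  }
  n <- spec$n_measurements %||% 1L
  if (n < 1L) validation_error("n_measurements must be >= 1")
  log(sprintf("[%s] generating %d phantom measurements", condition, n))
  lapply(seq_len(n), function(j) {
    overrides <- spec$phantom
    overrides$dialect <- cfg$dialect
    overrides$seed <- derive_seed(cfg$seed, cond_idx, j)
    pc <- do.call(phantom_config, overrides)
    generate_stack(pc, condition = condition,
                   sample_id = sprintf("%s_%02d", condition, j))
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates input materialization (phantom generation or cube
#' reading), layer assignment on the raw stacks, per-pixel preprocessing,
#' depth profiling and the control-vs-metastasis comparison.  When
#' `output_dir` is set, writes `ratios.tsv`, `comparison.tsv`,
#' `report.md`, `run.log` and `resolved_config.yaml`.  Deterministic for a
#' fixed seed.
#'
#' @param config A [run_config()], or the path of a YAML file.
#' @return Invisibly, a list: `profiles` (per condition), `comparison`, and
#'   `output_dir` (NULL when nothing was written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    validation_error("config must be a run_config or a YAML path")
  log_lines <- character(0L)
  log <- function(msg) {
    line <- sprintf("%s %s", format(Sys.time(), "%H:%M:%S"), msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  pp_args <- config$preprocess
  pp_args$dialect <- config$dialect
  pp <- do.call(preprocess_config, pp_args)
  log(sprintf("preprocess: dialect=%s baseline=%s region=[%g, %g] despike=%gxMAD window=%d",
              pp$dialect, pp$baseline_method, pp$region[1L], pp$region[2L],
              pp$despike_threshold, pp$despike_window))
  profiles <- list()
  for (ci in c(control = 1L, metastasis = 2L)) {
    cond <- names(c(control = 1L, metastasis = 2L))[ci]
    inputs <- condition_stacks(config, cond, ci, log)
    profs <- vector("list", length(inputs))
    for (j in seq_along(inputs)) {
      raw <- inputs[[j]]$stack
      assignment <- assign_layers(raw, config$n_upper,
                                  config$signal_fraction_threshold)
      pre <- preprocess_stack(raw, pp)
      profs[[j]] <- profile_stack(pre, dialect = config$dialect,
                                  assignment = assignment)
      log(sprintf("[%s] %s: z0 plane %d, labels [%s], %d channels despiked",
                  cond, raw$sample_id, assignment$z0_index,
                  paste(assignment$labels, collapse = ", "),
                  sum(attr(pre, "n_despiked"))))
    }
    profiles[[cond]] <- profs
  }
  comparison <- compare_conditions(profiles$control, profiles$metastasis,
                                   alpha = config$alpha,
                                   variant = config$variant,
                                   bonferroni = config$bonferroni)
  log(sprintf("comparison: %d of %d compartment x measure cells significant at alpha = %g",
              sum(comparison$significant), nrow(comparison), config$alpha))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile_tsv(c(profiles$control, profiles$metastasis),
                      file.path(out_dir, "ratios.tsv"))
    write_comparison(comparison, out_dir)
    resolved <- unclass(config)
    resolved$preprocess <- unclass(pp)
    yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(list(profiles = profiles, comparison = comparison,
                 output_dir = out_dir))
}
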