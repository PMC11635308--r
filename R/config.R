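#' Read and validate a run configuration
#'
#' Run configurations are plain YAML with (at most) the top-level keys
#' `seed`, `community`, `sweep`, `control`, `tie_tol`, `scenarios`,
#' `output_dir`, `log_level`.  Unknown keys are rejected so typos fail loudly
#' before any computation.  A bundled example lives at
#' `system.file("extdata", "default_config.yaml", package = "thermocompete")`.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with validated components:
#'   `community` (tibble), `sweep` (t_start/t_end/step), `control`
#'   ([steady_control()]), `tie_tol`, `scenarios` ([scenario_spec()] or
#'   NULL), `seed`, `output_dir`, `log_level`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param x A named list with the schema above (e.g. parsed YAML).
#' @export
as_run_config <- function(x) {
  known <- c("seed", "community", "sweep", "control", "tie_tol", "scenarios",
             "output_dir", "log_level")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$community)) stop("config must define a community", call. = FALSE)
  comm <- as_community(dplyr::bind_rows(purrr::map(x$community, tibble::as_tibble)))

  sweep <- x$sweep %||% list()
  unknown <- setdiff(names(sweep), c("t_start", "t_end", "step"))
  if (length(unknown)) {
    stop("unknown sweep keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  # YAML 1.1 parses exponent literals without a sign (1.0e4) as strings;
  # coerce every numeric field defensively
  sweep <- list(t_start = as.numeric(sweep$t_start %||% 25),
                t_end = as.numeric(sweep$t_end %||% 45),
                step = as.numeric(sweep$step %||% 0.1))
  # validates t_start < t_end, step > 0
  temperature_grid(sweep$t_start, sweep$t_end, sweep$step)

  ctl <- x$control %||% list()
  unknown <- setdiff(names(ctl),
                     c("deriv_tol", "horizon", "extinction_tol", "rtol", "atol"))
  if (length(unknown)) {
    stop("unknown control keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  control <- do.call(steady_control, lapply(ctl, as.numeric))

  seed <- as.integer(x$seed %||% 1L)
  scn <- NULL
  if (!is.null(x$scenarios)) {
    s <- x$scenarios
    unknown <- setdiff(names(s), c("skew_range", "spacing_range",
                                   "r_peak_range", "normalize", "axes",
                                   "n_draws", "include_pairwise",
                                   "spacing_scale"))
    if (length(unknown)) {
      stop("unknown scenarios keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    scn <- scenario_spec(
      base_community = comm,
      skew_range = as.numeric(s$skew_range %||% c(0.05, 0.8)),
      spacing_range = as.numeric(s$spacing_range %||% c(2, 8)),
      r_peak_range = as.numeric(s$r_peak_range %||% c(0.5, 1.5)),
      normalize = s$normalize %||% TRUE,
      axes = unlist(s$axes) %||% c("skewness", "spacing", "normalization"),
      n_draws = s$n_draws %||% 10,
      include_pairwise = s$include_pairwise %||% TRUE,
      spacing_scale = s$spacing_scale %||% "linear",
      seed = seed
    )
  }

  structure(
    list(community = comm, sweep = sweep, control = control,
         tie_tol = as.numeric(x$tie_tol %||% 1e-6), scenarios = scn,
         seed = seed,
         output_dir = x$output_dir %||% ".",
         log_level = x$log_level %||% "info"),
    class = "run_config"
  )
}

run_config_to_list <- function(config) {
  list(
    seed = config$seed,
    community = purrr::pmap(config$community, function(...) list(...)),
    sweep = config$sweep,
    control = unclass(config$control),
    tie_tol = config$tie_tol,
    scenarios = if (!is.null(config$scenarios)) {
      s <- config$scenarios
      list(skew_range = s$skew_range, spacing_range = s$spacing_range,
           r_peak_range = s$r_peak_range, normalize = s$normalize,
           axes = s$axes, n_draws = s$n_draws,
           include_pairwise = s$include_pairwise,
           spacing_scale = s$spacing_scale)
    },
    output_dir = config$output_dir,
    log_level = config$log_level
  )
}

#' Write a run configuration back to YAML
#'
#' The written file re-parses to an equivalent `run_config` (round-trip
#' contract used by the run manifest).
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(run_config_to_list(config), path)
  invisible(path)
}

tc_log <- function(config_level, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[config_level %||% "info"]]) {
    message("[", toupper(level), "] ", ...)
  }
}

write_manifest <- function(config, dir, extra = list()) {
  manifest <- c(
    list(
      package = "thermocompete",
      package_version = as.character(utils::packageVersion("thermocompete")),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    extra,
    list(config = run_config_to_list(config))
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}

resolve_config <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    if (!is.null(config$scenarios)) config$scenarios$seed <- as.integer(seed)
  }
  if (!is.null(out_dir)) config$output_dir <- out_dir
  config
}

#' Run the temperature sweep stage from a configuration
#'
#' Sweeps the configured community across the configured grid and writes
#' `community_sweep.tsv` plus `manifest.yaml` (config echo, seed, versions,
#' timestamp) into the output directory.  Partial outputs are removed on
#' failure.
#'
#' @param config Path to a YAML config or a `run_config` object.
#' @param seed Optional seed override.
#' @param out_dir Optional output-directory override.
#' @return Invisibly, a list with `status` (0 on success), `paths`, and the
#'   `lv_sweep` object.
#' @export
cmd_sweep <- function(config, seed = NULL, out_dir = NULL) {
  config <- resolve_config(config, seed, out_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$output_dir,
                     c("community_sweep.tsv", "manifest.yaml"))
  on_fail <- function(e) {
    unlink(paths)
    stop("sweep run failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    tc_log(config$log_level, "info", "sweeping ", nrow(config$community),
           " species over [", config$sweep$t_start, ", ", config$sweep$t_end,
           "] degC, step ", config$sweep$step)
    sw <- run_temperature_sweep(
      config$community, config$sweep$t_start, config$sweep$t_end,
      config$sweep$step, config$control, config$tie_tol
    )
    write_sweep_tsv(sw, paths[1], scenario_id = "community")
    write_manifest(config, config$output_dir,
                   extra = list(stage = "sweep", seed = config$seed))
    tc_log(config$log_level, "info", "wrote ", paths[1])
    invisible(list(status = 0L, paths = paths, sweep = sw))
  }, error = on_fail)
}

#' Run the robustness-ensemble stage from a configuration
#'
#' Generates the seeded scenario ensemble, evaluates every scenario's sweep,
#' and writes `ensemble_sweep.tsv` (per scenario x temperature x species),
#' `robustness_scenarios.tsv`, `robustness_summary.tsv` and `manifest.yaml`.
#' Per-scenario failures are logged and counted; the run continues.
#'
#' @inheritParams cmd_sweep
#' @return Invisibly, a list with `status`, `paths`, and the
#'   `robustness_summary`.
#' @export
cmd_robustness <- function(config, seed = NULL, out_dir = NULL) {
  config <- resolve_config(config, seed, out_dir)
  if (is.null(config$scenarios)) {
    stop("config has no scenarios block", call. = FALSE)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$output_dir,
                     c("ensemble_sweep.tsv", "robustness_scenarios.tsv",
                       "robustness_summary.tsv", "manifest.yaml"))
  on_fail <- function(e) {
    unlink(paths)
    stop("robustness run failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    scn <- generate_scenarios(config$scenarios)
    tc_log(config$log_level, "info", nrow(scn), " scenarios generated (",
           attr(scn, "rejections"), " rejected draws)")
    summ <- evaluate_robustness(
      scn, config$sweep$t_start, config$sweep$t_end, config$sweep$step,
      config$control, config$tie_tol
    )
    readr::write_tsv(summ$details, paths[1])
    readr::write_tsv(tidy(summ), paths[2])
    readr::write_tsv(glance(summ), paths[3])
    write_manifest(config, config$output_dir,
                   extra = list(stage = "robustness", seed = config$seed))
    tc_log(config$log_level, "info", "monotone hand-over in ",
           summ$n_monotone, "/", summ$n_scenarios, " scenarios")
    invisible(list(status = 0L, paths = paths, summary = summ))
  }, error = on_fail)
}
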