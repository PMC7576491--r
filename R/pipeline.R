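# Pipeline commands tying the stages together: fixture generation, full
# analysis (summaries, I/O ratios, diagnostics, risks, Monte Carlo) and
# simulation-only runs. Each command takes a run config (a named list, or a
# YAML file via read_run_config) and writes plain-CSV reports plus an
# effective-config echo sufficient to reproduce the run.

RUN_CONFIG_KEYS <- c("seed", "out_dir", "samples", "participants",
                     "n_iterations", "seasons", "tef", "exclude",
                     "acceptable_risk", "generator", "overwrite")

#' Default run configuration
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param out_dir Output directory for reports.
#' @param ... Overrides for any config key (`samples`, `participants`,
#'   `n_iterations`, `seasons`, `tef`, `exclude`, `acceptable_risk`,
#'   `generator`, `overwrite`).
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("pahrisk-"),
                               ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    samples = NULL,
    participants = NULL,
    n_iterations = 10000L,
    seasons = SEASONS,
    tef = NULL,
    exclude = NULL,
    acceptable_risk = 1e-6,
    generator = list(),
    overwrite = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file with any subset of the run-config keys.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(default_run_config, raw)
}

config_registry <- function(config) {
  reg_cfg <- list()
  if (!is.null(config$tef)) reg_cfg$tef <- config$tef
  if (!is.null(config$exclude)) reg_cfg$exclude <- config$exclude
  if (length(reg_cfg)) load_registry(reg_cfg, merge = TRUE) else
    load_registry()
}

echo_effective_config <- function(config, out_dir) {
  echo <- unclass(config)
  echo$out_dir <- out_dir
  yaml::write_yaml(echo, file.path(out_dir, "effective_config.yaml"))
}

#' Generate and write a fixture bundle
#'
#' Delegates to the synthetic-data generator with the config seed (plus any
#' `generator` overrides) and writes the bundle into `out_dir`.
#'
#' @param config A `run_config` (or path to one).
#' @return Named vector of written paths, invisibly.
#' @export
cmd_make_fixtures <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  gen_args <- c(list(seed = config$seed), config$generator)
  spec <- do.call(generator_spec, gen_args)
  cohort <- generate_cohort(spec)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_fixture_bundle(cohort, config$out_dir,
                                overwrite = isTRUE(config$overwrite))
  echo_effective_config(config, config$out_dir)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Reads the sample and participant tables, applies the personal-sample
#' validity rule, and writes: seasonal summaries, the indoor/outdoor ratio
#' table, the diagnostic-ratio scatter table, the per-participant risk table
#' and the Monte Carlo report -- all as CSV under `out_dir`, together with an
#' `effective_config.yaml` echo.
#'
#' @param config A `run_config` with `samples` and `participants` paths set
#'   (defaults to `samples.csv` / `participants.csv` in `out_dir`, as written
#'   by [cmd_make_fixtures()]).
#' @return Named list of output paths, invisibly.
#' @export
cmd_analyze <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  registry <- config_registry(config)
  samples_path <- config$samples %||% file.path(config$out_dir,
                                                "samples.csv")
  participants_path <- config$participants %||%
    file.path(config$out_dir, "participants.csv")
  samples <- read_pah_samples(samples_path, registry)
  if (nrow(samples) == 0L) {
    stop("samples file ", samples_path, " contains no rows", call. = FALSE)
  }
  participants <- read_participants(participants_path)
  samples <- filter_valid_personal(samples)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # seasonal summaries
  summaries <- lapply(intersect(config$seasons, unique(samples$season)),
                      function(s) season_summary(samples, s, registry))
  summary_rows <- do.call(rbind, lapply(summaries, function(s) {
    cbind(season = s$season, n = s$n, s$stats,
          pah_pm_fraction = s$pah_pm_fraction)
  }))
  if (length(summaries) == 2L) {
    fold <- data.frame(
      season = "ratio", n = NA, metric = "sigma_pah_fold_change",
      mean = season_ratio(summaries[[1]], summaries[[2]], "sigma_pah"),
      sd = NA, min = NA, max = NA,
      pah_pm_fraction = season_ratio(summaries[[1]], summaries[[2]],
                                     "pah_pm_fraction"))
    summary_rows <- rbind(summary_rows, fold)
  }

  # per-participant deterministic risk: exposure = own personal sample BaPeq
  personal <- samples[samples$sampler_kind == "personal", , drop = FALSE]
  bapeq <- setNames(bapeq_by_sample(personal, registry),
                    personal$participant_id)
  measured <- participants[participants$participant_id %in% names(bapeq), ,
                           drop = FALSE]
  risk <- per_participant_risk(measured, bapeq)

  # Monte Carlo per season
  mc <- lapply(config$seasons, function(s) {
    simulation_report(run_ilcr_simulation(
      ilcr_scenario(s, n_iterations = config$n_iterations,
                    seed = config$seed,
                    acceptable_risk = config$acceptable_risk)),
      threshold = config$acceptable_risk)
  })

  paths <- list(
    summaries = file.path(config$out_dir, "season_summaries.csv"),
    io_ratios = file.path(config$out_dir, "io_ratios.csv"),
    diagnostics = file.path(config$out_dir, "diagnostics.csv"),
    risk = file.path(config$out_dir, "participant_risk.csv"),
    mc_stats = file.path(config$out_dir, "monte_carlo_stats.csv"),
    mc_hist = file.path(config$out_dir, "monte_carlo_histogram.csv")
  )
  write.csv(summary_rows, paths$summaries, row.names = FALSE)
  write.csv(io_ratio_table(samples, registry), paths$io_ratios,
            row.names = FALSE)
  write.csv(source_scatter(samples), paths$diagnostics, row.names = FALSE)
  write.csv(as.data.frame(risk), paths$risk, row.names = FALSE)
  write.csv(do.call(rbind, lapply(mc, `[[`, "stats")), paths$mc_stats,
            row.names = FALSE)
  write.csv(do.call(rbind, lapply(mc, `[[`, "histogram")), paths$mc_hist,
            row.names = FALSE)
  echo_effective_config(config, config$out_dir)
  invisible(paths)
}

#' Run the Monte Carlo simulation only
#'
#' No sample files needed; simulates the configured seasons from the scenario
#' defaults and writes the report CSVs.
#'
#' @param config A `run_config`.
#' @return Named list of output paths, invisibly.
#' @export
cmd_simulate <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (length(config$seasons) == 0L) {
    stop("config lists no seasons to simulate", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  mc <- lapply(config$seasons, function(s) {
    simulation_report(run_ilcr_simulation(
      ilcr_scenario(s, n_iterations = config$n_iterations,
                    seed = config$seed,
                    acceptable_risk = config$acceptable_risk)),
      threshold = config$acceptable_risk)
  })
  paths <- list(
    mc_stats = file.path(config$out_dir, "monte_carlo_stats.csv"),
    mc_hist = file.path(config$out_dir, "monte_carlo_histogram.csv")
  )
  write.csv(do.call(rbind, lapply(mc, `[[`, "stats")), paths$mc_stats,
            row.names = FALSE)
  write.csv(do.call(rbind, lapply(mc, `[[`, "histogram")), paths$mc_hist,
            row.names = FALSE)
  echo_effective_config(config, config$out_dir)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
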