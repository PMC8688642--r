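#' Run the full analysis pipeline and write its outputs
#'
#' Loads and validates a configuration, runs the paired scenarios for `R`
#' replicates, optionally runs a quit-proportion sweep, and writes:
#'
#' * `replicate_results.csv` — one row per scenario x replicate x tally
#'   group (overall plus each sex x race/ethnicity cell);
#' * `table_scenarios.csv` — per-scenario MI/stroke rates per million and
#'   cost per person with 95% percentile CIs, plus averted cases and
#'   savings columns;
#' * `table_subgroups.csv` — six subgroup rows of percent reductions and
#'   per-person savings;
#' * `table_sweep.csv` — averted cases per million versus quit proportion
#'   (when `sweep` is given);
#' * `summary.json` — all headline numbers;
#' * `manifest.json` — config hash, seed, sizes, scenario list, package
#'   version and timestamp; reruns with identical manifest fields (apart
#'   from the timestamp) reproduce the outputs byte for byte.
#'
#' @param config Path to a YAML configuration or a validated
#'   `menthol_config` (default: the shipped configuration).
#' @param n,horizon,replicates Cohort size, horizon in years and replicate
#'   count; defaults from the configuration's `simulation` section.
#' @param seed Integer base seed for all randomness.
#' @param quit_proportion Optional override of the ban scenario's quit
#'   proportion.
#' @param discount_rate Optional override of the cost discount rate.
#' @param sweep Optional numeric vector of quit proportions for the
#'   averted-cases sweep.
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with the `menthol_report`, the replicate
#'   results tibble, the sweep tibble (or `NULL`) and the manifest.
#' @export
run_pipeline <- function(config = default_config_path(), n = NULL,
                         horizon = NULL, replicates = NULL, seed = 1L,
                         quit_proportion = NULL, discount_rate = NULL,
                         sweep = NULL, outdir = ".") {
  config <- validate_config(config)
  if (!is.null(discount_rate)) {
    config$costs$discount_rate <- discount_rate
    config <- validate_config(unclass_config(config))
  }
  scenarios <- config_scenarios(config)
  if (!is.null(quit_proportion)) {
    scenarios <- lapply(scenarios, function(sc) {
      if (sc$quit_proportion > 0) {
        policy_scenario(sc$name, quit_proportion, sc$start_year_index)
      } else {
        sc
      }
    })
  }
  if (is.null(n)) n <- config$simulation$n
  if (is.null(horizon)) horizon <- config$simulation$horizon_years
  if (is.null(replicates)) replicates <- config$simulation$replicates

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  message(sprintf("running %d replicates of %d scenarios (n=%d, horizon=%d)",
                  replicates, length(scenarios), n, horizon))
  t0 <- Sys.time()
  results <- run_replicates(config, scenarios, n = n, horizon = horizon,
                            base_seed = seed, R = replicates)
  message(sprintf("simulation finished in %.1f s (%.2f s/replicate)",
                  as.numeric(Sys.time() - t0, units = "secs"),
                  as.numeric(Sys.time() - t0, units = "secs") / replicates))

  sq_name <- scenarios[[1]]$name
  ban_name <- scenarios[[length(scenarios)]]$name
  report <- comparison_report(results, status_quo = sq_name, ban = ban_name,
                              population = config$population$adult_smokers)

  sweep_tab <- NULL
  if (!is.null(sweep)) {
    message("running quit-proportion sweep: ",
            paste(sweep, collapse = ", "))
    sweep_tab <- quit_proportion_sweep(config, sweep, n = n,
                                       horizon = horizon, base_seed = seed,
                                       R = max(5L, replicates %/% 10L))
  }

  write.csv(results, file.path(outdir, "replicate_results.csv"),
            row.names = FALSE)
  scen_tab <- dplyr::left_join(
    report$scenarios,
    tidyr::pivot_longer(report$comparison[, c("ban", "averted_mi_per_million",
                                              "averted_stroke_per_million",
                                              "per_person_saving")],
                        cols = -"ban", names_to = "metric") |>
      tidyr::pivot_wider(names_from = "metric") |>
      dplyr::rename(scenario = "ban"),
    by = "scenario"
  )
  write.csv(scen_tab, file.path(outdir, "table_scenarios.csv"),
            row.names = FALSE)
  write.csv(report$subgroups, file.path(outdir, "table_subgroups.csv"),
            row.names = FALSE)
  if (!is.null(sweep_tab)) {
    write.csv(sweep_tab, file.path(outdir, "table_sweep.csv"),
              row.names = FALSE)
  }

  cmp <- report$comparison
  summary <- list(
    mi_per_million = as.list(setNames(report$scenarios$mi_per_million,
                                      report$scenarios$scenario)),
    stroke_per_million = as.list(setNames(report$scenarios$stroke_per_million,
                                          report$scenarios$scenario)),
    cost_per_person = as.list(setNames(report$scenarios$cost_per_person,
                                       report$scenarios$scenario)),
    averted_mi_per_million = cmp$averted_mi_per_million,
    averted_stroke_per_million = cmp$averted_stroke_per_million,
    mi_percent_reduction = cmp$mi_percent_reduction,
    stroke_percent_reduction = cmp$stroke_percent_reduction,
    per_person_saving = cmp$per_person_saving,
    total_saving = cmp$total_saving
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    config_hash = config_hash(config),
    seed = seed, n = n, horizon = horizon, replicates = replicates,
    scenarios = vapply(scenarios, function(s) s$name, character(1)),
    quit_proportions = vapply(scenarios, function(s) s$quit_proportion,
                              numeric(1)),
    discount_rate = config$costs$discount_rate,
    package_version = as.character(packageVersion("mentholsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(report = report, results = results, sweep = sweep_tab,
                 manifest = manifest))
}

unclass_config <- function(config) {
  config$population$strata_weights_matrix <- NULL
  config$population$menthol_prevalence_matrix <- NULL
  config$population$diabetes_prevalence_matrix <- NULL
  config$population$age_band_table <- NULL
  config$life_table_tables <- NULL
  config$coefficients_parsed <- NULL
  config$costs$background_table <- NULL
  unclass(config)
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper around [run_pipeline()], used by the
#' `inst/scripts/mentholsim.R` launcher.  Exit codes: 0 success, 2
#' configuration error, 3 runtime error, 4 I/O error.
#'
#' @param argv Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Integer exit code.
#' @export
mentholsim_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--config", type = "character",
                          default = default_config_path()),
    optparse::make_option("--n", type = "integer", default = NULL),
    optparse::make_option("--horizon", type = "integer", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--replicates", type = "integer", default = NULL),
    optparse::make_option("--quit-proportion", type = "double",
                          default = NULL, dest = "quit_proportion"),
    optparse::make_option("--discount-rate", type = "double",
                          default = NULL, dest = "discount_rate"),
    optparse::make_option("--sweep", type = "character", default = NULL,
                          help = "comma-separated quit proportions"),
    optparse::make_option("--outdir", type = "character", default = ".")
  )
  opts <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = argv),
    error = function(e) {
      message("argument error: ", conditionMessage(e))
      NULL
    }
  )
  if (is.null(opts)) return(2L)
  sweep <- if (!is.null(opts$sweep)) {
    as.numeric(strsplit(opts$sweep, ",")[[1]])
  }
  tryCatch({
    run_pipeline(config = opts$config, n = opts$n, horizon = opts$horizon,
                 replicates = opts$replicates, seed = opts$seed,
                 quit_proportion = opts$quit_proportion,
                 discount_rate = opts$discount_rate,
                 sweep = sweep, outdir = opts$outdir)
    0L
  },
  menthol_config_error = function(e) {
    message("configuration error: ", conditionMessage(e)); 2L
  },
  menthol_io_error = function(e) {
    message("I/O error: ", conditionMessage(e)); 4L
  },
  error = function(e) {
    message("runtime error: ", conditionMessage(e)); 3L
  })
}
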