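#' Bundle the transition models from a configuration
#'
#' Collects the three annual risk equations (MI, stroke, CVD death), the
#' non-CVD life table and the cost parameters into the model list consumed
#' by [run_year()] and [run_scenario()].
#'
#' @param config A validated `menthol_config`.
#' @return A list with elements `coefficients`, `life_table`, `costs`.
#' @export
build_models <- function(config) {
  stopifnot(inherits(config, "menthol_config"))
  list(
    coefficients = config$coefficients_parsed,
    life_table = config$life_table_tables,
    costs = config$costs
  )
}

# Deterministic 32-bit sub-seed derivation (Lehmer-style mixing); keeps all
# derived seeds inside R's integer range.
derive_seed <- function(base, k) {
  as.integer((as.numeric(base) * 48271 + as.numeric(k) * 16807 + 12345) %%
               2147483629)
}

N_TRANSITIONS <- 4L # non-CVD death, CVD death, MI, stroke

# Uniform draws for every (person, transition, year) triple, generated in a
# fixed layout so that paired scenarios sharing `event_seed` reuse identical
# uniforms (common random numbers).
event_uniforms <- function(n, horizon, event_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(event_seed)
  matrix(runif(n * N_TRANSITIONS * horizon), nrow = n)
}

#' Advance a cohort by one simulated year
#'
#' For each living person, in fixed order: (1) draw non-CVD death; (2) draw
#' CVD death; (3) draw incident MI if no prior MI; (4) draw incident stroke
#' if no prior stroke; (5) accrue the year's discounted cost (survivors
#' only); (6) age by one year.  Each potential transition consumes the
#' uniform reserved for that (person, transition) pair, compared against
#' the transition probability (inverse-CDF rule), so a person's outcome
#' never depends on the order in which persons are processed.
#'
#' @param cohort Cohort tibble; a `death_cause` column is added on first
#'   use.
#' @param models Model list from [build_models()].
#' @param year_index Zero-based year index (used for discounting).
#' @param u An `n x 4` matrix of Uniform(0,1) draws, columns ordered
#'   (non-CVD death, CVD death, MI, stroke).
#' @return The cohort advanced one year.
#' @export
run_year <- function(cohort, models, year_index, u) {
  n <- nrow(cohort)
  stopifnot(is.matrix(u), nrow(u) == n, ncol(u) >= N_TRANSITIONS)
  if (is.null(cohort$death_cause)) {
    cohort$death_cause <- factor(rep("none", n),
                                 levels = c("none", "cvd", "non_cvd"))
  }
  alive <- cohort$alive

  q_nc <- non_cvd_death_probability(cohort$age, cohort$sex, models$life_table)
  die_nc <- alive & (u[, 1] < q_nc)

  p_cd <- annual_event_probability(cohort, models$coefficients$cvd_death)
  die_cvd <- alive & !die_nc & (u[, 2] < p_cd)

  survives <- alive & !die_nc & !die_cvd

  p_mi <- annual_event_probability(cohort, models$coefficients$mi)
  mi_event <- survives & !cohort$had_mi & (u[, 3] < p_mi)

  p_st <- annual_event_probability(cohort, models$coefficients$stroke)
  stroke_event <- survives & !cohort$had_stroke & (u[, 4] < p_st)

  # cost uses start-of-year condition flags; the dead accrue nothing
  cost <- annual_cost(cohort, mi_event, stroke_event, models$costs, year_index)
  cohort$discounted_cost <- cohort$discounted_cost + ifelse(survives, cost, 0)

  cohort$had_mi <- cohort$had_mi | mi_event
  cohort$had_stroke <- cohort$had_stroke | stroke_event
  dc <- as.character(cohort$death_cause)
  dc[die_nc] <- "non_cvd"
  dc[die_cvd] <- "cvd"
  cohort$death_cause <- factor(dc, levels = c("none", "cvd", "non_cvd"))
  cohort$alive <- cohort$alive & survives
  cohort$age <- cohort$age + ifelse(survives, 1, 0)
  cohort
}

summarise_cohort <- function(cohort) {
  overall <- tibble::tibble(
    group = "overall", sex = NA_character_, race_ethnicity = NA_character_,
    n_persons = nrow(cohort),
    mi = sum(cohort$had_mi),
    stroke = sum(cohort$had_stroke),
    cvd_deaths = sum(cohort$death_cause == "cvd"),
    noncvd_deaths = sum(cohort$death_cause == "non_cvd"),
    alive = sum(cohort$alive),
    total_discounted_cost = sum(cohort$discounted_cost)
  )
  cells <- cohort |>
    dplyr::group_by(.data$sex, .data$race_ethnicity, .drop = FALSE) |>
    dplyr::summarise(
      n_persons = dplyr::n(),
      mi = sum(.data$had_mi),
      stroke = sum(.data$had_stroke),
      cvd_deaths = sum(.data$death_cause == "cvd"),
      noncvd_deaths = sum(.data$death_cause == "non_cvd"),
      alive = sum(.data$alive),
      total_discounted_cost = sum(.data$discounted_cost),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = "cell",
                  sex = as.character(.data$sex),
                  race_ethnicity = as.character(.data$race_ethnicity)) |>
    dplyr::relocate("group")
  dplyr::bind_rows(overall, cells)
}

#' Run one scenario over the full horizon
#'
#' Generates the cohort from `(config, seed)`, applies the policy at its
#' start year, advances the cohort one year at a time for `horizon` years
#' and returns the cumulative tallies, overall and per sex x race/ethnicity
#' cell.  All randomness derives from `seed`: the cohort, the policy quit
#' draws and the event draws each use a deterministic sub-seed, so two
#' scenarios run with the same `seed` share the same cohort and the same
#' event uniforms (common random numbers) and differ only through the
#' policy.
#'
#' @param config A validated `menthol_config`.
#' @param scenario A [policy_scenario()].
#' @param n Cohort size (default: configuration `simulation.n`).
#' @param horizon Number of simulated years (default: configuration
#'   `simulation.horizon_years`).
#' @param seed Integer seed.
#' @param replicate_id Replicate label carried into the result.
#' @param models Optional pre-built model list (see [build_models()]);
#'   pass one to override e.g. the discount rate without editing `config`.
#' @return A `scenario_result`: list with `scenario`, `replicate_id`, `n`,
#'   `horizon`, `summary` (tally tibble) and `cohort` (final state).
#' @examples
#' cfg <- default_config()
#' res <- run_scenario(cfg, policy_scenario("ban", 0.212), n = 500,
#'                     horizon = 5, seed = 1)
#' tidy(res)
#' @export
run_scenario <- function(config, scenario, n = NULL, horizon = NULL, seed,
                         replicate_id = 1L, models = NULL) {
  stopifnot(inherits(config, "menthol_config"),
            inherits(scenario, "policy_scenario"))
  if (is.null(n)) n <- config$simulation$n
  if (is.null(horizon)) horizon <- config$simulation$horizon_years
  n <- as.integer(n); horizon <- as.integer(horizon)
  if (n < 1) abort("n must be >= 1", class = "menthol_domain_error")
  if (horizon < 0) abort("horizon must be >= 0", class = "menthol_domain_error")
  if (is.null(models)) models <- build_models(config)

  cohort_seed <- derive_seed(seed, 1)
  quit_seed <- derive_seed(seed, 2)
  event_seed <- derive_seed(seed, 3)

  cohort <- generate_population(config, n, cohort_seed)
  cohort$death_cause <- factor(rep("none", n),
                               levels = c("none", "cvd", "non_cvd"))

  if (horizon > 0) {
    u_all <- event_uniforms(n, horizon, event_seed)
    u_quit <- event_uniforms(n, 1, quit_seed)[, 1]
    for (year in seq_len(horizon) - 1L) {
      if (year == scenario$start_year_index) {
        cohort <- apply_policy(cohort, scenario, u = u_quit)
      }
      cols <- year * N_TRANSITIONS + seq_len(N_TRANSITIONS)
      cohort <- run_year(cohort, models, year, u_all[, cols, drop = FALSE])
    }
  }

  structure(
    list(scenario = scenario$name,
         quit_proportion = scenario$quit_proportion,
         replicate_id = as.integer(replicate_id),
         n = n, horizon = horizon,
         summary = summarise_cohort(cohort),
         cohort = cohort),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  ov <- x$summary[x$summary$group == "overall", ]
  cat("<scenario_result> ", x$scenario,
      " (replicate ", x$replicate_id, ")\n", sep = "")
  cat(sprintf("  n = %d, horizon = %d years\n", x$n, x$horizon))
  cat(sprintf("  MI %d | stroke %d | CVD deaths %d | non-CVD deaths %d\n",
              ov$mi, ov$stroke, ov$cvd_deaths, ov$noncvd_deaths))
  cat(sprintf("  mean discounted cost $%.0f\n", ov$total_discounted_cost / x$n))
  invisible(x)
}

#' @describeIn run_scenario Tidy a scenario result into one row per tally
#'   group (overall plus each sex x race/ethnicity cell).
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(scenario = x$scenario, replicate = x$replicate_id,
                   n_simulated = x$n, horizon_years = x$horizon),
    x$summary
  )
}

#' Run replicated paired scenarios
#'
#' Runs `R` independent replicates of every scenario.  Replicate `r` uses a
#' seed derived deterministically from `base_seed`, shared by all scenarios
#' within the replicate, so scenarios are paired by common random numbers:
#' they see the same cohort and the same event uniforms, and differ only
#' through the policy.
#'
#' @param config A validated `menthol_config`.
#' @param scenarios List of [policy_scenario()] objects; defaults to the
#'   configuration's `scenarios` section.
#' @param n,horizon Cohort size and horizon (defaults from the
#'   configuration).
#' @param base_seed Integer seed from which per-replicate seeds derive.
#' @param R Number of replicates.
#' @param models Optional pre-built model list passed to [run_scenario()].
#' @return A tibble with one row per scenario x replicate x tally group
#'   (the `overall` row plus one per sex x race/ethnicity cell), columns as
#'   in [tidy.scenario_result()].
#' @examples
#' cfg <- default_config()
#' run_replicates(cfg, n = 200, horizon = 3, base_seed = 1, R = 2)
#' @export
run_replicates <- function(config, scenarios = NULL, n = NULL, horizon = NULL,
                           base_seed, R = 1L, models = NULL) {
  stopifnot(R >= 1)
  if (is.null(scenarios)) scenarios <- config_scenarios(config)
  if (is.null(models)) models <- build_models(config)
  purrr::map_dfr(seq_len(R), function(r) {
    rep_seed <- derive_seed(base_seed, 1000 + r)
    purrr::map_dfr(scenarios, function(sc) {
      tidy(run_scenario(config, sc, n = n, horizon = horizon,
                        seed = rep_seed, replicate_id = r, models = models))
    })
  })
}

#' Scenarios declared in a configuration
#'
#' @param config A validated `menthol_config`.
#' @return List of [policy_scenario()] objects.
#' @export
config_scenarios <- function(config) {
  lapply(config$scenarios, function(sc) {
    policy_scenario(sc$name, sc$quit_proportion,
                    sc$start_year_index %||% 0L)
  })
}
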