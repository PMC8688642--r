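#' Scale an event tally to a rate per million adults
#'
#' @param count Event count (may be a replicate mean, hence fractional).
#' @param n_simulated Cohort size the count came from.
#' @return `count * 1e6 / n_simulated`.
#' @examples
#' per_million(572, 10000) # 57200
#' @export
per_million <- function(count, n_simulated) {
  stopifnot(all(n_simulated >= 1))
  count * 1e6 / n_simulated
}

#' Averted cases and percent reduction between paired scenarios
#'
#' @param status_quo,ban Event rates (any common scale, conventionally per
#'   million) under the status-quo and intervention scenarios.
#' @return A tibble with columns `averted` (`status_quo - ban`) and
#'   `percent_reduction` (`100 * averted / status_quo`; `NA` when
#'   `status_quo` is 0).
#' @examples
#' averted_and_reduction(57232, 54370) # averted 2862, 5.0% reduction
#' @export
averted_and_reduction <- function(status_quo, ban) {
  averted <- status_quo - ban
  pct <- ifelse(status_quo > 0, 100 * averted / status_quo, NA_real_)
  tibble::tibble(averted = averted, percent_reduction = pct)
}

#' Per-person and total cost savings
#'
#' @param status_quo_per_person,ban_per_person Mean discounted cost per
#'   person under each scenario (USD).
#' @param population Number of adults the per-person saving scales to
#'   (default 880,000 NYC adult smokers).
#' @return A tibble with columns `per_person_saving` and `total_saving`.
#' @examples
#' cost_savings(41479, 39643, 880000) # $1836 per person, ~$1.62B total
#' @export
cost_savings <- function(status_quo_per_person, ban_per_person,
                         population = 880000) {
  stopifnot(all(population >= 0))
  d <- status_quo_per_person - ban_per_person
  tibble::tibble(per_person_saving = d, total_saving = d * population)
}

percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7)
}

overall_rows <- function(results) {
  results |>
    dplyr::filter(.data$group == "overall") |>
    dplyr::mutate(
      mi_pm = per_million(.data$mi, .data$n_simulated),
      stroke_pm = per_million(.data$stroke, .data$n_simulated),
      cost_pp = .data$total_discounted_cost / .data$n_simulated
    )
}

#' Headline comparison report for paired scenarios
#'
#' Aggregates a replicate results tibble (from [run_replicates()]) into the
#' headline quantities of the analysis: per-million MI and stroke rates
#' with 95% percentile confidence intervals per scenario, averted cases
#' per million, percent reductions, mean discounted cost per person with
#' CI, and per-person / total cost savings.  Averted quantities are
#' differences of replicate means; because scenarios are paired by common
#' random numbers these differences isolate the policy effect.
#'
#' @param results Tibble from [run_replicates()] containing both scenarios.
#' @param status_quo,ban Scenario names to compare.
#' @param population Population scalar for the total saving (default
#'   880,000).
#' @return An object of class `menthol_report` with elements `scenarios`
#'   (per-scenario rates and CIs), `comparison` (one-row tibble of averted
#'   cases, reductions and savings) and `subgroups` (see
#'   [subgroup_report()]).
#' @export
comparison_report <- function(results, status_quo = "status_quo",
                              ban = "menthol_ban", population = 880000) {
  ov <- overall_rows(results)
  missing <- setdiff(c(status_quo, ban), unique(ov$scenario))
  if (length(missing) > 0) {
    abort(paste0("results contain no scenario named: ",
                 paste(missing, collapse = ", ")),
          class = "menthol_domain_error")
  }
  scen <- ov |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      mi_per_million = mean(.data$mi_pm),
      mi_ci_lo = percentile_ci(.data$mi_pm)[1],
      mi_ci_hi = percentile_ci(.data$mi_pm)[2],
      stroke_per_million = mean(.data$stroke_pm),
      stroke_ci_lo = percentile_ci(.data$stroke_pm)[1],
      stroke_ci_hi = percentile_ci(.data$stroke_pm)[2],
      cost_per_person = mean(.data$cost_pp),
      cost_ci_lo = percentile_ci(.data$cost_pp)[1],
      cost_ci_hi = percentile_ci(.data$cost_pp)[2],
      .groups = "drop"
    )
  sq <- scen[scen$scenario == status_quo, ]
  bn <- scen[scen$scenario == ban, ]
  mi <- averted_and_reduction(sq$mi_per_million, bn$mi_per_million)
  st <- averted_and_reduction(sq$stroke_per_million, bn$stroke_per_million)
  sv <- cost_savings(sq$cost_per_person, bn$cost_per_person, population)
  comparison <- tibble::tibble(
    status_quo = status_quo, ban = ban, population = population,
    averted_mi_per_million = mi$averted,
    mi_percent_reduction = mi$percent_reduction,
    averted_stroke_per_million = st$averted,
    stroke_percent_reduction = st$percent_reduction,
    per_person_saving = sv$per_person_saving,
    total_saving = sv$total_saving
  )
  structure(
    list(scenarios = scen, comparison = comparison,
         subgroups = subgroup_report(results, status_quo = status_quo,
                                     ban = ban)),
    class = "menthol_report"
  )
}

#' @export
print.menthol_report <- function(x, ...) {
  cmp <- x$comparison
  cat("<menthol_report>\n")
  cat(sprintf("  averted MI:     %8.0f per million (%.1f%% reduction)\n",
              cmp$averted_mi_per_million, cmp$mi_percent_reduction))
  cat(sprintf("  averted stroke: %8.0f per million (%.1f%% reduction)\n",
              cmp$averted_stroke_per_million, cmp$stroke_percent_reduction))
  cat(sprintf("  saving: $%.0f per person, $%.2f billion over %s adults\n",
              cmp$per_person_saving, cmp$total_saving / 1e9,
              format(cmp$population, big.mark = ",")))
  invisible(x)
}

#' @describeIn comparison_report One row per scenario with rates and CIs.
#' @param x A `menthol_report`.
#' @param ... Unused.
#' @method tidy menthol_report
#' @export
tidy.menthol_report <- function(x, ...) x$scenarios

#' @describeIn comparison_report One-row tibble of the headline comparison.
#' @method glance menthol_report
#' @export
glance.menthol_report <- function(x, ...) x$comparison

#' Subgroup disparity report
#'
#' Per sex x race/ethnicity cell: percent reduction in MI and stroke
#' (within-cell, `100 * (status_quo - ban) / status_quo`, on replicate-mean
#' counts) and mean per-person discounted cost saving.  Cells with no
#' simulated persons are emitted with `NA` values and a warning.
#'
#' @param results Tibble from [run_replicates()].
#' @param status_quo,ban Scenario names to compare.
#' @return A tibble with one row per cell: `sex`, `race_ethnicity`,
#'   `n_persons`, `mi_status_quo`, `mi_ban`, `mi_reduction_pct`,
#'   `stroke_status_quo`, `stroke_ban`, `stroke_reduction_pct`,
#'   `saving_per_person`.
#' @export
subgroup_report <- function(results, status_quo = "status_quo",
                            ban = "menthol_ban") {
  cells <- results |>
    dplyr::filter(.data$group == "cell",
                  .data$scenario %in% c(status_quo, ban)) |>
    dplyr::group_by(.data$scenario, .data$sex, .data$race_ethnicity) |>
    dplyr::summarise(
      n_persons = mean(.data$n_persons),
      mi = mean(.data$mi),
      stroke = mean(.data$stroke),
      cost_pp = ifelse(mean(.data$n_persons) > 0,
                       mean(.data$total_discounted_cost) / mean(.data$n_persons),
                       NA_real_),
      .groups = "drop"
    )
  wide <- cells |>
    tidyr::pivot_wider(names_from = "scenario",
                       values_from = c("mi", "stroke", "cost_pp"),
                       names_sep = "...")
  sq <- function(col) wide[[paste0(col, "...", status_quo)]]
  bn <- function(col) wide[[paste0(col, "...", ban)]]
  out <- tibble::tibble(
    sex = wide$sex,
    race_ethnicity = wide$race_ethnicity,
    n_persons = wide$n_persons,
    mi_status_quo = sq("mi"),
    mi_ban = bn("mi"),
    mi_reduction_pct = ifelse(sq("mi") > 0,
                              100 * (sq("mi") - bn("mi")) / sq("mi"),
                              NA_real_),
    stroke_status_quo = sq("stroke"),
    stroke_ban = bn("stroke"),
    stroke_reduction_pct = ifelse(sq("stroke") > 0,
                                  100 * (sq("stroke") - bn("stroke")) / sq("stroke"),
                                  NA_real_),
    saving_per_person = sq("cost_pp") - bn("cost_pp")
  )
  if (any(out$n_persons == 0)) {
    warn(paste0("empty subgroup cell(s): ",
                paste(paste(out$sex[out$n_persons == 0],
                            out$race_ethnicity[out$n_persons == 0]),
                      collapse = "; ")))
  }
  out
}

#' Averted cases as a function of the quit proportion
#'
#' For each quit proportion, runs the ban scenario paired with the same
#' status-quo run under common random numbers and reports mean averted MI
#' and stroke cases per million across replicates.  Because quit draws use
#' shared uniforms, quitter sets are nested across proportions and the
#' averted curves are non-decreasing replicate by replicate.
#'
#' @param config A validated `menthol_config`.
#' @param proportions Quit proportions in \[0, 1\] to evaluate.
#' @param n,horizon Cohort size and horizon (defaults from `config`).
#' @param base_seed Integer seed.
#' @param R Replicates per proportion.
#' @return A tibble of class `menthol_sweep` with columns
#'   `quit_proportion`, `averted_mi_per_million`,
#'   `averted_stroke_per_million`.
#' @export
quit_proportion_sweep <- function(config, proportions = c(0, 0.1, 0.212, 0.3, 0.5),
                                  n = NULL, horizon = NULL, base_seed, R = 20L) {
  stopifnot(all(proportions >= 0 & proportions <= 1))
  models <- build_models(config)
  scenarios <- c(
    list(policy_scenario("status_quo", 0)),
    lapply(proportions, function(p) policy_scenario(paste0("quit_", p), p))
  )
  res <- run_replicates(config, scenarios, n = n, horizon = horizon,
                        base_seed = base_seed, R = R, models = models)
  ov <- overall_rows(res) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(mi_pm = mean(.data$mi_pm),
                     stroke_pm = mean(.data$stroke_pm), .groups = "drop")
  sq <- ov[ov$scenario == "status_quo", ]
  out <- tibble::tibble(
    quit_proportion = proportions,
    averted_mi_per_million = sq$mi_pm -
      ov$mi_pm[match(paste0("quit_", proportions), ov$scenario)],
    averted_stroke_per_million = sq$stroke_pm -
      ov$stroke_pm[match(paste0("quit_", proportions), ov$scenario)]
  )
  class(out) <- c("menthol_sweep", class(out))
  out
}

#' Cost-saving sensitivity to the discount rate
#'
#' Re-runs the paired scenarios at each discount rate (costs only; event
#' dynamics are identical across rates for a given seed) and reports the
#' mean per-person discounted saving.
#'
#' @param config A validated `menthol_config`.
#' @param rates Discount rates to evaluate (default 0 to 6%).
#' @param n,horizon Cohort size and horizon (defaults from `config`).
#' @param base_seed Integer seed.
#' @param R Replicates per rate.
#' @return A tibble with columns `discount_rate`, `saving_per_person`,
#'   `cost_per_person_status_quo`.
#' @export
discount_rate_sweep <- function(config, rates = c(0, 0.015, 0.03, 0.045, 0.06),
                                n = NULL, horizon = NULL, base_seed, R = 5L) {
  scenarios <- config_scenarios(config)
  purrr::map_dfr(rates, function(r) {
    models <- build_models(config)
    models$costs$discount_rate <- r
    res <- run_replicates(config, scenarios, n = n, horizon = horizon,
                          base_seed = base_seed, R = R, models = models)
    ov <- overall_rows(res) |>
      dplyr::group_by(.data$scenario) |>
      dplyr::summarise(cost_pp = mean(.data$cost_pp), .groups = "drop")
    tibble::tibble(
      discount_rate = r,
      saving_per_person = ov$cost_pp[ov$scenario == "status_quo"] -
        ov$cost_pp[ov$scenario == "menthol_ban"],
      cost_per_person_status_quo = ov$cost_pp[ov$scenario == "status_quo"]
    )
  })
}
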