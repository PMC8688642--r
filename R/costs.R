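#' Discount a cost to baseline dollars
#'
#' Divides an amount accrued in year `year_index` by
#' `(1 + rate)^year_index`, expressing it in base-year (year 0) dollars.
#' Year 0 is undiscounted.
#'
#' @param amount Cost(s) in nominal dollars.
#' @param year_index Non-negative year index (0 = base year); vectorized.
#' @param rate Annual discount rate as a proportion (default 0.03).
#' @return Discounted amount(s).
#' @examples
#' discount(100, 1, 0.03) # 97.087...
#' @export
discount <- function(amount, year_index, rate = 0.03) {
  if (any(year_index < 0)) {
    abort("year_index must be non-negative", class = "menthol_domain_error")
  }
  amount / (1 + rate)^year_index
}

#' Annual healthcare cost for a person-year
#'
#' The undiscounted cost of a person-year is the age-banded background cost
#' plus the one-time cost of any MI or stroke occurring this year plus the
#' ongoing annual cost of conditions established in earlier years; the
#' returned value is that total discounted to baseline.  `person` must hold
#' the start-of-year state, so its `had_mi` / `had_stroke` flags mark
#' previously established conditions, not this year's events.
#'
#' @param person Cohort tibble (start-of-year state).
#' @param mi_event,stroke_event Logical vectors: did the event occur this
#'   year (per person).  Scalars are recycled.
#' @param params The `costs` section of a validated configuration.
#' @param year_index Year index used for discounting.
#' @return Numeric vector of discounted costs, one per person.
#' @examples
#' cfg <- default_config()
#' p <- generate_population(cfg, n = 3, seed = 1)
#' annual_cost(p, mi_event = c(TRUE, FALSE, FALSE), stroke_event = FALSE,
#'             params = cfg$costs, year_index = 0)
#' @export
annual_cost <- function(person, mi_event = FALSE, stroke_event = FALSE,
                        params, year_index) {
  n <- nrow(person)
  mi_event <- rep_len(as.logical(mi_event), n)
  stroke_event <- rep_len(as.logical(stroke_event), n)
  bg_tab <- params$background_table
  if (is.null(bg_tab)) bg_tab <- band_table(params$background, "cost")
  i <- findInterval(person$age, bg_tab$lo)
  if (any(i < 1)) {
    abort("age below the background cost table", class = "menthol_config_error")
  }
  i[i > nrow(bg_tab)] <- nrow(bg_tab)
  undisc <- bg_tab$value[i] +
    mi_event * params$mi_event_cost +
    stroke_event * params$stroke_event_cost +
    person$had_mi * params$post_mi_annual_cost +
    person$had_stroke * params$post_stroke_annual_cost
  discount(undisc, year_index, params$discount_rate)
}
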