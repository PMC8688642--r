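#' Define a policy scenario
#'
#' A scenario names an intervention and the proportion of current menthol
#' smokers who quit when it takes effect.  The default quit proportion for
#' a menthol sales ban is 21.2%, the quit rate observed after Ontario's
#' provincial menthol ban; the remaining menthol smokers are assumed to
#' switch to non-menthol cigarettes (or obtain menthol elsewhere), which
#' leaves their modelled risk unchanged under the default coefficient
#' coding.
#'
#' @param name Scenario label.
#' @param quit_proportion Probability in \[0, 1\] that a current menthol
#'   smoker quits when the policy starts.
#' @param start_year_index Year index (0 = baseline) at which the policy is
#'   applied, before that year's event draws.
#' @return An object of class `policy_scenario`.
#' @export
policy_scenario <- function(name, quit_proportion, start_year_index = 0L) {
  quit_proportion <- as.numeric(quit_proportion)
  if (!is.finite(quit_proportion) || quit_proportion < 0 || quit_proportion > 1) {
    abort("quit_proportion must be in [0,1]", class = "menthol_config_error")
  }
  structure(
    list(name = as.character(name), quit_proportion = quit_proportion,
         start_year_index = as.integer(start_year_index)),
    class = "policy_scenario"
  )
}

#' Apply a policy scenario to a cohort
#'
#' Under a menthol ban, each current menthol smoker independently quits
#' (becomes `former`) with probability `quit_proportion`; menthol smokers
#' who do not quit switch to `current_nonmenthol`.  Persons who are not
#' current menthol smokers are returned unchanged, field for field.  A
#' `quit_proportion` of 0 is a null policy and returns the cohort exactly
#' as given.
#'
#' Quit draws use their own uniforms, independent of the event draws, so
#' paired scenarios on the same cohort share identical event randomness
#' (common random numbers).  For a fixed set of uniforms the quitter sets
#' are nested across quit proportions: person `i` quits iff
#' `u[i] < quit_proportion`.
#'
#' @param cohort Cohort tibble.
#' @param scenario A [policy_scenario()].
#' @param u Uniform(0,1) vector, one per person (the person's policy
#'   substream); drawn from the current RNG stream when omitted.
#' @return The transformed cohort tibble.
#' @export
apply_policy <- function(cohort, scenario, u = NULL) {
  stopifnot(inherits(scenario, "policy_scenario"))
  if (scenario$quit_proportion == 0) {
    return(cohort)
  }
  if (is.null(u)) u <- runif(nrow(cohort))
  menthol <- cohort$smoking_status == "current_menthol"
  quits <- menthol & (u < scenario$quit_proportion)
  status <- as.character(cohort$smoking_status)
  status[quits] <- "former"
  status[menthol & !quits] <- "current_nonmenthol"
  cohort$smoking_status <- factor(status, levels = SMOKING_LEVELS)
  cohort
}
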