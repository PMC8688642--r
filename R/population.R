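#' Generate a synthetic cohort of adult smokers
#'
#' Draws `n` simulated adult cigarette smokers from the generative model in
#' the configuration's `population` section: sex x race/ethnicity stratum
#' from the stratum weights, age uniformly within weighted age bands,
#' metabolic risk factors (BMI, SBP, LDL-C, HDL-C) from per-factor
#' parametric marginals (with an optional linear age trend for SBP),
#' diabetes and menthol use as Bernoulli draws with stratum-specific
#' probabilities.  Everyone starts as a current smoker (menthol or
#' non-menthol), alive, event-free, with zero accumulated cost.
#'
#' Generation is fully reproducible: the same `(spec, n, seed)` yields a
#' bitwise-identical cohort.  Risk factors are clamped to physiologic
#' ranges (BMI 12-80, SBP 70-260, LDL-C 20-400, HDL-C 10-150).
#'
#' @param spec A validated `menthol_config` (its `population` section is
#'   used) or the population section itself.
#' @param n Number of persons; defaults to the configuration's `n_default`.
#' @param seed Integer seed controlling every draw.
#' @return A tibble with one row per person and columns `person_id`, `age`,
#'   `sex`, `race_ethnicity`, `bmi`, `sbp`, `ldl_c`, `hdl_c`, `diabetes`,
#'   `smoking_status`, `alive`, `had_mi`, `had_stroke`, `discounted_cost`.
#' @examples
#' cohort <- generate_population(default_config(), n = 100, seed = 1)
#' dplyr::count(cohort, sex, race_ethnicity, smoking_status)
#' @export
generate_population <- function(spec, n = NULL, seed) {
  pop <- if (!is.null(spec$population)) spec$population else spec
  if (is.null(pop$strata_weights_matrix)) {
    abort("spec must be a validated configuration (see validate_config())",
          class = "menthol_config_error")
  }
  if (is.null(n)) n <- pop$n_default
  n <- as.integer(n)
  if (is.na(n) || n < 1) {
    abort("n must be a positive integer", class = "menthol_domain_error")
  }

  w <- pop$strata_weights_matrix
  cells <- expand.grid(sex = SEX_LEVELS, race = RACE_LEVELS,
                       stringsAsFactors = FALSE)
  cell_w <- mapply(function(s, r) w[s, r], cells$sex, cells$race)

  withr_seed <- function(code) { # localize RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    code
  }

  withr_seed({
    idx <- sample.int(nrow(cells), n, replace = TRUE, prob = cell_w)
    sex <- factor(cells$sex[idx], levels = SEX_LEVELS)
    race <- factor(cells$race[idx], levels = RACE_LEVELS)

    ages <- pop$age_band_table
    band <- sample.int(nrow(ages), n, replace = TRUE, prob = ages$value)
    age <- runif(n, ages$lo[band], ages$hi[band])

    draw_factor <- function(name) {
      d <- pop$risk_factors[[name]]
      x <- switch(d$family,
        normal = {
          mu <- as.numeric(d$mean)
          if (!is.null(d$age_slope)) {
            mu <- mu + as.numeric(d$age_slope) * (age - as.numeric(d$age_center %||% 45))
          }
          stats::rnorm(n, mu, as.numeric(d$sd))
        },
        lognormal = stats::rlnorm(n, as.numeric(d$meanlog), as.numeric(d$sdlog))
      )
      rng <- RISK_FACTOR_RANGES[[name]]
      lo <- as.numeric(d$min %||% rng[1])
      hi <- as.numeric(d$max %||% rng[2])
      pmin(pmax(x, max(lo, rng[1])), min(hi, rng[2]))
    }

    bmi <- draw_factor("bmi")
    sbp <- draw_factor("sbp")
    ldl <- draw_factor("ldl_c")
    hdl <- draw_factor("hdl_c")

    dm_p <- pop$diabetes_prevalence_matrix[cbind(as.character(sex), as.character(race))]
    diabetes <- runif(n) < dm_p

    smoking <- assign_menthol_status(sex, race, pop$menthol_prevalence_matrix,
                                     u = runif(n))

    tibble::tibble(
      person_id = seq_len(n),
      age = age,
      sex = sex,
      race_ethnicity = race,
      bmi = bmi,
      sbp = sbp,
      ldl_c = ldl,
      hdl_c = hdl,
      diabetes = diabetes,
      smoking_status = smoking,
      alive = TRUE,
      had_mi = FALSE,
      had_stroke = FALSE,
      discounted_cost = 0
    )
  })
}

#' Assign menthol versus non-menthol smoking status
#'
#' Each person becomes a current menthol smoker with the probability stored
#' in their sex x race/ethnicity cell of the prevalence matrix, otherwise a
#' current non-menthol smoker.
#'
#' @param sex,race_ethnicity Vectors (factor or character) of equal length.
#' @param menthol_prevalence A sex x race/ethnicity matrix of probabilities
#'   with `dimnames` `list(c("male","female"), c("nl_white","nl_black","latino"))`.
#' @param u Uniform(0,1) draws, one per person; drawn from the current RNG
#'   stream when omitted.
#' @return Factor with levels `current_menthol`, `current_nonmenthol`,
#'   `former` (the last never assigned here).
#' @export
assign_menthol_status <- function(sex, race_ethnicity, menthol_prevalence,
                                  u = NULL) {
  sex <- as.character(sex)
  race <- as.character(race_ethnicity)
  if (!all(sex %in% rownames(menthol_prevalence)) ||
      !all(race %in% colnames(menthol_prevalence))) {
    abort("menthol prevalence cell missing for some sex x race/ethnicity combination",
          class = "menthol_config_error")
  }
  p <- menthol_prevalence[cbind(sex, race)]
  if (anyNA(p)) {
    abort("menthol prevalence cell is NA for some sex x race/ethnicity combination",
          class = "menthol_config_error")
  }
  if (is.null(u)) u <- runif(length(p))
  factor(ifelse(u < p, "current_menthol", "current_nonmenthol"),
         levels = SMOKING_LEVELS)
}

#' Write or read a cohort as CSV
#'
#' One row per person, columns exactly the person-state fields, header
#' included.  Factors round-trip as their level labels.
#'
#' @param cohort A cohort tibble from [generate_population()].
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort[PERSON_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PERSON_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("cohort CSV missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "menthol_io_error")
  }
  out <- tibble::as_tibble(raw[PERSON_COLUMNS])
  out$sex <- factor(out$sex, levels = SEX_LEVELS)
  out$race_ethnicity <- factor(out$race_ethnicity, levels = RACE_LEVELS)
  out$smoking_status <- factor(out$smoking_status, levels = SMOKING_LEVELS)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
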