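#' Path to the default configuration shipped with the package
#'
#' @return Path to the default YAML configuration file.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "mentholsim",
              mustWork = TRUE)
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration describing the synthetic population, the
#' annual risk equations, the life table, the cost parameters and the
#' policy scenarios, validates every section, and returns it as a classed
#' list.  `default_config()` is shorthand for loading the configuration
#' shipped with the package.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration of class `menthol_config`.
#' @seealso [validate_config()] for the checks applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "menthol_config_error")
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort(paste0("config parse failure in '", path, "': ",
                   conditionMessage(e)),
            class = "menthol_config_error")
    }
  )
  validate_config(raw)
}

#' @rdname load_config
#' @export
default_config <- function() {
  load_config(default_config_path())
}

cell_names <- function() {
  unlist(lapply(SEX_LEVELS, function(s) paste(s, RACE_LEVELS, sep = ".")))
}

# Pull a sex x race matrix out of a nested list section; missing cells -> NA.
sex_race_matrix <- function(section) {
  m <- matrix(NA_real_, nrow = length(SEX_LEVELS), ncol = length(RACE_LEVELS),
              dimnames = list(SEX_LEVELS, RACE_LEVELS))
  for (s in SEX_LEVELS) {
    for (r in RACE_LEVELS) {
      v <- section[[s]][[r]]
      if (!is.null(v)) m[s, r] <- as.numeric(v)
    }
  }
  m
}

band_table <- function(rows, value_field) {
  tibble::tibble(
    lo = vapply(rows, function(b) as.numeric(b$lo), numeric(1)),
    hi = vapply(rows, function(b) as.numeric(b$hi), numeric(1)),
    value = vapply(rows, function(b) as.numeric(b[[value_field]]), numeric(1))
  )
}

check_partition <- function(tab, lo = 18, hi = 100) {
  nrow(tab) > 0 &&
    !is.unsorted(tab$lo, strictly = TRUE) &&
    isTRUE(all(tab$hi[-nrow(tab)] == tab$lo[-1])) &&
    tab$lo[1] == lo && tab$hi[nrow(tab)] == hi
}

#' Validate a configuration
#'
#' Checks every section of a configuration (population, coefficients, life
#' table, costs, scenarios, simulation) against its invariants: probabilities
#' in \[0, 1\], stratum weights summing to one, age bands partitioning their
#' range without gaps or overlaps, risk-equation covariates drawn from the
#' known person-state fields, finite coefficient values, and non-negative
#' costs with a discount rate in \[0, 0.10\].  All violations are collected
#' and reported together, each with a path-like locator such as
#' `population.menthol_prevalence.female.nl_black`.
#'
#' @param config A configuration list (parsed YAML) or a path to a YAML file.
#' @return The validated configuration, classed `menthol_config`, with
#'   matrix/tibble representations attached for internal use.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    return(load_config(config))
  }
  if (!is.list(config)) {
    abort("config must be a list or a file path", class = "menthol_config_error")
  }
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))

  for (sec in c("population", "coefficients", "life_table", "costs",
                "scenarios", "simulation")) {
    if (is.null(config[[sec]])) note("missing section: ", sec)
  }
  if (length(errs) > 0) {
    abort(paste0("invalid configuration:\n  ",
                 paste(errs, collapse = "\n  ")),
          class = "menthol_config_error")
  }

  pop <- config$population

  w <- sex_race_matrix(pop$strata_weights)
  if (anyNA(w)) {
    note("population.strata_weights: missing cell(s): ",
         paste(cell_names()[is.na(t(w))[RACE_LEVELS, SEX_LEVELS]], collapse = ", "))
  } else {
    if (any(w < 0 | w > 1)) {
      bad <- which(w < 0 | w > 1, arr.ind = TRUE)
      for (i in seq_len(nrow(bad))) {
        note("population.strata_weights.", SEX_LEVELS[bad[i, 1]], ".",
             RACE_LEVELS[bad[i, 2]], ": must be in [0,1], got ",
             w[bad[i, 1], bad[i, 2]])
      }
    }
    if (abs(sum(w) - 1) > 1e-9) {
      note("population.strata_weights: cells must sum to 1 (got ",
           format(sum(w), digits = 12), ")")
    }
  }

  for (nm in c("menthol_prevalence", "diabetes_prevalence")) {
    m <- sex_race_matrix(pop[[nm]])
    if (anyNA(m)) {
      note("population.", nm, ": missing cell(s)")
    } else if (any(m < 0 | m > 1)) {
      bad <- which(m < 0 | m > 1, arr.ind = TRUE)
      for (i in seq_len(nrow(bad))) {
        note("population.", nm, ".", SEX_LEVELS[bad[i, 1]], ".",
             RACE_LEVELS[bad[i, 2]], ": probability must be in [0,1], got ",
             m[bad[i, 1], bad[i, 2]])
      }
    }
  }

  ages <- band_table(pop$age_bands, "weight")
  if (any(ages$value < 0) || abs(sum(ages$value) - 1) > 1e-9) {
    note("population.age_bands: weights must be >= 0 and sum to 1")
  }
  if (any(ages$lo < 18)) note("population.age_bands: ages below 18 not allowed")
  if (any(ages$hi <= ages$lo)) note("population.age_bands: empty band")

  for (rf in c("bmi", "sbp", "ldl_c", "hdl_c")) {
    d <- pop$risk_factors[[rf]]
    if (is.null(d)) {
      note("population.risk_factors.", rf, ": missing")
    } else if (!d$family %in% c("normal", "lognormal")) {
      note("population.risk_factors.", rf, ".family: must be normal or lognormal")
    }
  }

  coefs <- list()
  for (oc in c("mi", "stroke", "cvd_death")) {
    sec <- config$coefficients[[oc]]
    if (is.null(sec)) {
      note("coefficients.", oc, ": missing")
      next
    }
    alpha <- as.numeric(sec$alpha)
    betas <- vapply(sec$betas, as.numeric, numeric(1))
    unknown <- setdiff(names(betas), RISK_COVARIATES)
    if (length(unknown) > 0) {
      note("coefficients.", oc, ".betas: unknown covariate(s): ",
           paste(unknown, collapse = ", "))
    }
    if (!is.finite(alpha) || !all(is.finite(betas))) {
      note("coefficients.", oc, ": all values must be finite")
    }
    coefs[[oc]] <- risk_coefficients(oc, alpha, as.list(betas),
                                     .validate = FALSE)
  }

  lt <- list()
  for (s in SEX_LEVELS) {
    rows <- config$life_table[[s]]
    if (is.null(rows)) {
      note("life_table.", s, ": missing")
      next
    }
    tab <- band_table(rows, "q")
    if (!check_partition(tab)) {
      note("life_table.", s, ": age bands must partition [18,100) with no gaps/overlaps")
    }
    if (any(tab$value < 0 | tab$value > 1)) {
      note("life_table.", s, ": probabilities must be in [0,1]")
    }
    lt[[s]] <- tab
  }

  costs <- config$costs
  bg <- band_table(costs$background, "cost")
  if (!check_partition(bg)) {
    note("costs.background: age bands must partition [18,100) with no gaps/overlaps")
  }
  for (nm in c("mi_event_cost", "stroke_event_cost", "post_mi_annual_cost",
               "post_stroke_annual_cost")) {
    v <- as.numeric(costs[[nm]])
    if (length(v) != 1 || !is.finite(v) || v < 0) {
      note("costs.", nm, ": must be a single non-negative number")
    }
  }
  if (any(bg$value < 0)) note("costs.background: costs must be >= 0")
  dr <- as.numeric(costs$discount_rate)
  if (!is.finite(dr) || dr < 0 || dr > 0.10) {
    note("costs.discount_rate: must be in [0, 0.10], got ", costs$discount_rate)
  }

  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    qp <- as.numeric(sc$quit_proportion)
    if (is.null(sc$name) || !nzchar(sc$name)) {
      note("scenarios[", i, "].name: required")
    }
    if (!is.finite(qp) || qp < 0 || qp > 1) {
      note("scenarios[", i, "].quit_proportion: must be in [0,1], got ",
           sc$quit_proportion)
    }
  }

  if (length(errs) > 0) {
    abort(paste0("invalid configuration:\n  ",
                 paste(errs, collapse = "\n  ")),
          class = "menthol_config_error")
  }

  config$population$strata_weights_matrix <- w / sum(w)
  config$population$menthol_prevalence_matrix <-
    sex_race_matrix(pop$menthol_prevalence)
  config$population$diabetes_prevalence_matrix <-
    sex_race_matrix(pop$diabetes_prevalence)
  config$population$age_band_table <- ages
  config$life_table_tables <- lt
  config$coefficients_parsed <- coefs
  config$costs$background_table <- bg
  class(config) <- c("menthol_config", "list")
  config
}

#' @export
print.menthol_config <- function(x, ...) {
  cat("<menthol_config>\n")
  cat("  default cohort size:", x$population$n_default, "\n")
  cat("  scenarios:",
      paste(vapply(x$scenarios, function(s) s$name, character(1)),
            collapse = ", "), "\n")
  cat("  horizon:", x$simulation$horizon_years, "years;",
      x$simulation$replicates, "replicates\n")
  invisible(x)
}

# Stable short hash of the configuration content for the run manifest.
config_hash <- function(config) {
  stripped <- unclass(config)
  stripped$population$strata_weights_matrix <- NULL
  stripped$population$menthol_prevalence_matrix <- NULL
  stripped$population$diabetes_prevalence_matrix <- NULL
  stripped$population$age_band_table <- NULL
  stripped$life_table_tables <- NULL
  stripped$coefficients_parsed <- NULL
  stripped$costs$background_table <- NULL
  rlang::hash(stripped)
}
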