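#' Construct an annual risk equation
#'
#' An annual transition probability in logistic form:
#' `P(event) = exp(eta) / (1 + exp(eta))` with
#' `eta = alpha + sum(beta[k] * x[k])`, where the covariates `x` are taken
#' from the person state.  Valid covariate names are `age`, `male`,
#' `female`, `nl_white`, `nl_black`, `latino`, `bmi`, `sbp`, `ldl_c`,
#' `hdl_c`, `diabetes`, `smoking_current`, `smoking_former`.
#'
#' @param outcome One of `"mi"`, `"stroke"`, `"cvd_death"`.
#' @param alpha Log-odds intercept.
#' @param betas Named list or vector of per-unit log-odds weights.
#' @param .validate Internal flag; leave as `TRUE`.
#' @return An object of class `risk_coefficients`.
#' @export
risk_coefficients <- function(outcome, alpha, betas, .validate = TRUE) {
  betas <- vapply(betas, as.numeric, numeric(1))
  if (.validate) {
    unknown <- setdiff(names(betas), RISK_COVARIATES)
    if (length(unknown) > 0) {
      abort(paste0("unknown covariate(s) in risk equation '", outcome, "': ",
                   paste(unknown, collapse = ", ")),
            class = "menthol_config_error")
    }
    if (!is.finite(alpha) || !all(is.finite(betas))) {
      abort(paste0("non-finite coefficient in risk equation '", outcome, "'"),
            class = "menthol_config_error")
    }
  }
  structure(list(outcome = outcome, alpha = as.numeric(alpha), betas = betas),
            class = "risk_coefficients")
}

# Covariate design matrix for a cohort, restricted to the requested names.
covariate_matrix <- function(cohort, names) {
  n <- nrow(cohort)
  cols <- lapply(names, function(nm) {
    switch(nm,
      age = cohort$age,
      male = as.numeric(cohort$sex == "male"),
      female = as.numeric(cohort$sex == "female"),
      nl_white = as.numeric(cohort$race_ethnicity == "nl_white"),
      nl_black = as.numeric(cohort$race_ethnicity == "nl_black"),
      latino = as.numeric(cohort$race_ethnicity == "latino"),
      bmi = cohort$bmi,
      sbp = cohort$sbp,
      ldl_c = cohort$ldl_c,
      hdl_c = cohort$hdl_c,
      diabetes = as.numeric(cohort$diabetes),
      smoking_current = as.numeric(cohort$smoking_status %in%
                                     c("current_menthol", "current_nonmenthol")),
      smoking_former = as.numeric(cohort$smoking_status == "former"),
      abort(paste0("unknown covariate: ", nm), class = "menthol_config_error")
    )
  })
  matrix(unlist(cols), nrow = n, dimnames = list(NULL, names))
}

#' Annual event probability from a logistic risk equation
#'
#' Evaluates `plogis(alpha + sum(beta * x))` for every person in the
#' cohort.  The computation uses the numerically stable log-sum form, so
#' linear predictors with magnitude up to several hundred neither overflow
#' nor collapse to exactly 0 or 1 prematurely.
#'
#' @param person A cohort tibble (one or more rows of person state).
#' @param coeffs A [risk_coefficients()] object.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @examples
#' cfg <- default_config()
#' cohort <- generate_population(cfg, n = 5, seed = 1)
#' annual_event_probability(cohort, cfg$coefficients_parsed$mi)
#' @export
annual_event_probability <- function(person, coeffs) {
  stopifnot(inherits(coeffs, "risk_coefficients"))
  if (length(coeffs$betas) == 0) {
    eta <- rep(coeffs$alpha, nrow(person))
  } else {
    x <- covariate_matrix(person, names(coeffs$betas))
    if (anyNA(x) || !all(is.finite(x))) {
      bad <- colnames(x)[colSums(!is.finite(x)) > 0]
      abort(paste0("missing or non-finite covariate value(s) for: ",
                   paste(bad, collapse = ", ")),
            class = "menthol_domain_error")
    }
    eta <- coeffs$alpha + drop(x %*% coeffs$betas)
  }
  plogis(eta)
}

#' Annual non-CVD death probability from a life table
#'
#' Looks up the age- and sex-banded annual probability of death from causes
#' other than cardiovascular disease.  Ages at or above the top of the
#' table use its last band.
#'
#' @param age Ages in years (vector); must be at least 18.
#' @param sex Vector of `"male"` / `"female"` matching `age`.
#' @param table Life table: either the `life_table_tables` element of a
#'   validated configuration (a list of per-sex tibbles with columns `lo`,
#'   `hi`, `value`) or a single such tibble applied to both sexes.
#' @return Numeric vector of probabilities.
#' @export
non_cvd_death_probability <- function(age, sex, table) {
  if (any(age < 18)) {
    abort("age below 18 is outside the life table domain",
          class = "menthol_domain_error")
  }
  sex <- as.character(sex)
  lookup <- function(tab, a) {
    i <- findInterval(a, tab$lo)
    i[i > nrow(tab)] <- nrow(tab) # ages past the table use the last band
    tab$value[i]
  }
  if (is.data.frame(table)) return(lookup(table, age))
  out <- numeric(length(age))
  for (s in unique(sex)) {
    tab <- table[[s]]
    if (is.null(tab)) {
      abort(paste0("life table has no entry for sex '", s, "'"),
            class = "menthol_config_error")
    }
    sel <- sex == s
    out[sel] <- lookup(tab, age[sel])
  }
  out
}
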