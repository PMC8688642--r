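# Shared test fixtures, built in code.

raw_default_config <- function() {
  yaml::read_yaml(default_config_path())
}

safe_logit <- function(p) {
  if (p <= 0) -1000 else if (p >= 1) 1000 else stats::qlogis(p)
}

# Configuration whose transitions have constant, covariate-free
# probabilities; used to pin the engine against binomial oracles.
config_with_probs <- function(p_mi = 0, p_stroke = 0, p_cvd = 0,
                              q_noncvd = 0) {
  raw <- raw_default_config()
  probs <- c(mi = p_mi, stroke = p_stroke, cvd_death = p_cvd)
  for (oc in names(probs)) {
    raw$coefficients[[oc]]$alpha <- safe_logit(probs[[oc]])
    raw$coefficients[[oc]]$betas <- list()
  }
  for (s in c("male", "female")) {
    raw$life_table[[s]] <- list(list(lo = 18, hi = 100, q = q_noncvd))
  }
  validate_config(raw)
}

# Randomized but valid population spec for property tests.
random_spec_config <- function(seed) {
  set.seed(seed)
  raw <- raw_default_config()
  w <- runif(6)
  w <- w / sum(w)
  w[6] <- 1 - sum(w[1:5])
  i <- 1
  for (s in c("male", "female")) {
    for (r in c("nl_white", "nl_black", "latino")) {
      raw$population$strata_weights[[s]][[r]] <- w[i]
      raw$population$menthol_prevalence[[s]][[r]] <- runif(1)
      raw$population$diabetes_prevalence[[s]][[r]] <- runif(1)
      i <- i + 1
    }
  }
  rf <- raw$population$risk_factors
  rf$bmi$meanlog <- runif(1, 3.1, 3.5)
  rf$bmi$sdlog <- runif(1, 0.05, 0.35)
  rf$sbp$mean <- runif(1, 100, 145)
  rf$sbp$sd <- runif(1, 5, 25)
  rf$sbp$age_slope <- runif(1, 0, 0.6)
  rf$ldl_c$mean <- runif(1, 70, 170)
  rf$ldl_c$sd <- runif(1, 10, 50)
  rf$hdl_c$meanlog <- runif(1, 3.6, 4.2)
  rf$hdl_c$sdlog <- runif(1, 0.05, 0.35)
  raw$population$risk_factors <- rf
  validate_config(raw)
}

# A bare-hands cohort tibble for unit tests that bypass the generator.
make_cohort <- function(n, smoking = "current_menthol", age = 50,
                        sex = "male", race = "nl_white") {
  tibble::tibble(
    person_id = seq_len(n),
    age = rep_len(age, n),
    sex = factor(rep_len(sex, n), levels = c("male", "female")),
    race_ethnicity = factor(rep_len(race, n),
                            levels = c("nl_white", "nl_black", "latino")),
    bmi = 27, sbp = 120, ldl_c = 110, hdl_c = 50, diabetes = FALSE,
    smoking_status = factor(rep_len(smoking, n),
                            levels = c("current_menthol",
                                       "current_nonmenthol", "former")),
    alive = TRUE, had_mi = FALSE, had_stroke = FALSE, discounted_cost = 0
  )
}
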