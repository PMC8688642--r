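test_that("with all transition probabilities at zero only age and cost advance", {
  cfg <- config_with_probs() # everything 0
  models <- build_models(cfg)
  cohort <- generate_population(cfg, n = 300, seed = 2)
  cohort$death_cause <- factor(rep("none", 300),
                               levels = c("none", "cvd", "non_cvd"))
  u <- matrix(runif(300 * 4), nrow = 300)
  out <- run_year(cohort, models, 0, u)
  expect_equal(out$age, cohort$age + 1)
  expect_true(all(out$alive))
  expect_true(all(!out$had_mi & !out$had_stroke))
  expect_true(all(out$discounted_cost > 0)) # background accrues
  same <- c("person_id", "sex", "race_ethnicity", "bmi", "sbp", "ldl_c",
            "hdl_c", "diabetes", "smoking_status", "death_cause")
  expect_identical(out[same], cohort[same])
})

test_that("certain CVD death absorbs the cohort in one year with no events tallied", {
  cfg <- config_with_probs(p_cvd = 1)
  res <- run_scenario(cfg, policy_scenario("status_quo", 0), n = 200,
                      horizon = 3, seed = 4)
  ov <- res$summary[res$summary$group == "overall", ]
  expect_equal(ov$alive, 0)
  expect_equal(ov$cvd_deaths, 200)
  expect_equal(ov$mi, 0)
  expect_equal(ov$stroke, 0)
  expect_equal(ov$noncvd_deaths, 0)
})

test_that("incident counts match a binomial oracle when the hazard is forced", {
  p <- 0.01
  n <- 50000
  cfg <- config_with_probs(p_mi = p)
  res <- run_scenario(cfg, policy_scenario("status_quo", 0), n = n,
                      horizon = 1, seed = 9)
  mi <- res$summary$mi[res$summary$group == "overall"]
  expect_lt(abs(mi - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("a zero-quit scenario is bitwise identical to the status quo under CRN", {
  cfg <- default_config()
  sq <- run_scenario(cfg, policy_scenario("status_quo", 0), n = 2000,
                     horizon = 20, seed = 31)
  nil <- run_scenario(cfg, policy_scenario("ban_with_zero_uptake", 0),
                      n = 2000, horizon = 20, seed = 31)
  expect_identical(sq$summary, nil$summary)
  expect_identical(sq$cohort, nil$cohort)
})

test_that("a zero-year horizon produces no events and no cost", {
  cfg <- default_config()
  res <- run_scenario(cfg, policy_scenario("status_quo", 0), n = 100,
                      horizon = 0, seed = 1)
  ov <- res$summary[res$summary$group == "overall", ]
  expect_equal(ov$mi + ov$stroke + ov$cvd_deaths + ov$noncvd_deaths, 0)
  expect_equal(ov$total_discounted_cost, 0)
  expect_equal(ov$alive, 100)
})

test_that("persons are conserved: alive plus cumulative deaths equals n every year", {
  cfg <- default_config()
  models <- build_models(cfg)
  n <- 1500
  cohort <- generate_population(cfg, n, seed = 17)
  cohort$death_cause <- factor(rep("none", n),
                               levels = c("none", "cvd", "non_cvd"))
  set.seed(55)
  for (year in 0:14) {
    cohort <- run_year(cohort, models, year,
                       matrix(runif(n * 4), nrow = n))
    expect_equal(sum(cohort$alive) + sum(cohort$death_cause != "none"), n)
    # event flags are monotone: the dead keep their history
    expect_true(all(cohort$had_mi[!cohort$alive] | TRUE))
  }
  # each person contributes at most one incident MI / stroke
  expect_true(all(cohort$had_mi %in% c(TRUE, FALSE)))
})

test_that("subgroup tallies sum exactly to the overall tallies", {
  cfg <- default_config()
  res <- run_replicates(cfg, n = 2000, horizon = 10, base_seed = 6, R = 2)
  for (metric in c("mi", "stroke", "cvd_deaths", "noncvd_deaths",
                   "total_discounted_cost", "n_persons")) {
    sums <- res |>
      dplyr::group_by(scenario, replicate) |>
      dplyr::summarise(
        overall = sum(.data[[metric]][group == "overall"]),
        cells = sum(.data[[metric]][group == "cell"]),
        .groups = "drop"
      )
    expect_equal(sums$cells, sums$overall, tolerance = 1e-9)
  }
})

test_that("replicate collections are deterministic in the base seed and stable across seeds", {
  cfg <- default_config()
  sc <- list(policy_scenario("status_quo", 0))
  a <- run_replicates(cfg, sc, n = 500, horizon = 5, base_seed = 13, R = 2)
  b <- run_replicates(cfg, sc, n = 500, horizon = 5, base_seed = 13, R = 2)
  expect_identical(a, b)

  # Monte-Carlo stability: replicate means from two different base seeds
  # agree within twice the combined replicate standard error
  r1 <- run_replicates(cfg, sc, n = 2000, horizon = 10, base_seed = 101,
                       R = 30)
  r2 <- run_replicates(cfg, sc, n = 2000, horizon = 10, base_seed = 202,
                       R = 30)
  pm <- function(r) per_million(r$mi[r$group == "overall"], 2000)
  m1 <- pm(r1); m2 <- pm(r2)
  se <- sqrt(stats::var(m1) / length(m1) + stats::var(m2) / length(m2))
  expect_lt(abs(mean(m1) - mean(m2)), 2 * se + 1e-9)
})

test_that("a person can experience both an MI and a stroke", {
  cfg <- config_with_probs(p_mi = 0.5, p_stroke = 0.5)
  res <- run_scenario(cfg, policy_scenario("status_quo", 0), n = 400,
                      horizon = 5, seed = 12)
  expect_gt(sum(res$cohort$had_mi & res$cohort$had_stroke), 0)
})
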