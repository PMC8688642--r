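test_that("per-million scaling is exact", {
  expect_equal(per_million(0, 10000), 0)
  expect_equal(per_million(572, 10000), 57200)
  expect_equal(per_million(521.95, 10000), 52195)
})

test_that("averted cases and percent reduction follow their identities", {
  x <- averted_and_reduction(57232, 54370)
  expect_equal(x$averted, 2862)
  expect_equal(x$percent_reduction, 5.000699, tolerance = 1e-6)

  y <- averted_and_reduction(52195, 50212)
  expect_equal(y$averted, 1983)
  expect_equal(y$percent_reduction, 3.799215, tolerance = 1e-6)

  same <- averted_and_reduction(41000, 41000)
  expect_equal(same$averted, 0)
  expect_equal(same$percent_reduction, 0)

  degenerate <- averted_and_reduction(0, 0)
  expect_equal(degenerate$averted, 0)
  expect_true(is.na(degenerate$percent_reduction))
})

test_that("cost savings scale to the population", {
  s <- cost_savings(41479, 39643, 880000)
  expect_equal(s$per_person_saving, 1836)
  expect_equal(s$total_saving, 1615680000)
  expect_equal(cost_savings(100, 90, 10)$total_saving, 100)
  expect_equal(cost_savings(5, 5, 1e6)$per_person_saving, 0)
})

test_that("report identities hold exactly on simulated results", {
  cfg <- default_config()
  res <- run_replicates(cfg, n = 2000, horizon = 10, base_seed = 3, R = 4)
  rep <- comparison_report(res, population = 880000)
  scen <- rep$scenarios
  cmp <- rep$comparison

  sq <- scen[scen$scenario == "status_quo", ]
  bn <- scen[scen$scenario == "menthol_ban", ]
  expect_equal(cmp$averted_mi_per_million,
               sq$mi_per_million - bn$mi_per_million, tolerance = 1e-9)
  expect_equal(cmp$mi_percent_reduction,
               100 * cmp$averted_mi_per_million / sq$mi_per_million,
               tolerance = 1e-9)
  expect_equal(cmp$total_saving, cmp$per_person_saving * 880000,
               tolerance = 1e-9)

  # percentile CI contains the replicate mean
  expect_true(sq$mi_ci_lo <= sq$mi_per_million &
                sq$mi_per_million <= sq$mi_ci_hi)
  expect_true(bn$cost_ci_lo <= bn$cost_per_person &
                bn$cost_per_person <= bn$cost_ci_hi)

  # tidy/glance accessors expose the same tables
  expect_identical(tidy(rep), rep$scenarios)
  expect_identical(glance(rep), rep$comparison)
})

test_that("a cell with zero menthol prevalence has exactly zero averted cases", {
  raw <- raw_default_config()
  raw$population$menthol_prevalence$female$nl_white <- 0
  cfg <- validate_config(raw)
  res <- run_replicates(cfg, n = 3000, horizon = 20, base_seed = 44, R = 2)
  sg <- subgroup_report(res)
  row <- sg[sg$sex == "female" & sg$race_ethnicity == "nl_white", ]
  expect_equal(row$mi_status_quo, row$mi_ban)
  expect_equal(row$stroke_status_quo, row$stroke_ban)
  expect_equal(row$saving_per_person, 0, tolerance = 1e-9)
})

test_that("identical menthol prevalence across cells yields similar reductions", {
  raw <- raw_default_config()
  for (s in c("male", "female")) {
    for (r in c("nl_white", "nl_black", "latino")) {
      raw$population$menthol_prevalence[[s]][[r]] <- 0.5
    }
  }
  cfg <- validate_config(raw)
  res <- run_replicates(cfg, n = 12000, horizon = 20, base_seed = 10, R = 6)
  sg <- subgroup_report(res)
  # under symmetric prevalence the six cell reductions differ only by
  # Monte-Carlo noise, far less than the ~6-point spread under Table-1 cells
  expect_lt(max(sg$mi_reduction_pct) - min(sg$mi_reduction_pct), 4)
  expect_true(all(sg$mi_reduction_pct > 0))
})

test_that("the averted-cases sweep is anchored at zero and monotone", {
  cfg <- default_config()
  sw <- quit_proportion_sweep(cfg, c(0, 0.1, 0.212, 0.3, 0.5, 1),
                              n = 3000, horizon = 10, base_seed = 5, R = 3)
  expect_equal(sw$averted_mi_per_million[1], 0)
  expect_equal(sw$averted_stroke_per_million[1], 0)
  expect_true(all(diff(sw$averted_mi_per_million) >= 0))
  expect_true(all(diff(sw$averted_stroke_per_million) >= 0))
  expect_gt(sw$averted_mi_per_million[sw$quit_proportion == 0.5],
            sw$averted_mi_per_million[sw$quit_proportion == 0.212])

  # full cessation equals the direct status-quo minus all-quit difference
  sq <- run_replicates(cfg, list(policy_scenario("status_quo", 0),
                                 policy_scenario("quit_1", 1)),
                       n = 3000, horizon = 10, base_seed = 5, R = 3)
  ov <- sq[sq$group == "overall", ]
  direct <- mean(per_million(ov$mi[ov$scenario == "status_quo"], 3000)) -
    mean(per_million(ov$mi[ov$scenario == "quit_1"], 3000))
  expect_equal(sw$averted_mi_per_million[sw$quit_proportion == 1], direct,
               tolerance = 1e-9)
})

test_that("empty subgroups warn and report NA", {
  raw <- raw_default_config()
  for (r in c("nl_white", "nl_black", "latino")) {
    raw$population$strata_weights$female[[r]] <- 0
  }
  tot <- sum(unlist(raw$population$strata_weights$male))
  for (r in c("nl_white", "nl_black", "latino")) {
    raw$population$strata_weights$male[[r]] <-
      raw$population$strata_weights$male[[r]] / tot
  }
  # exact renormalization to machine precision
  raw$population$strata_weights$male$latino <-
    1 - raw$population$strata_weights$male$nl_white -
    raw$population$strata_weights$male$nl_black
  cfg <- validate_config(raw)
  res <- run_replicates(cfg, n = 400, horizon = 3, base_seed = 2, R = 1)
  expect_warning(sg <- subgroup_report(res), "empty subgroup")
  expect_true(all(is.na(sg$saving_per_person[sg$sex == "female"])))
})

test_that("plot builders return ggplot objects", {
  cfg <- default_config()
  sw <- quit_proportion_sweep(cfg, c(0, 0.5), n = 500, horizon = 3,
                              base_seed = 1, R = 1)
  expect_s3_class(autoplot(sw), "ggplot")
  res <- run_replicates(cfg, n = 500, horizon = 3, base_seed = 1, R = 2)
  expect_s3_class(plot_subgroup_reductions(comparison_report(res)), "ggplot")
})
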