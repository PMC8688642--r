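# Default mentholsim configuration.
#
# The population section emulates the joint demographic / risk-factor profile
# of NYC adult cigarette smokers circa 2018.  Menthol-use prevalence by sex
# and race/ethnicity and the age-band structure come from published survey
# margins; the joint sex x race/ethnicity menthol matrix is built by
# independence scaling (cell = race value * sex value / overall 0.49, clamped
# to [0, 1]) because no joint table is published.  Risk-factor marginals are
# SYNTHETIC parametric stand-ins, not a survey microdata fit.
#
# The coefficients section is SYNTHETIC as well: the pooled-cohort CVD risk
# equation coefficients are not published, so these are plausible approximate
# values calibrated only so that the default smoker cohort's 20-year
# cumulative MI incidence lands in the 4-8% range.  Cost parameters are
# likewise plausible placeholders in 2018 dollars.  Every value here can be
# overridden by editing a copy of this file.

population:
  adult_smokers: 880000        # NYC adult smokers, 2018
  menthol_smokers: 431000      # of whom usually smoke menthol (49%)
  n_default: 10000
  strata_weights:              # sex x race/ethnicity shares of adult smokers
    male:
      nl_white: 0.245423
      nl_black: 0.181937
      latino: 0.176507
    female:
      nl_white: 0.160996
      nl_black: 0.119349
      latino: 0.115788
  menthol_prevalence:          # P(usually smokes menthol | sex, race/ethnicity)
    male:
      nl_white: 0.230400
      nl_black: 0.754200
      latino: 0.538200
    female:
      nl_white: 0.309812
      nl_black: 1.000000       # independence scaling exceeded 1; clamped
      latino: 0.723702
  diabetes_prevalence:
    male:
      nl_white: 0.09
      nl_black: 0.14
      latino: 0.16
    female:
      nl_white: 0.08
      nl_black: 0.16
      latino: 0.17
  age_bands:                   # uniform within band; weights are smoker shares
    - {lo: 18, hi: 25, weight: 0.075362}
    - {lo: 25, hi: 45, weight: 0.454744}
    - {lo: 45, hi: 65, weight: 0.388015}
    - {lo: 65, hi: 85, weight: 0.081879}
  risk_factors:
    bmi:                       # kg/m^2
      family: lognormal
      meanlog: 3.3142
      sdlog: 0.18
      min: 12
      max: 80
    sbp:                       # mmHg; mean rises linearly with age
      family: normal
      mean: 118
      sd: 13
      age_slope: 0.35
      age_center: 45
      min: 70
      max: 260
    ldl_c:                     # mg/dL
      family: normal
      mean: 117
      sd: 32
      min: 20
      max: 400
    hdl_c:                     # mg/dL
      family: lognormal
      meanlog: 3.93
      sdlog: 0.22
      min: 10
      max: 150

# Annual transition log-odds: P(event) = plogis(alpha + sum(beta * x)).
# Covariates may be any of: age, male, female, nl_white, nl_black, latino,
# bmi, sbp, ldl_c, hdl_c, diabetes, smoking_current, smoking_former.
# smoking_former defaults to 0 (quitting confers never-smoker risk).
# cvd_death carries no smoking term so paired scenarios share survival and
# the policy contrast is isolated in MI/stroke incidence.
coefficients:
  mi:
    alpha: -11.15
    betas:
      age: 0.050
      male: 0.25
      nl_black: 0.10
      latino: 0.05
      bmi: 0.015
      sbp: 0.010
      ldl_c: 0.005
      hdl_c: -0.012
      diabetes: 0.45
      smoking_current: 0.70
      smoking_former: 0.0
  stroke:
    alpha: -11.45
    betas:
      age: 0.055
      male: 0.10
      nl_black: 0.15
      latino: 0.08
      bmi: 0.008
      sbp: 0.014
      ldl_c: 0.002
      hdl_c: -0.008
      diabetes: 0.50
      smoking_current: 0.48
      smoking_former: 0.0
  cvd_death:
    alpha: -12.6
    betas:
      age: 0.085
      male: 0.30
      sbp: 0.008
      diabetes: 0.40

# Annual probability of death from non-CVD causes, by age band and sex.
# Synthetic life table: monotone in age, male excess mortality.
life_table:
  male:
    - {lo: 18, hi: 30, q: 0.0009}
    - {lo: 30, hi: 40, q: 0.0015}
    - {lo: 40, hi: 50, q: 0.0027}
    - {lo: 50, hi: 60, q: 0.0060}
    - {lo: 60, hi: 70, q: 0.0135}
    - {lo: 70, hi: 80, q: 0.0330}
    - {lo: 80, hi: 90, q: 0.0900}
    - {lo: 90, hi: 100, q: 0.2250}
  female:
    - {lo: 18, hi: 30, q: 0.0006}
    - {lo: 30, hi: 40, q: 0.0010}
    - {lo: 40, hi: 50, q: 0.0018}
    - {lo: 50, hi: 60, q: 0.0040}
    - {lo: 60, hi: 70, q: 0.0090}
    - {lo: 70, hi: 80, q: 0.0220}
    - {lo: 80, hi: 90, q: 0.0600}
    - {lo: 90, hi: 100, q: 0.1500}

# Healthcare costs, 2018 US dollars.  Synthetic placeholders of the right
# order for US adult healthcare spending; discounted at 3%/yr to baseline.
costs:
  background:                  # annual cost by age band
    - {lo: 18, hi: 45, cost: 2000}
    - {lo: 45, hi: 65, cost: 3200}
    - {lo: 65, hi: 100, cost: 5200}
  mi_event_cost: 30000
  stroke_event_cost: 25000
  post_mi_annual_cost: 3500
  post_stroke_annual_cost: 4000
  discount_rate: 0.03
  base_year_index: 0

scenarios:
  - {name: status_quo, quit_proportion: 0.0, start_year_index: 0}
  - {name: menthol_ban, quit_proportion: 0.212, start_year_index: 0}

simulation:
  n: 10000
  horizon_years: 20
  replicates: 200
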