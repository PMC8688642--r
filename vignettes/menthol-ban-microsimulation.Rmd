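---
title: "Modelling the cardiovascular impact of a menthol cigarette ban"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cardiovascular impact of a menthol cigarette ban}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mentholsim)
library(dplyr)
```

## The question

Menthol flavouring makes cigarettes easier to start and harder to quit, and
menthol use is strongly patterned by sex and race/ethnicity: in New York
City roughly half of adult smokers usually smoke menthol cigarettes, with
far higher prevalence among non-Latino Black smokers (~84%) and women
(~59%) than among non-Latino White smokers (~26%) or men (~44%). A sales
ban that pushes a fraction of menthol smokers to quit should therefore
reduce smoking-attributable cardiovascular disease (CVD) *unevenly*,
concentrating its benefit in the groups that smoke menthol most — which is
exactly the disparity question a policy maker cares about.

`mentholsim` is a discrete-time microsimulation built to answer it. A
synthetic cohort of adult smokers is generated, each person is a menthol or
non-menthol smoker with a probability determined by their sex and
race/ethnicity, and the cohort is then advanced year by year through
myocardial infarction (MI), stroke, CVD death and non-CVD death
transitions while accruing discounted healthcare costs. Two scenarios are
run on *the same people with the same random numbers*: the status quo, and
a ban under which a fixed proportion of menthol smokers quits at baseline.
Differences between the paired runs are the policy effect.

## Model structure

### Population synthesis

`generate_population()` draws, for each person:

* a sex × race/ethnicity stratum from configurable weights (defaults
  back-derived from published NYC smoker counts: race shares
  0.406/0.301/0.292 for White/Black/Latino, sex shares 0.604/0.396
  male/female);
* an age, uniform within weighted bands 18–24, 25–44, 45–64, 65–84 (the
  only published age structure for this population);
* BMI, systolic blood pressure, LDL-C and HDL-C from independent
  parametric marginals (normal or lognormal per the config), SBP with a
  linear age trend; all values clamped to physiologic ranges
  (BMI 12–80 kg/m², SBP 70–260 mmHg, LDL-C 20–400 mg/dL, HDL-C
  10–150 mg/dL);
* diabetes and menthol use as Bernoulli draws with stratum-specific
  probabilities.

The joint menthol matrix is the one genuinely open design point: published
tables give menthol prevalence by sex *or* by race/ethnicity, never
jointly. The default config fills the six cells by independence scaling —
`cell = race value × sex value / overall 0.49` — clamped to [0, 1]. The
female × non-Latino-Black cell scales to 1.014 and is clamped to 1.0, so
the printed margins are reproduced only approximately (the Black margin
comes out 0.852 rather than 0.838). The matrix is data, not code; a user
with a better joint estimate edits six numbers in the YAML.

The risk-factor marginals are a documented *stand-in*, not a fit to survey
microdata (which is restricted). Passing tests therefore demonstrate that
the pipeline recovers whatever joint structure it is configured with — not
that the default cohort matches the real NYC smoker population
moment-for-moment. Correlations between metabolic factors (beyond the
SBP–age trend) are deliberately absent.

### Annual transitions

Each year, in fixed order per living person: non-CVD death, CVD death,
incident MI (if none before), incident stroke (if none before), cost
accrual, ageing by one year. The order is a convention — nothing in the
underlying evidence dictates one — and the competing-risk refinement of
fractional-year timing is out of scope. A person can have both an MI and a
stroke over the horizon; each outcome is counted at most once per person.
Dead persons accrue no further events or costs; risk factors other than
age are frozen over the horizon.

MI, stroke and CVD death use logistic annual probabilities

$$P(\text{event}) = \frac{e^{\eta}}{1+e^{\eta}}, \qquad
\eta = \alpha + \sum_k \beta_k x_k,$$

with covariates drawn from age, sex, race/ethnicity indicators, BMI, SBP,
LDL-C, HDL-C, diabetes and smoking-status indicators. The evaluation uses
the numerically stable log-sum form (`plogis`), exact against the naive
ratio to 10⁻¹² wherever the latter is representable and safe for |η| in
the hundreds. Non-CVD death comes from a synthetic age-banded, sex-specific
life table, monotone in age with male excess mortality.

**The shipped coefficients are synthetic.** The pooled-cohort equations
the design imitates are not published coefficient-by-coefficient, so the
defaults are plausible approximate values with one deliberate calibration:
the intercepts were chosen (once) so the default status-quo cohort's
20-year cumulative MI incidence lands in the 4–8% band, i.e. of the same
order as published projections (~5.7%). The smoking log-odds are the
defaults that matter most:

* `smoking_current`: 0.70 for MI, 0.48 for stroke — roughly the ×2 / ×1.6
  odds that make a 21.2% quit rate among ~49% menthol prevalence produce
  overall reductions near the published ~5% (MI) and ~3.8% (stroke);
* `smoking_former`: 0 — quitting confers never-smoker risk immediately.
  No cessation lag is modelled because none is specified in the evidence
  base; a user can set a positive former-smoker beta to add one.
* the CVD-death equation carries **no smoking term** by default. This is a
  design choice, not an oversight: with survival identical across paired
  scenarios, every difference between runs flows through MI/stroke
  incidence and the ban can be proven never to increase event tallies
  under shared uniforms (see below). With a smoking effect on mortality, a
  quitter kept alive longer under the ban could mechanically accrue *more*
  events than under the status quo, which entangles the policy contrast
  with survivorship. Users who want mortality benefits add a
  `smoking_current` beta to `cvd_death` in the config.

### Policy operator

`apply_policy()` implements a one-time shock at the ban's start year: each
current menthol smoker quits with probability `quit_proportion` (default
0.212, the quit rate observed after Ontario's provincial menthol ban);
non-quitters switch to non-menthol cigarettes, which is risk-identical
under the default coding. Non-menthol and former smokers are untouched —
the multiset of their records is invariant. A quit proportion of zero is a
null policy and returns the cohort bit-for-bit. No relapse or initiation
dynamics are modelled.

### Common random numbers

Scenario comparison is paired by design. For a given replicate seed the
engine derives three sub-seeds — cohort, policy quit draws, event draws —
and pre-generates one uniform per (person, transition, year) triple in a
fixed layout. Both scenarios of a replicate consume the identical array,
and quit draws live on their own stream, so:

* `quit_proportion = 0` reproduces the status quo exactly (a free
  correctness oracle, asserted in the tests);
* quitter sets are nested across quit proportions (person *i* quits iff
  `u_i < q`), so averted-case curves are monotone replicate by replicate,
  not just in expectation;
* with survival shared (default coefficients), the ban's MI and stroke
  tallies are ≤ the status quo's in *every* replicate, because quitting
  only lowers the probability each shared uniform is compared against.

This is a variance-reduction choice the evidence base is silent on; it
changes no marginal distribution, only the coupling between scenarios.

### Costs

Each survivor-year costs its age-banded background amount, plus one-time
MI/stroke event costs in the year of the event, plus annual post-MI and
post-stroke maintenance costs for conditions established in earlier years;
the year's total is discounted by `1/(1+r)^t` with year 0 undiscounted and
r = 3% by default (configurable 0–10%, with the sensitivity sweep covering
0–6%). People who die during a year accrue nothing that year — death is
drawn before events, so no event cost can precede it within the year. The
dollar values are placeholders of the right order for US healthcare
spending (the underlying expenditure-survey parameters are not published);
the default 20-year mean discounted cost per person comes out near $48k,
the same order as the published ~$41k. Because event dynamics do not
depend on costs, the per-person saving is a discounted sum of non-negative
within-replicate differences, hence provably non-increasing in the
discount rate — the direction reported in the sensitivity analysis it
mirrors.

### Uncertainty

`run_replicates()` runs R independent replicates (seeds derived from one
base seed) and the reporting layer summarises them with means and 2.5/97.5
percentile intervals — the conventional Monte-Carlo reading of a
microsimulation CI. Replicate results are returned as a tidy tibble (one
row per scenario × replicate × tally group), so the whole reporting layer
is ordinary dplyr.

## A worked run

```{r run, message = FALSE}
cfg <- default_config()
results <- run_replicates(cfg, n = 2000, horizon = 20, base_seed = 1, R = 20)
report <- comparison_report(results, population = cfg$population$adult_smokers)
report
glance(report)
report$subgroups |>
  select(sex, race_ethnicity, mi_reduction_pct, stroke_reduction_pct,
         saving_per_person) |>
  arrange(desc(mi_reduction_pct))
```

The disparity pattern is the load-bearing qualitative result: reductions
order non-Latino Black > Latino > non-Latino White within each sex and
women ≥ men within each race/ethnicity, simply because the policy can only
help menthol smokers and those groups contain the most of them. At this
small demonstration scale adjacent cells can swap by Monte-Carlo noise; at
the reference scale (n = 10,000, R = 200 replicates, as the test suite
runs it) the ordering is strict. A cell with zero menthol prevalence gets
exactly zero averted cases under the paired design.

```{r sweep, fig.width = 6, fig.height = 3.5, message = FALSE}
sw <- quit_proportion_sweep(cfg, c(0, 0.1, 0.212, 0.3, 0.5),
                            n = 2000, horizon = 20, base_seed = 1, R = 5)
autoplot(sw)
```

## Problem sizes and numerical choices

The package's reference experiment is n = 10,000 persons over 20 years
with paired scenarios; one scenario-replicate takes ~0.25 s, so hundreds
of replicates are cheap. The test suite exercises the full-size design
where the property under test needs it (dominance across 50 replicates,
subgroup ordering across 200) and smaller cohorts where it does not;
binomial checks use 3-standard-deviation bands. Tie-breaks and
conventions worth knowing:

* events fire when `u < p` (strict), so p = 0 never fires and p = 1
  always does;
* within-year order is death-before-events; a death year accrues no cost;
* ages at or beyond the last life-table band reuse that band;
* stratum weights must sum to 1 within 10⁻⁹; probabilities are validated
  to [0, 1] with path-like error locators;
* all derived seeds stay within 32-bit integer range.

## Limitations

Everything the generator does not emulate is a limitation on external
validity: no SES covariates (absent from the risk equations this design
follows), no non-CVD outcomes of smoking, no initiation or relapse, no
secondhand-smoke or smoking-intensity channel, no correlation structure
among metabolic risk factors, and synthetic (clearly labelled) risk
coefficients, life table and costs wherever the true parameters are
unpublished. The model projects *relative* policy contrasts under a
transparent, fully configurable parameterisation; absolute burden numbers
inherit the placeholder parameters and should be read as order-of-magnitude.
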