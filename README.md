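# medroute

Causal mediation analysis of the comorbidity gap in lymphoma survival,
decomposed by diagnostic route.

## The problem

In population-based cancer registries, patients with chronic comorbidities
have markedly worse survival after a diagnosis of diffuse large B-cell or
follicular lymphoma. Part of that gap may operate through *how* the cancer
is found: comorbidity makes an unplanned **emergency presentation** more
likely, and emergency presentation carries worse survival than the elective
pathways (two-week-wait, GP referral, in/outpatient). `medroute` is for
epidemiologists and biostatisticians who want to quantify how much of the
comorbidity effect on mortality travels through the diagnostic route.

With exposure A (any comorbidity), mediator M (emergency route), outcome Y
(death within a conditional follow-up window) and confounders C (age, sex,
deprivation quintile, ethnicity), the package estimates the nested
counterfactual risks P(Y<sub>a,M<sub>a*</sub></sub> = 1) by Monte Carlo
g-computation and reports, on the odds-ratio scale,

    OR_TCE = OR_NDE x OR_NIE ,    PM = OR_NDE (OR_NIE - 1) / (OR_NDE OR_NIE - 1)

the total causal effect, its natural direct (not through route) and natural
indirect (through route) components — an exact telescoping product — and
the proportion mediated. Intervals are percentile bootstrap with full
re-estimation, including single stochastic imputation of missing routes,
inside every replicate.

Around the core the package provides:

* a **synthetic registry cohort generator** (`scenario_spec()`,
  `generate_cohort()`) encoding the causal ordering C → A → M → Y on a
  discrete confounder grid, with an **exact enumeration oracle**
  (`true_natural_effects()`) for the true effects implied by any scenario;
* Table-1 style **descriptive statistics**: cross-tabulations, Wald odds
  ratios with 95% CIs, chi-squared tests, per-decade age OR
  (`describe_cohort()`, `odds_ratio_wald()`, ...);
* **Pohar Perme net survival** against an (age, sex, year) life table, with
  a Kaplan–Meier implementation that is its exact zero-background limit
  (`pohar_perme()`, `kaplan_meier()`, `generate_life_table()`);
* a config-driven **pipeline runner and CLI** (`run_pipeline()`,
  `medroute_cli()`; subcommands `simulate`, `describe`, `netsurv`,
  `mediate`, `run`).

## Worked example

```r
library(medroute)

spec <- default_scenario(n_patients = 20000, seed = 3)
cohort <- generate_cohort(spec)

est <- estimate_natural_effects(cohort, window = 1,
                                list(seed = 42, n_bootstrap = 200))
est
#> <natural effects, window 1 (0, 12] months>
#>   at risk 20000, events 7008, imputed routes 1190 [gcomp-mc]
#>   TCE  1.410 (1.299-1.552)
#>   NDE  1.310 (1.219-1.434)
#>   NIE  1.076 (1.051-1.101)
#>   PM   24.3% (15.6%-31.7%)

true_natural_effects(spec, 1)
#> <true natural effects, window 1>
#>   TCE 1.4553  NDE 1.3464  NIE 1.0809  PM 0.2393
```

Reading: among patients with comorbidity the odds of death within 12 months
are 1.41 times those without; holding the diagnostic route at its
no-comorbidity value would still leave an OR of 1.31 (direct effect), while
the route shift alone contributes an OR of 1.08 (indirect effect). About a
quarter of the total effect travels through the diagnostic route. The
second call shows the exact truth implied by the generating scenario, which
the estimate recovers within Monte Carlo error.

The full pipeline — descriptives, net survival by comorbidity and route,
and all three conditional windows (0–12, 12–36 | alive at 12,
36–60 | alive at 36 months) — from one config:

```r
run_pipeline(list(scenario = spec, seed = 404, n_bootstrap = 200,
                  out_dir = "results/run1"))
```

writes `table1.csv`, `net_survival.csv`, `natural_effects.csv/.json` and a
`manifest.json` whose seeds reproduce every number exactly.

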