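---
title: "Decomposing the comorbidity gap in lymphoma survival by diagnostic route"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the comorbidity gap in lymphoma survival by diagnostic route}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Patients with non-Hodgkin lymphoma (diffuse large B-cell or follicular
subtypes) who carry chronic comorbidities die sooner than patients without
them. Part of that gap may arise *before* treatment ever starts: comorbidity
changes how a cancer is found. A patient whose comorbid symptoms obscure the
lymphoma is more likely to be diagnosed through an unplanned emergency
presentation rather than an elective pathway (two-week-wait, GP referral,
in/outpatient), and emergency presentation is strongly associated with worse
survival. `medroute` implements the causal mediation analysis that separates
these channels:

* **exposure** A — any recorded comorbidity (a dichotomised RCS Charlson
  style flag), A = 1 for one or more conditions;
* **mediator** M — diagnostic route, M = 1 for emergency presentation;
* **outcome** Y — all-cause death within a conditional follow-up window;
* **confounders** C — age at diagnosis, sex, deprivation quintile,
  ethnicity.

The assumed causal ordering is C → A → M → Y, with no unmeasured
confounding of the A–Y, M–Y and A–M relationships, consistency, and no
interference. These assumptions are encoded literally in the synthetic data
generator, which is why the generator can also serve as a ground-truth
oracle.

## Natural effects on the odds-ratio scale

Write $Y_{a, M_{a^*}}$ for the outcome under exposure $a$ with the mediator
set to the value it would take under exposure $a^*$. With marginal odds
$o(a, a^*) = P(Y_{a,M_{a^*}}=1) / P(Y_{a,M_{a^*}}=0)$ the package reports

* total causal effect $\mathrm{OR}_{TCE} = o(1,1)/o(0,0)$,
* natural direct effect $\mathrm{OR}_{NDE} = o(1,0)/o(0,0)$ (mediator held
  at its no-comorbidity value),
* natural indirect effect $\mathrm{OR}_{NIE} = o(1,1)/o(1,0)$ (route
  shifted while exposed),

so that $\mathrm{OR}_{TCE} = \mathrm{OR}_{NDE}\times\mathrm{OR}_{NIE}$ holds
*identically* — the decomposition is a telescoping product, and the test
suite asserts it to 1e-10 on every run. The proportion of the total effect
transmitted through diagnostic route is computed on the odds-ratio scale as

$$\mathrm{PM} = \frac{\mathrm{OR}_{NDE}(\mathrm{OR}_{NIE}-1)}
                    {\mathrm{OR}_{NDE}\,\mathrm{OR}_{NIE}-1},$$

which is 0 when the indirect effect is null and 1 when the direct effect is
null. PM is undefined when the total effect is null; the package returns
`NA` with a warning in that case rather than a number.

A caveat worth stating plainly: applying this transformation to a
*published* pair of rounded odds ratios need not reproduce a published PM
value, because the original computation used unrounded estimates. For
example the transformation of 1.36 and 1.10 gives 0.2742, not the
often-quoted "about a quarter". `medroute` always computes PM from
full-precision internal estimates and makes no attempt to chase rounded
published numbers.

## Estimation: Monte Carlo g-computation

`estimate_natural_effects()` runs, per window:

1. restrict to patients alive at the window start;
2. singly impute missing mediator values (below);
3. fit logistic regressions for the mediator, `M ~ A + C`, and the outcome,
   `Y ~ A + M + A:M + C` (the exposure–mediator interaction is retained so
   the outcome model is a faithful natural effect model; `C` enters as age
   per decade, sex, four deprivation contrasts and ethnicity — no `A:C` or
   `M:C` terms by default, configurable);
4. for each counterfactual leg $(a, a^*) \in \{(1,1), (1,0), (0,0)\}$, draw
   `mc_draws` (default 50) mediator values per subject from the mediator
   model at $a^*$, evaluate the outcome model at $a$ with those draws, and
   average — the g-computation estimate of $P(Y_{a,M_{a^*}}=1)$;
5. convert to marginal odds and report the three ORs and PM;
6. percentile-bootstrap everything (default 1000 replicates): patients are
   resampled with replacement and the whole pipeline — imputation included —
   is re-run per replicate. Replicates that fail to converge are dropped and
   counted; more than 5% failing is an error.

The reported ORs are **marginal** over the window's at-risk confounder
distribution, not conditional at a reference covariate pattern: a single OR
per window is what the applied analysis reports, and marginalisation is
what the g-formula computes. The closed-form *conditional* expressions
(`nde_or_closed_form()`, `nie_or_closed_form()`), which for the natural
effect model
$\operatorname{logit} E[Y_{a,M_{a^*}}\mid C] = \beta_0 + \beta_1 a +
\beta_2 a^* + \beta_3'C + \beta_4 a a^* + \beta_5' aC + \beta_6' a^*C$
give $\mathrm{OR}_{NDE} = \exp\{(\beta_1+\beta_4 a^*+\beta_5'C)(a-a^*)\}$
and $\mathrm{OR}_{NIE} = \exp\{(\beta_2+\beta_4 a+\beta_6'C)(a-a^*)\}$, are
kept as a separate verification surface.

Because the mediator is binary, the Monte Carlo average over `mc_draws`
draws is computed as $k/\text{mc}\cdot\hat p(M{=}1) +
(1-k/\text{mc})\cdot\hat p(M{=}0)$ with $k \sim
\mathrm{Bin}(\text{mc}, \hat p_M)$ — distributionally identical to looping
over individual draws, and cheap. `mode = "closed_form"` replaces $k/mc$ by
its expectation $\hat p_M$, giving the deterministic infinite-draw limit;
it is used where tests need exactness.

**Missing mediator.** Routes are missing for some patients (5.8% in the
default scenario). A logistic imputation model for M on A, C and the
window's Y — all analysis variables — is fitted on complete cases, and each
missing value is replaced by a single Bernoulli draw. The imputation is
repeated inside every bootstrap replicate so the intervals propagate
imputation noise.

**Seeds.** Every random step (imputation, mediator draws per leg, each
bootstrap replicate) receives a sub-seed derived from the single master seed
via `split_seed()`, so any number in the output is reproducible from the
master seed alone.

**Windows.** Mortality is analysed as three conditional binary outcomes:
death within (0,12] months, within (12,36] given survival to 12, and within
(36,60] given survival to 36. Intervals are half-open on the right, so a
death at exactly month 12 is a window-1 event. Windows 2 and 3 refit all
models on their surviving subset; nothing is shared across windows.

## Conditional windows and the enumeration oracle

`true_natural_effects()` computes the *exact* natural effects implied by a
generating scenario, with no sampling: the confounders live on a finite
grid (integer ages 45–99 × sex × five deprivation quintiles × ethnicity =
1,100 cells), so every counterfactual risk is a finite sum. For windows 2
and 3 the confounder distribution is re-weighted by the exact probability
of surviving all earlier windows given C, marginalised over the joint law
of (A, M) given C — survival selection is handled in closed form.

This is why age is generated on an integer grid (a discretised normal with
mean 71, SD 11, truncated to 45–99): an exact oracle beats a Monte Carlo
approximation of the truth as a test target. One consequence is worth
noting: for windows 2 and 3 the estimator's mediator model is fitted among
survivors, whose mediator distribution differs from the baseline structural
one, so estimator-vs-oracle agreement is asserted where both target the
same quantity (window 1) and the later windows are checked for internal
consistency (telescoping, at-risk counts).

## The synthetic cohort: what it does and does not emulate

`default_scenario()` states the world once, loosely calibrated to the
margins of an English DLBCL registry cohort:

| quantity | default | source of the choice |
|---|---|---|
| comorbidity prevalence | 11.4% | published cohort margin |
| emergency presentation | 33.7% | published cohort margin |
| route missingness | 5.8%, completely at random | published rate; mechanism unstated, MCAR chosen |
| age | truncated normal(71, 11) on 45–99 | published mean (SD) |
| female share | 46.5% | published margin |
| deprivation shares | 21.5/22.8/21.0/19.5/15.2% | published margins |
| ethnicity "other" | 10% | not published; plausible for England |
| window death probabilities | 35/25/15% conditional | observed survival ≈ 65/49/41% at 12/36/60 months, DLBCL-like |
| comorbidity→route log-OR | log 1.44 | published univariable OR |
| route→death log-OR | log 2.5, log 1.3, log 1.1 by window | fading mediated pathway, as published effects fade |
| A×M interaction | 0.05, 0.02, 0 | small, non-zero to keep the interaction term honest |

Model intercepts are calibrated *deterministically by exact enumeration*
(`uniroot` on the enumerated marginal) so these targets hold exactly under
the generating process, not merely approximately. Under these defaults the
implied true effects are TCE ≈ 1.46, NDE ≈ 1.35, NIE ≈ 1.08 and PM ≈ 24%
in the first window, with NIE fading to ≈ 1.01 by the third — the same
qualitative pattern as the applied study.

The generator deliberately does **not** emulate: hospital episode
structure, ICD code lists or the comorbidity scoring window; geography
(LSOA/CCG) beyond the quintile label; death-certificate-only diagnoses
(never emitted); loss to follow-up (none — every survivor is censored
administratively at 60 months); calendar trends (one diagnosis year);
confounder dependence (age, sex, deprivation and ethnicity are generated
independently, because the joint distribution is not published — only the
margins are matched). A green test therefore establishes correctness of the
*method* under a registry-shaped world, not agreement with the restricted
real data, whose Table-2/Table-3 values are out of reach by construction.

## Net survival

The Pohar Perme estimator corrects all-cause mortality for expected
(background) mortality from a population life table, weighting each
patient by the inverse of their cumulative expected survival
$1/S^*_i(t)$. The package implements it on a monthly grid with deaths at
month-end; ageing and calendar year advance on integer-year boundaries
(floor convention), the standard life-table practice. The excess-hazard
increment at month $u$ is

$$\Delta\hat\Lambda_E(u) = \frac{\sum_i w_i(u)\,dN_i(u) -
\sum_i w_i(u)\,Y_i(u)\,\lambda^*_i(u)}{\sum_i w_i(u)\,Y_i(u)},$$

and the curve is accumulated with the discrete product-integral
$\hat S_E(t) = \prod_{u\le t}\bigl(1-\Delta\hat\Lambda_E(u)\bigr)$ rather
than $\exp(-\hat\Lambda_E(t))$. This choice is deliberate: with a zero life
table the weights are all 1, the expected-hazard term vanishes, and the
product form reduces *exactly* (to machine precision) to the Kaplan–Meier
product-limit estimator — the oracle identity the suite checks at 1e-12.
The exponential form would differ from Kaplan–Meier by $O(d_u/n_u)^2$ terms
and make that clean identity impossible. With a positive background hazard
the increment can be negative, so net survival need not be monotone and can
locally exceed 1; the suite asserts boundedness in (0, 1.5] rather than
monotonicity. Variances use the weighted counting-process estimator
(reducing to a Greenwood-type form at zero background).

The bundled life-table generator uses a Gompertz hazard
$b\,e^{c\cdot\text{age}}$ (defaults $b=2\times10^{-5}$, $c=0.1$: about
0.02/yr at 70 and 0.1/yr at 85, the order of magnitude of an English life
table, with a 1.3× male scaling). The grid must cover age 104 — the oldest
possible diagnosis age plus five years of follow-up — and refuses to build
otherwise.

## Numerical choices

* **Logistic fits** use a compiled Newton–Raphson with step halving
  (`src/logit_newton.cpp`), warm-started at the full-data coefficients
  inside the bootstrap. It converges to the same solution as `stats::glm`
  (asserted to ~1e-8 in the suite); coefficients above 30 in absolute value
  or a singular information matrix raise a convergence error (separation),
  which bootstrap replicates catch and count. The compiled kernel exists
  because the bootstrap re-fits three models per replicate and the
  acceptance coverage experiment runs 20,000 replicates.
* **Degenerate curves**: if the risk set empties because everyone died, the
  survivor function is carried forward at 0; if it empties through
  censoring, the curve is truncated with a warning.
* **Zero cells** in a 2×2 table make the Wald OR undefined; the package
  errors and points at a continuity correction rather than silently adding
  0.5 (the published tables have no zero cells).
* **Ties** are impossible in the g-computation (probabilities are
  continuous); death months within a fatal window are placed uniformly on
  the integer months of the window, which only matters to the survival
  module — the mediation analysis sees only window-level indicators.
* **Percentile bootstrap** (not BCa) with default 1000 replicates: the
  interval convention of g-formula practice; the CI method behind the
  published intervals is unstated, so the conventional choice is taken and
  checked by a coverage experiment (empirical 95% coverage of the true NIE
  within [0.88, 0.99] over 100 simulated datasets).

## Known limitations

* Natural-effects identification rests on untestable no-unmeasured-
  confounding assumptions; the package encodes them, it cannot verify them.
* The closed-form conditional ORs and the marginal g-computation ORs agree
  only under collapsibility conditions; both are exposed, and the marginal
  estimator is the headline.
* Windows 2 and 3 inherit survivor selection in the mediator model, as in
  the applied analysis; the enumeration oracle targets the structural
  estimand, so small systematic gaps between the two are expected there.
* The life-table key is (age, sex, year); deprivation-specific life tables
  are a configuration hook, not implemented.
* Sensitivity analysis for unmeasured mediator–outcome confounding and
  4-way interaction decompositions are out of scope.
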