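# adaptRMST

Planning, interim monitoring and final analysis of **two-stage adaptive
group-sequential clinical trials whose primary endpoint is the difference
in restricted mean survival time (RMST)** — built for settings with a
delayed treatment effect, where hazards are expected to coincide until a
change point `t0` and diverge afterwards, so that hazard ratios are a poor
effect summary and proportional-hazards methodology does not apply.

It is aimed at trial statisticians who want to

* size a trial on the RMST difference
  `Δ = ∫₀^τ {S_I(t) − S_C(t)} dt` despite uncertain event and dropout
  rates,
* take one interim look with early stopping for efficacy (O'Brien–Fleming
  alpha spending) or non-binding futility (conditional power below a
  floor), and
* recalculate the second-stage sample size from the interim data without
  inflating the type-I error, via an inverse normal combination test
  `Z_final = w₁Z₁ + w₂Z₂` over independent stage-wise statistics.

## What is inside

| Area | Functions |
| --- | --- |
| Estimation (right-censored + left-truncated) | `km_fit`, `rmst`, `rmst_difference`, `stage_statistic` |
| Trial data model | `hazard_scenario`, `simulate_subjects`, `interim_snapshot`, `stage_two_assemble`, `assemble_full_data` |
| Planning | `solve_lambda_I`, `rmst_diff_closed_form`, `estimate_sigmas`, `fixed_sample_size`, `max_information`, `stage_one_size`, `combination_weights`, `inflation_factor`, `design_plan` |
| Sequential testing | `obf_spending`, `critical_values`, `stage_two_variants`, `combine_stages`, `logrank_z`, `tau_year_z` |
| Interim adaptation | `conditional_power`, `interim_nuisance_update`, `recalculate_n2`, `interim_decide` |
| Operating characteristics | `scenario_fixtures` (S1–S10), `run_trial_once`, `run_scenario` |

Stage-2 data of patients recruited before the interim analysis are
**left-truncated** (they contribute only conditional on being event-free
at interim); the Kaplan–Meier/RMST core handles delayed-entry risk sets
`Y(t) = #{L < t ≤ T}` natively, in compiled code. Three variants of the
stage-2 statistic are provided (truncated-data, Desseaux–Porcher, and a
combined form), plus log-rank and τ-year-survival comparator tests on the
same stage-wise datasets.

The methods vignette (`vignettes/adaptive-rmst-design.Rmd`) documents the
model, every tunable constant, the numerical choices, and the design
decisions in detail.

## Worked example

Planning a trial with a minimal clinically relevant difference
`Δ0 = 0.05` years, one-sided `α = 0.025`, power 80%, horizon `τ = 1.5`
years, accrual over 3 years, interim at 1.8 years, guessed hazards
0.4 (shared, before `t0 = 0.8`) and 0.7 (control, after), dropout rate
0.1:

```r
library(adaptRMST)
scen <- hazard_scenario(t0 = 0.8, lambda0 = 0.4, lambdaC = 0.7,
                        delta = 0.05, dropout_rate = 0.1,
                        tau = 1.5, tE = 3)
plan <- design_plan(scen, t_int = 1.8, seed = 42)
plan
#> Adaptive two-stage RMST design plan
#>   alpha = 0.025 (one-sided), power = 0.8, delta0 = 0.05, tau = 1.5
#>   n (total, gamma = 1.01) = 3256  [fixed design 3224, cap 4836]
#>   n1 = 1954 at t_int = 1.8 (accrual 3 y), I_max = 3170.9
#>   weights: w1 = 0.663, w2 = 0.748
#> Nuisance SDs (L = 100 x n = 10000): sigma1 = 1.1836, sigma1* = 1.0132, sigma21 = 1.4897
#>   expected pipeline fraction nbar1/n1 = 0.577
```

Reading: the intervention hazard implied by `Δ0` is 0.343; the
full-follow-up scaled standard deviation of the RMST-difference estimator
is `σ₁* ≈ 1.013`, giving 1628 patients per group (3256 total, including
the 1% group-sequential inflation), of whom 977 per group are recruited
before the interim analysis; the combination weights are the square root
of the expected interim information fraction.

At the interim analysis, on simulated stage-1 data from the same
scenario:

```r
set.seed(7)
subjects <- simulate_subjects(scen, plan$n1, accrual = c(0, 1.8))
x1 <- interim_snapshot(subjects, t_int = 1.8, tau = 1.5)
interim_decide(x1, plan, L_sims = 100, sim_n = 10000)
#> Interim decision: continue
#>   z1 = 2.280 vs c1 = 3.177 (info 1400.7); c_final = 1.964
#>   CP at planned n2 = 0.937; recalculated n2 = 310 (CP 0.800)
```

Reading: the interim statistic 2.28 does not cross the early
O'Brien–Fleming boundary 3.18, so the trial continues; the data are
favourable enough that conditional power at the initially planned
second-stage recruitment would be 94%, so recruitment is *cut* to the
smallest even size (310 patients, on top of the 1146 pipeline patients
still under observation) that keeps conditional power at the 80% target.

Scenario-level operating characteristics (power / type-I error, expected
sample sizes, stopping probabilities, conditional-power summaries,
sample-size histograms):

```r
res <- run_scenario(scenario_fixtures()$S1, n_mc = 1000, L_sims = 50, seed = 1)
res
```

A thin command-line front end with `plan` / `interim` / `final` /
`simulate` subcommands is installed at `inst/cli/adaptrmst`.

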