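---
title: "Adaptive two-stage trials with the restricted mean survival time"
author: "adaptRMST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive two-stage trials with the restricted mean survival time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptRMST)
```

## The problem

When a delayed treatment effect is expected — hazards identical in both
arms until some change point $t_0$ and diverging only afterwards — the
proportional-hazards assumption fails and a hazard ratio is a questionable
effect summary. The difference in restricted mean survival time (RMST),

$$\Delta = \mu_\tau^{(I)} - \mu_\tau^{(C)}, \qquad
  \mu_\tau = \int_0^\tau S(t)\,dt,$$

is a well-defined alternative: the average extra survival time gained over
a fixed horizon $\tau$. Its drawback for planning is that the sample size
depends on several nuisance quantities (event rates in both arms, the
change point, the dropout rate) that are often guessed poorly before the
trial starts. `adaptRMST` implements a two-stage adaptive group-sequential
design around the RMST difference: one interim look with the option to
stop early for efficacy or futility, and otherwise a second stage whose
recruitment is recalculated from the interim data so that the conditional
power reaches its target.

## Stage-wise data and why truncation appears

The interim analysis happens at calendar time $t_{int}$. Stage-1 data
$X_1$ are the $n_1$ patients recruited before $t_{int}$, administratively
censored at $L_j = t_{int} - E_j$ ($E_j$ the entry time). Stage-2 data
$X_2$ consist of (a) the *pipeline* patients — the $\bar n_1$ stage-1
patients still under observation at interim — contributing their full
follow-up but *left-truncated* at $L_j$, because they enter stage 2 only
conditional on being event-free at interim, and (b) the $n_2$ newly
recruited patients, untruncated. This split makes $X_1$ and $X_2$
analyzable as independent stages, which is what justifies a combination
test under data-dependent sample-size adaptation. The Kaplan–Meier
machinery in the package therefore supports delayed entry throughout: the
risk set at $t$ is $Y(t) = \#\{j: L_j < t \le \tilde T_j\}$, and with all
$L_j = 0$ the estimator reduces bit-for-bit to the usual right-censored
product-limit estimator.

Every patient is followed for exactly $\tau$ years (absent dropout), so
the same estimand is targeted at the interim and final analysis and no
information is lost by comparing RMSTs rather than hazards.

## Test statistics

For a dataset with $n$ records split 1:1, the package computes
$\hat\Delta$ from the two Kaplan–Meier curves and the scaled dispersion
$\hat\sigma^2 = n(\widehat{se}_I^2 + \widehat{se}_C^2)$, where
$\widehat{se}_i$ is the Greenwood-type standard error of the integrated
survival curve,

$$\widehat{se}^2 \;=\; \sum_{t_i \le \tau} A_i^2\,
    \frac{d_i}{Y_i\,(Y_i - d_i)},
  \qquad A_i = \int_{t_i}^{\tau} \hat S(t)\,dt .$$

The standardized stage statistic is $Z = \sqrt{n}\hat\Delta/\hat\sigma =
\hat\Delta/\sqrt{\widehat{se}_I^2+\widehat{se}_C^2}$, and the information
level is $\hat I = n/\hat\sigma^2$. A note on scaling: some presentations
scale the variance sum by the per-group count $n/2$ rather than by $n$;
the package uses $n$ throughout because that is the unique convention
under which $Z$ is asymptotically standard normal and the sample-size
formula below reproduces itself — the unit tests pin this down against a
bootstrap oracle and a null-calibration simulation.

The final test is the inverse normal combination
$Z_{final} = w_1 Z_1 + w_2 Z_2$ with pre-specified weights,
$w_1^2 + w_2^2 = 1$. Three versions of the stage-2 statistic are
available:

* **truncated** — $Z_2$ computed directly from the left-truncated $X_2$;
* **Desseaux–Porcher** — $Z_2' = (Z_{all}\sqrt{\hat I_{all}} -
  Z_1\sqrt{\hat I_1})/\sqrt{\hat I_{all}-\hat I_1}$, which avoids
  truncated-data estimation entirely by working from the full final
  dataset;
* **combined** — $Z_2'' = \hat\Delta(X_2)\sqrt{\hat I_{all}-\hat I_1}$,
  the truncated-data effect estimate with the untruncated information
  increment.

They are asymptotically equivalent (the information decomposition
$\hat I_{all} = \hat I_1 + \hat I_2 + o_p(n)$ is verified empirically in
the test suite); at trial-scale sample sizes the truncated estimator
suffers from small early risk sets, which is why the Desseaux–Porcher
variant tends to be the most powerful and is a sensible default for
planning.

## Boundaries

Critical values come from the O'Brien–Fleming-type alpha-spending
function
$\tilde\alpha(\hat I) = 2\{1-\Phi(\Phi^{-1}(1-\alpha/2)\big/
\sqrt{\hat I/I_{max}}\,)\}$ evaluated at the *observed* interim
information against the *planned* maximum information
$I_{max} = \gamma\,\{\Phi^{-1}(\alpha)+\Phi^{-1}(\beta)\}^2/\Delta_0^2$
(standard error-spending practice; if the interim information overshoots
$I_{max}$, all remaining alpha is spent at the interim look and the final
boundary is $+\infty$). The interim boundary is
$c_1 = \Phi^{-1}(1-\tilde\alpha(\hat I_1))$ and $c_{final}$ solves
$P(Z_{final}\ge c,\, Z_1 < c_1) = \alpha - \tilde\alpha(\hat I_1)$ under
the null joint law of $(Z_1, Z_{final})$, bivariate normal with
correlation $w_1$. The package evaluates that probability by the exact
one-dimensional conditioning integral
$\int_{-\infty}^{c_1}\varphi(z)\,\bar\Phi\{(c-w_1z)/w_2\}\,dz$ with
`stats::integrate` (relative tolerance $10^{-10}$) and finds the root by
bracketed search to $10^{-10}$; a 2-million-draw Monte-Carlo check in the
test suite confirms alpha conservation. One-sided testing throughout:
$H_0\colon \Delta < 0$ is rejected for large positive statistics.

## Conditional power and sample-size recalculation

Given the interim statistic $z_1$, the probability of final rejection
under the design alternative $\Delta_0$ is

$$CP(\Delta_0, z_1) = 1 - \Phi\!\left(\frac{c_{final}-w_1z_1}{w_2}
  - \Delta_0\sqrt{\frac{\bar n_1}{\sigma_{21}^2}
  + \frac{n_2}{\sigma_1^{*2}}}\right),$$

where $\sigma_1^*$ is the asymptotic SD of the full-follow-up estimator
and $\sigma_{21}$ the per-pipeline-patient analogue for the post-interim
follow-up of stage-1 patients. The decision logic at interim is:

1. stop for efficacy if $z_1 \ge c_1$;
2. otherwise re-estimate nuisance parameters (below) and stop —
   non-bindingly — for futility if $CP$ at the *initially planned* $n_2$
   falls below $CP_{min}$ (default 20%);
3. otherwise recruit the smallest even $n_2$ achieving
   $CP \ge 1-\beta_{cond}$ (default 80%), clamped to
   $[0,\,n_{max}-n_1]$: favourable interim data can make the pipeline
   patients alone sufficient ($n_2 = 0$), and if even the cap falls short
   the trial continues at the cap.

The closed-form inversion and its minimality are verified on a grid in
the tests. The boundary $c_{final}$ inside $CP$ is the one computed from
the observed interim information — the only boundary actually available
mid-trial.

### Interim nuisance re-estimation

Rates are re-estimated from the interim data by occurrence/exposure
maximum likelihood for the piecewise-exponential working model: the
shared early hazard $\hat\lambda_0$ from pooled events and person-time on
$(0, t_0]$, the control late hazard $\hat\lambda_C$ from the control arm
on $(t_0, \tau]$, and the dropout rate from censorings identified as
dropouts (censored strictly before both $\tau$ and the administrative
horizon). The intervention hazard is *not* estimated freely: it is fixed
by the constraint that the closed-form RMST difference of the working
model equals $\Delta_0$ — the design effect is imposed, only nuisance
values are updated. The change point $t_0$ is treated as known and is not
updated. If a window carries no events the planning guess is kept for
that rate (with a warning), and if $\Delta_0$ is outside the attainable
range at the updated rates the intervention hazard is clamped to the
boundary.

### Simulation-based asymptotic SDs

$\sigma_1$, $\sigma_1^*$ and $\sigma_{21}$ have no convenient closed form
under censoring, truncation, staggered entry and a piecewise hazard, so
they are estimated by simulation (`estimate_sigmas`): $L$ replicates of
$n$ subjects entering uniformly on $[0, t_{int}]$ are generated from the
working model; $\hat\sigma_1^2$ is averaged from the interim snapshots
and $\hat\sigma_{all}^2 \to \sigma_1^{*2}$ from the full $\tau$-year
follow-up. $\sigma_{21}$ is then derived from information additivity with
no new recruits, $n_1/\sigma_1^{*2} = n_1/\sigma_1^2 +
\bar n_1/\sigma_{21}^2$, i.e.
$\sigma_{21}^2 = (\bar n_1/n_1)\,/\,(1/\sigma_1^{*2} - 1/\sigma_1^2)$,
with $\bar n_1/n_1$ the simulated pipeline fraction. This derivation of
$\sigma_{21}$ is a reconstruction from the stage-wise information
decomposition — it is the only decomposition consistent with treating
pipeline information and new-recruit information as additive — and it is
guarded by the data-level conditional-power simulation in the test suite.
An estimator using the pipeline data alone is known to behave poorly and
is not offered. Defaults are $L = 100$ and $n = 10{,}000$; both matter
mainly for the *variance* of the recalculated $n_2$, and larger values
are advisable in a real trial where the computation is run once.

## Planning

`design_plan()` runs the pre-trial pipeline: solve the intervention
hazard from $\Delta_0$, estimate $\sigma_1$ and $\sigma_1^*$ at the
guessed rates, compute

$$n = \gamma\,\frac{\{\Phi^{-1}(\alpha)+\Phi^{-1}(\beta)\}^2}
  {(\Delta_0/\sigma_1^*)^2}$$

(rounded up to even; $\gamma \approx 1.01$ for the two-look
O'Brien–Fleming design, computable exactly with `inflation_factor()`),
$n_1 = n\,t_{int}/t_E$ under uniform accrual, the cap
$n_{max} = 1.5\,n_{fix}$, and the weights
$w_1 = \sqrt{(n_1/\sigma_1^2)/(n/\sigma_1^{*2})}$ — the square root of
the expected interim information fraction, which maximizes the power of
the combination test.

```{r planning, eval = FALSE}
scen <- hazard_scenario(t0 = 0.8, lambda0 = 0.4, lambdaC = 0.7,
                        delta = 0.05, dropout_rate = 0.1,
                        tau = 1.5, tE = 3)
plan <- design_plan(scen, t_int = 1.8, seed = 42)
plan
```

## The simulator and what it does (not) emulate

`simulate_subjects()` draws entry times uniformly over the accrual
window, event times from the two-piece exponential model by inversion,
and dropout times exponentially; arms are assigned by deterministic 1:1
alternation so allocation noise does not leak into operating
characteristics. The benchmark grid `scenario_fixtures()` (S1–S10) varies
the true effect (0, 0.05, 0.075, 0.1), the interim timing (1.8, 2.0, 2.2
years) and the quality of the planning guesses (multipliers on the true
rates, including one scenario with true and guessed rates interchanged so
the initial sample size is too large). Dropout rates are 0.095 (true) vs
0.090 (guessed); all scenarios use $t_0 = 0.8$, $\tau = 1.5$, $t_E = 3$,
$\alpha = 0.025$ one-sided, power 80%.

The generator is faithful to the working model, which is also the model
assumed by the recalculation machinery. Passing tests therefore
demonstrate internal validity — correct estimation, boundaries, error
control and recalculation under the stated data model — not robustness to
real-world features the model lacks: non-uniform accrual, a mis-placed
change point, non-exponential dropout, competing risks, or covariate
effects. Type-I error control of the combination test itself does not
depend on the working model (it only requires stage-wise independence),
and the test suite includes an adversarial data-dependent $n_2$ rule to
exercise exactly that guarantee.

## Numerical choices and edge cases

* Ties: tied events aggregate into one multiplicative step; censorings
  tied with an event time stay in the risk set for that event; truncated
  subjects enter the risk set strictly after $L$.
* Tail: if the last step is before $\tau$, the curve is carried forward.
  With no events before $\tau$ the RMST is $\tau$ with standard error 0,
  flagged; an event-free arm contributes zero variance with a warning.
* If a truncated risk set is exhausted ($Y_i = d_i$) the curve drops to 0
  and stays there; the residual-area Greenwood terms vanish with it.
* Sample sizes are rounded up to even integers (1:1 allocation);
  $n_1$ rounds to the nearest even integer, ties upward.
* The root searches (intervention hazard, final boundary, inflation
  factor) are bracketed bisections to $10^{-10}$ or better; the
  closed-form RMST difference is exact, so solve-then-evaluate
  round-trips at $10^{-9}$.
* Reproducibility: every simulation entry point takes a seed;
  `run_scenario()` derives per-replicate sub-seeds once from the master
  seed, so results are independent of execution order.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the planning pipeline at
$L = 100 \times 10{,}000$ subjects and the scenario engine at
$n_{MC} = 1000$ replicates with $L = 50$ for the interim re-estimation —
sizes chosen so the whole suite runs on a single desktop core in minutes
while keeping Monte-Carlo error well inside the tolerances asserted
(about 1.3 percentage points of simulation error on a rejection
probability at $n_{MC} = 1000$). A full $n_{MC} = 10{,}000$ replication
of all ten scenarios is a cluster-scale computation and is intentionally
not part of the default test run.

## Known limitations

* Two stages only; more looks would need a multivariate extension of the
  boundary computation.
* Only the O'Brien–Fleming-type spending family is implemented (a custom
  spending function can be passed to `inflation_factor()`, but
  `critical_values()` is deliberately fixed to the design's family).
* The effect size $\Delta_0$ is never adapted at interim — it is the
  minimal clinically relevant difference by design.
* The comparator log-rank and $\tau$-year tests are provided for power
  benchmarking on the same datasets (with delayed-entry risk sets for the
  truncated stage-2 data and the same combination weights); under a
  delayed effect they are typically more powerful than the RMST test, at
  the price of a less interpretable estimand.
* Estimators for left-truncated data are known to be unstable when early
  risk sets are small; prefer the Desseaux–Porcher variant at the final
  analysis.
* Among the operating characteristics, the non-binding futility-stopping
  probability is by far the most sensitive quantity to how
  $\sigma_{21}$ is estimated (it moves by several percentage points per
  0.1 change in $\sigma_{21}$, while power, expected sample sizes and the
  conditional-power summaries barely react, since recalculated trials are
  frequently capped). Because futility is non-binding, this sensitivity
  affects expected sample size under the null far more than it affects
  error rates.
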