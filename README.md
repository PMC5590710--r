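# mlmmpower

Power analysis and sample-size calculation for two-arm longitudinal
clinical trials with several correlated outcomes, built around a
multivariate linear mixed-effects model (MLMM) with correlated random
intercepts.  The motivating application is early Alzheimer's disease,
where trials follow mild-cognitive-impairment participants for years
and measure cognition with a battery of instruments (MMSE, CDR-SB,
ADAS-11) — decline is slow, no single endpoint is sensitive, and the
choice of test statistic and composite weighting drives the required
sample size by tens of thousands of participants.

## The model and the three tests

Component score $j$ of subject $n$ at time $t$ (years):

$$Y_{ntj} = \beta_{j0} + \gamma_j\,(\mathrm{Trt} \times t) + \beta_{j2}\,t + b_{nj} + \epsilon_{ntj},
\qquad b_n \sim N_J(0,\Sigma_b),\quad \epsilon_{nt} \sim N_J(0,\Sigma_\epsilon).$$

With known covariances the GLS estimator of the treatment-by-time
interaction vector $\gamma$ has covariance $\Sigma_{\gamma 1}/N$,
computed from the visit schedule.  Three Wald tests are supported, each
noncentral chi-square under an alternative $\gamma^*$:

| statistic | tests | df | per-participant noncentrality |
|---|---|---|---|
| $\Xi_J$ | $\gamma = 0$ | $J$ | $\gamma^{*\prime}\Sigma_{\gamma 1}^{-1}\gamma^*$ |
| $\Xi_{JC}(w)$ | $w'\gamma = 0$ | 1 | $(w'\gamma^*)^2/(w'\Sigma_{\gamma 1}w)$ |
| $\Xi_C(w)$ | composite-score effect | 1 | $(w'\gamma^*)^2/\sigma^2_{\gamma 1}(w)$ |

Required size: $N = \lceil \lambda_{req}/\lambda_1 \rceil$ total across
both arms.  The package derives the optimal weights
$w^*_{JC} \propto \Sigma_{\gamma 1}^{-1}\gamma^*$ (closed form) and
$w^*_C$ (numerical maximization), a Bonferroni per-component
comparator, one-sided Z variants, a trial simulator with Monte-Carlo
power as a brute-force check, and an EM fitter (`mlmm_fit()`) that
estimates all model parameters from longitudinal data and feeds them
back into the power engine.

## Worked example

```r
library(mlmmpower)

params <- adni_mci_params()          # packaged MCI population parameters
effect <- effect_spec(0.25)          # treatment removes 25% of each annual rate
design <- trial_design(duration = 2) # biannual visits at 0, 0.5, 1, 1.5 years

power_analysis(params, effect, design, statistic = "JC", weights = "optimal_jc")
#> Wald test 'JC' with weights (optimal_jc) 0.7755, 0.4850, 0.4042
#>   df = 1, per-participant noncentrality = 0.000460388
#>   required noncentrality (alpha = 0.05, power = 0.8) = 7.84886
#>   required total sample size N = 17049 (about 8525 per arm)

bonferroni_sample_size(params, effect, design)$n_required
#> [1] 63646
```

Reading: testing the optimally weighted combination of the three
treatment effects needs about 17,000 participants in a 2-year trial to
detect a 25% slowing of decline with 80% power — the MMSE dominates the
optimal weights — while powering each instrument separately at
$\alpha/3$ would need nearly four times as many.  Longer follow-up
helps dramatically (`sample_size_table(params, effect, 2:6)` shows the
same test needs ~650 participants over 6 years), and
`empirical_power()` confirms any cell of that table by simulation.

The installed `exec/mlmm-power` script exposes the same operations from
the shell, e.g. `mlmm-power table3 --out table3.csv`.

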