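# paircop

Bivariate survival modelling for **paired-organ failure times** — two
right-censored event times per subject (the motivating case: right and
left kidney failure in a hospital registry of kidney-disease patients).
Because both organs belong to the same person, the two times are
dependent, and each subject falls into one of four censoring patterns:
both failures observed, right only, left only, or neither.

`paircop` joins two parametric marginal regressions through an
Archimedean copula,

S(t₁, t₂ | z) = C_η{ S₁(t₁ | z), S₂(t₂ | z) },

with Clayton (η > 0), Gumbel or Joe (η ≥ 1) dependence, and Weibull or
Gompertz proportional-hazards or log-logistic proportional-odds margins
sharing one coefficient vector β across the two organs. Kendall's τ is
reported as a closed-form (Clayton: τ = η/(η+2); Gumbel: τ = (η−1)/η)
or series (Joe) function of η. Estimation is two-stage maximum
likelihood — margins first under working independence, then the
dependence parameter, then a joint refinement — with Wald inference
(odds ratios and 95% CIs), AIC/BIC selection over the 3×3
margin-by-copula grid, univariable screening at the 25% rule, and
graphical adequacy diagnostics. A seeded synthetic-cohort generator
reproduces the covariate frequencies, dependence level, and
censoring-pattern mix of a 431-patient kidney registry for testing and
method study.

## Worked example

```r
library(paircop)

cfg    <- default_config(seed = 2026)   # 431 subjects, tau = 0.41
cohort <- generate_cohort(cfg)
pattern_table(cohort)
#>   pattern count   percent
#> 1   (0,0)   269 62.412993
#> 2   (1,0)    34  7.888631
#> 3   (0,1)    27  6.264501
#> 4   (1,1)   101 23.433875

covs <- c("male", "famhist", "age36_55", "age56plus",
          "diabetes", "hypertension", "anemia", "obesity")
fit <- two_step_fit(cohort$data, covs, "loglogistic", "clayton")
fit
#> Joint loglogistic-clayton copula survival model (n = 431)
#>   log-likelihood -2176.74 | AIC 4371.48 | BIC 4408.08 (K = 9)
#>   eta = 1.95 (SE 0.35), Kendall's tau = 0.49
#> Coefficients:
#>              estimate   se p_value   OR ci_lo ci_hi
#> male             0.51 0.19    0.01 1.67  1.16  2.40
#> famhist          0.22 0.20    0.27 1.24  0.84  1.84
#> age36_55        -0.05 0.26    0.86 0.95  0.58  1.58
#> age56plus        0.40 0.20    0.05 1.49  1.00  2.22
#> diabetes         0.51 0.19    0.01 1.67  1.15  2.42
#> hypertension     0.86 0.20    0.00 2.36  1.61  3.46
#> anemia           0.44 0.20    0.03 1.56  1.05  2.30
#> obesity          0.06 0.18    0.76 1.06  0.74  1.52
#> eta              1.95 0.35    0.00   NA    NA    NA
```

Read the rows as a regression table: `OR = exp(estimate)` is the
odds ratio of failure for that covariate under the proportional-odds
margin (e.g. hypertensive patients have 2.36 times the failure odds in
this draw), and the final row is the copula dependence parameter with
its delta-method SE — here η̂ = 1.95 (τ̂ = 0.49), within two standard
errors of the generating η = 1.39 (τ = 0.41) at this cohort size.

Model selection over all nine margin–copula pairs:

```r
compare_grid(cohort$data, covs)
#>        margin  copula     AIC     BIC final_llk  tau K   n converged
#> 1     weibull clayton 4371.06 4407.66  -2176.53 0.49 9 431      TRUE
#> ...
#> 7 loglogistic clayton 4371.48 4408.08  -2176.74 0.49 9 431      TRUE
#> ...
#> Selected (min AIC): weibull-clayton
```

The Clayton copula wins in every margin family; at n = 431 the Weibull
and log-logistic margins are within half an AIC point of each other —
single-cohort selection between close marginal families is noisy, which
is why the test suite checks selection consistency across 25 replicates
at n = 2000. Diagnostics (`km_survival()` + `linearization_coords()`
for the margins, `copula_scatter()` for the copula) return plot-ready
coordinates with a straightness score and empirical-tau comparison. The
whole analysis — screen, grid, final fit, diagnostics, manifest — runs
from one configuration with `run_pipeline()`, or from the shell via
`inst/cli/paircop.R`.

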