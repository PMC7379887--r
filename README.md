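# rnakinetics

Kinetic modeling of the gene-level RNA life cycle: synthesis of premature
RNA, its processing into mature RNA, and degradation of the latter. The
package is for researchers studying transcriptional and
post-transcriptional regulation from replicated expression time courses —
with or without nascent-RNA (metabolic-labeling) measurements of the
synthesis rate — and for anyone who wants to explore, without data, how
combinations of kinetic rates shape premature and mature RNA profiles.

## The model

The abundances of premature RNA *P* and mature RNA *M* follow

    dP/dt = k1(t) − k2(t)·P
    dM/dt = k2(t)·P − k3(t)·M

where k1 is the synthesis rate (RNA units·h⁻¹), k2 the processing rate
(h⁻¹) and k3 the degradation rate (h⁻¹). With constant rates the system
sits at the steady state P = k1/k2, M = k1/k3. Each rate is a constant,
a four-parameter sigmoid, or a six-parameter impulse (product of two
sigmoids) in time. Which rates vary defines a *regulatory class*, coded by
the letters s/p/d for variable synthesis/processing/degradation (e.g.
`"sd"`; the all-constant class is `"no-reg"`).

The package:

* solves the ODE system with an adaptive RK45 integrator (`solve_kinetics()`),
* fits rate-function parameters to replicated time courses by weighted
  least squares with multi-start Nelder–Mead or BFGS (`fit_kinetics()`),
* scores fits with two-tailed chi-squared p-values and the AIC
  (χ² + 2k) and compares regulatory classes (`select_model()`),
* computes profile-likelihood confidence intervals
  (`confidence_intervals()`),
* generates ground-truth models and noisy replicated profiles
  (`random_model()`, `simulate_profile()`),
* ships a command-line interface (`kinetics_cli()`, also installed at
  `inst/cli/rnakinetics`) with `simulate`, `solve`, `steady-state`,
  `fit`, `select` and `ci` subcommands.

Fits are tibble-friendly: `tidy()` returns the parameter table,
`glance()` the fit statistics, and `autoplot()` works on profiles,
trajectories and fits.

## Worked example

Simulate a gene whose synthesis rate doubles mid-course, then recover the
regulation from the noisy data:

```r
library(rnakinetics)

truth <- kinetic_model(
  k1 = rate_sigmoid(h0 = 2, h1 = 4, t1 = 6, beta = 1), # synthesis doubles at 6 h
  k2 = rate_constant(1),                               # processing, 1/h
  k3 = rate_constant(0.5)                              # degradation, 1/h
)
prof <- simulate_profile(truth, n_replicates = 3,
                         noise = noise_model(level = 0.05), seed = 42)

fit <- fit_kinetics(prof, class = "s", seed = 1)
glance(fit)
#> # A tibble: 1 × 10
#>   class objective   dof     p_value   aic n_free_params converged n_iterations
#>   <chr>     <dbl> <int>       <dbl> <dbl>         <int> <lgl>            <int>
#> 1 s          84.6    30 0.000000837  96.6             6 TRUE              8890
tidy(fit)
#> # A tibble: 6 × 4
#>   rate  form     term    estimate
#>   <chr> <chr>    <chr>      <dbl>
#> 1 k1    sigmoid  k1.h0      2.03
#> 2 k1    sigmoid  k1.h1      4.08
#> 3 k1    sigmoid  k1.t1      6.00
#> 4 k1    sigmoid  k1.beta    1.01
#> 5 k2    constant k2.h0      0.998
#> 6 k3    constant k3.h0      0.503
```

The fitted parameters land on the truth (k1: 2→4 around 6 h with unit
slope; k2 ≈ 1; k3 ≈ 0.5). Note the tiny two-tailed p-value despite the
correct model: the objective is weighted by empirical 3-replicate
variances, whose sampling noise inflates the chi-squared statistic (84.6
on 30 degrees of freedom) — exactly the situation the two-tailed test is
meant to flag, and the reason the package's calibration experiments use
known variances (see the vignette). Comparing regulatory classes:

```r
select_model(prof, classes = c("no-reg", "s", "sp", "sd"), seed = 1)[, 1:7]
#> # A tibble: 4 × 7
#>    rank class  n_free_params objective   dof     p_value     aic
#>   <int> <chr>          <int>     <dbl> <int>       <dbl>   <dbl>
#> 1     1 sd                 9      75.8    27 0.00000318     93.8
#> 2     2 s                  6      84.6    30 0.000000837    96.6
#> 3     3 sp                 9      83.6    27 0.000000213   102.
#> 4     4 no-reg             3   14477.     33 0           14483.
```

`no-reg` is rejected outright — it cannot explain the doubling. On this
particular draw the AIC narrowly prefers `sd` over the generating `s`
(93.8 vs 96.6): with only three replicates the noisy variance weights let
a richer class chase a few ill-weighted points. Under known variances the
same procedure ranks the generating class first in 94% of repetitions
(`scripts/acceptance.R`); with small replicate numbers, treat
near-ties in AIC as ties. The same analysis from a shell:

```sh
rnakinetics simulate --class s --seed 42 --cv 0.05 --out demo
rnakinetics fit --profile demo_profile.tsv --class s --seed 1 --out demo_fit.json
rnakinetics select --profile demo_profile.tsv --classes no-reg,s,sp,sd --out demo_sel.json
```

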