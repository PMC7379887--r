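---
title: "Modeling the RNA life cycle: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the RNA life cycle: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnakinetics)
```

## The model

The life cycle of a transcript is reduced to three first-order steps:
synthesis of premature (intron-containing) RNA at rate $k_1(t)$ (RNA
units·h$^{-1}$), processing of premature into mature RNA at rate $k_2(t)$
(h$^{-1}$), and degradation of mature RNA at rate $k_3(t)$ (h$^{-1}$). The
abundances $P(t)$ and $M(t)$ of the two species then obey

$$
\frac{dP}{dt} = k_1(t) - k_2(t)\,P, \qquad
\frac{dM}{dt} = k_2(t)\,P - k_3(t)\,M .
$$

When all three rates are constant the system settles at the steady state
$P = k_1/k_2$, $M = k_1/k_3$ (`steady_state()`); with at least one variable
rate the trajectories are obtained numerically (`solve_kinetics()`).

Each rate is parameterized by one of three functional forms
(`rate_constant()`, `rate_sigmoid()`, `rate_impulse()`):

* a **constant** $f(t) = h_0$ (1 parameter);
* a **sigmoid** $f(t) = h_0 + (h_1 - h_0)\,\sigma(\beta (t - t_1))$ with
  $\sigma(x) = 1/(1+e^{-x})$ (4 parameters: start level, final level,
  transition time, slope);
* an **impulse**, the product-of-sigmoids form
  $$
  f(t) = \tfrac{1}{h_1}\,
  \bigl[h_0 + (h_1-h_0)\,\sigma(\beta(t-t_1))\bigr]\,
  \bigl[h_2 + (h_1-h_2)\,\sigma(-\beta(t-t_2))\bigr]
  $$
  (6 parameters), which produces double-sigmoid or bell-shaped responses.
  The $1/h_1$ normalization makes the plateau between well-separated
  transitions equal $h_1$ exactly, and the asymptotes equal $h_0$ and
  $h_2$. A single slope $\beta$ is shared by both transitions, keeping the
  count at six parameters. This is the canonical parameterization of
  impulse-like expression responses; implementations without the
  normalization exist, so numerical comparisons across tools should check
  which convention is in use.

Levels are strictly positive (they are physical rates), $\beta > 0$, and
the impulse requires $t_1 < t_2$; all of this is validated at
construction. Time is linear, in hours — no log-time warping is applied.

Which rates are variable defines the **regulatory class**
(`regulatory_class()`): `"s"`, `"p"`, `"d"` flag variable synthesis,
processing, degradation, in that order; `"no-reg"` is the all-constant
class. A two-letter code such as `"sd"` leaves the *form* of the variable
rates open; functions taking a class code accept `variable_form =
"sigmoid"` (default) or `"impulse"`.

## Solving the ODE system

`solve_kinetics()` integrates the system with an adaptive
Cash–Karp Runge–Kutta 4(5) scheme implemented in C++ (defaults
`rtol = 1e-6`, `atol = 1e-9`), evaluating the solution exactly at the
requested times. The kernel is compiled because the fitting objective calls
the solver thousands of times per fit; an R-level integrator would dominate
the runtime of every downstream analysis. Two independent routes verify it
in the test suite: the exact closed-form solution for constant rates
(`closed_form_constant()`, including the degenerate branch where
$k_2 = k_3$ within a relative tolerance of $10^{-7}$ and the solution
acquires a $\tau e^{-k\tau}$ term), and a `deSolve::ode()` integration with
the rates evaluated in R.

Initial conditions default to the equilibrium implied by the rate values at
the first requested time: perturbation experiments start from a
pre-perturbation steady state, and trajectories begin on a flat plateau
when the transitions lie inside the window. An explicit `initial =`
override exists for studying relaxation from out-of-equilibrium states and
is used by the solver-vs-oracle checks; it is not the default because
observed time courses are modeled as perturbations of a steady state.
Integration output is clipped at zero (the system is positive; clipping
only ever removes tolerance-level undershoots, and a substantially negative
state raises an error instead).

## The objective and its statistics

Fitting (`fit_kinetics()`) minimizes

$$
\chi^2(\theta) = \sum_{\text{species}} \sum_{t}
\frac{\bigl(\hat y(t) - \bar y(t)\bigr)^2}{s(t)^2 / n_{\text{rep}}},
$$

the squared residuals between model predictions and observed replicate
means, weighted by the variance of the mean. Species are premature and
mature RNA and, when nascent-RNA measurements are available, the synthesis
rate itself, predicted directly by $k_1(t)$. Standard deviations are floored
at $\max(10^{-6},\, 0.01\,|\bar y|)$ so a degenerate replicate set cannot
receive infinite weight; floored points are reported. Under Gaussian
replicate error with known variances the minimized value is a chi-squared
statistic with $n_{\text{obs}} - k$ degrees of freedom, which motivates the
two reported statistics (`goodness_of_fit()`):

* the **two-tailed chi-squared p-value**,
  $p = \min\{1, 2\min(F(\chi^2), 1 - F(\chi^2))\}$ — two-tailed because an
  implausibly *good* fit flags misspecified variances or overfitting just
  as a poor fit flags a wrong model;
* the **AIC**, $\chi^2 + 2k$ with $k$ the free-parameter count, treating
  $\chi^2$ as $-2\log L$ up to a data-only constant. The constant cancels
  when comparing regulatory classes on the same data, which is the only
  use the package makes of the AIC (`select_model()`).

### Optimization

The optimizer works in a transformed space: levels and slopes on the log
scale (positivity by construction), the first transition time in plain
hours with a quadratic penalty outside the observation window extended by
one window-length on each side, and the impulse's second transition as
$\log(t_2 - t_1)$, enforcing the ordering. Minimization uses `stats::optim`
with Nelder–Mead (default) or BFGS, multi-started: the first start inverts
the steady-state relations at the first and last observations (anchored at
a unit degradation rate when synthesis is not observed, since a single
steady state cannot identify the overall scale) and places the transition
at the steepest observed change; the remaining `n_starts - 1` starts (5
total by default) jitter it with seeded Gaussian noise of sd 0.5 in the
transformed coordinates (scaled to an eighth of the window for transition
times). The best start is continued once more to firm up convergence. All
randomness flows from the `seed` argument: identical seed and inputs give
bit-identical results.

`select_model()` fits candidate classes in order of increasing complexity
and warm-starts every class with embeddings of already-fitted strictly
nested classes (a constant embeds in a sigmoid with $h_1 = h_0$; a sigmoid
in an impulse with $h_2 = h_1$, which makes the second factor exactly
constant). Because Nelder–Mead never returns a value worse than its
starting point, a richer class can never end with a larger minimized
$\chi^2$ than a class nested within it. Identical candidate codes receive
identical derived seeds and therefore tie exactly; ties are broken by
fewer free parameters, then lexicographically by code.

One exact special case bypasses optimization: a single steady-state time
point with observed synthesis and the all-constant class is solved by
inverting the steady-state relations ($k_1$ = observed synthesis,
$k_2 = k_1/P$, $k_3 = k_1/M$); with three observations and three
parameters the fit is exact and no p-value is defined.

### Confidence intervals

`confidence_intervals()` profiles the likelihood rather than inverting a
Hessian: impulse parameters in particular are strongly non-linear, and
curvature-based intervals misbehave near boundaries. For each parameter
the re-minimized $\chi^2$ (all other parameters free) is traced outward
from the estimate until it exceeds the minimum by the $\chi^2_1$ quantile
of the requested level (3.84 at 95%); the crossing is then located by root
bracketing. Search happens in the transformed space, so positivity floors
appear as transform bounds; a bound reached without a crossing is reported
at the window edge and flagged unbounded. For the impulse's second
transition the profiled coordinate is the gap $t_2 - t_1$, and the
reported bound is the inner-optimal $t_1$ plus the profiled gap.

## The synthetic-data generator

`random_model()` and `simulate_profile()` define the study conditions used
throughout the tests; no experimental data ships with the package.

* **Rate ranges**: levels are drawn log-uniformly, by default $k_1 \in
  [0.5, 50]$ units·h$^{-1}$, $k_2 \in [0.5, 20]$ h$^{-1}$, $k_3 \in
  [0.05, 5]$ h$^{-1}$ — plausible mammalian scales (processing typically
  minutes-to-an-hour, half-lives minutes-to-tens-of-hours). These are
  documented defaults, not claims about any particular dataset.
* **Effect sizes**: for a variable rate the second level is the starting
  level times a log-uniform fold change in $[2, 8]$, direction random,
  clamped to the range. Tying the levels guarantees a variable rate is
  genuinely regulated; two independent log-uniform draws can land within
  noise of each other, making the generating class unidentifiable by
  construction rather than by any property of the method.
* **Sampling design**: 12 time points over 16 h, denser early
  (`default_time_grid()`), 3 replicates — a typical perturbation
  time-course design.
* **Noise**: Gaussian per replicate with coefficient of variation 0.1 by
  default (`noise_model()`), truncated at zero (negative draws are clipped
  and counted). Count-based noise is out of scope: the fitting model
  assumes mean–sd summaries, and the generator emulates exactly what the
  fit assumes.
* **sd reporting**: by default profiles carry the empirical replicate sd.
  A `sd_mode = "theoretical"` option reports the exact noise-law sd
  instead. The calibration-style validation experiments (p-value
  uniformity, interval coverage, AIC ranking accuracy) use this mode
  deliberately: with three replicates the empirical variance has two
  degrees of freedom, each standardized residual is $t_2$- rather than
  normally distributed, and neither uniform p-values nor nominal 95%
  coverage is a property *any* correct implementation would exhibit under
  those weights ($\Pr(|t_2| < 1.96) \approx 0.81$). The known-variance
  mode isolates the property actually under test — that the objective,
  statistics and interval machinery are correct under the model's own
  assumptions.

What the generator does **not** emulate: sequencing-count noise and
library-size effects, intron/exon quantification ambiguity, correlated
replicates, multi-gene coupling, and model misspecification (real rate
modulations are not exact sigmoids). Passing the simulation studies
therefore demonstrates internal correctness and calibration, not that the
three-form family describes any particular gene.

## Validation experiments and problem sizes

The acceptance-style experiments (in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) use: 1000 random triples for
steady-state exactness; 100 random constant-rate models with
out-of-equilibrium starts for solver-vs-closed-form agreement (max
relative error below $10^{-5}$); 50 repetitions each for constant and
sigmoid parameter recovery (cv 0.05; median relative level error below 5%
and 15%); 50 repetitions of four-way model selection at cv 0.1 (AIC picks
the generating class at least 80% of the time); 200 repetitions for
p-value calibration (Kolmogorov–Smirnov distance from uniform below 0.15)
and for 95% interval coverage (within [0.90, 0.99]). The
identifiability-sensitive experiments (recovery, selection, coverage)
draw $k_2 \in [0.5, 8]$ and $k_3 \in [0.2, 2]$ so response timescales fit
inside the 16 h window — a gene with a 20 h mature half-life is simply not
measurable in a 16 h course, and including such draws would test the
experimental design rather than the estimator. These sizes are the
package's chosen study conditions and keep the full suite in the
several-minute range.

## Known limitations

* Identifiability without nascent RNA: from $P$ and $M$ profiles alone the
  overall scale of the rates is weakly constrained (at a single steady
  state it is not constrained at all); estimation of full rate sets from
  total RNA alone is deliberately not claimed.
* The impulse fit is multimodal; five starts suffice on the simulated
  designs, but pathological profiles may need more (`n_starts`).
* Profile-likelihood intervals assume the weighted-Gaussian objective;
  with empirical 3-replicate variances they are approximate, as discussed
  above.
* For the same reason, with few replicates the chi-squared statistic is
  inflated and AIC comparisons can tip toward slightly richer classes on
  individual datasets (a richer model can chase a few ill-weighted
  points). More replicates, or externally estimated variances, stabilize
  both; near-ties in AIC should be read as ties.
* The integrator is a non-stiff RK45; rate ratios within the documented
  ranges (stiffness ratio up to a few hundred) are handled by step
  adaptation, but extreme user-supplied ratios may be slow.
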