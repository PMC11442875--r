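---
title: "Modeling impedance-based T-cell killing assays"
author: "rtcafit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling impedance-based T-cell killing assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcafit)
```

## The experiment and its observable

Real-time cell analysis (RTCA) instruments such as the xCELLigence measure
the electrical impedance of micro-electrode culture wells every few minutes
and report it as a dimensionless **cell index (CI)**, a proxy for the number,
size and attachment strength of adherent cells.  In a killing assay, target
cancer cells are seeded and left to attach and grow for 20-24 h until the CI
is in the working range (0.5-1); effector T cells are then added at one or
more effector-to-target (E:T) ratios and the plate is followed for a further
48-72 h.  Because effector T cells stay in suspension they are invisible to
the electrodes: a falling CI after treatment is specifically the loss of
attached cancer cells.

Two summary statistics are standard.  **Percent cytolysis** at time $t$ is

$$\%\,\mathrm{lysis}(t) = \frac{CI_{\text{no effector}}(t) -
  CI_{\text{effector}}(t)}{CI_{\text{no effector}}(t)} \times 100,$$

computed after both wells are normalized to their CI just before effector
addition.  The **Killing Time** $KT_p$ is the earliest post-treatment time at
which the cytolysis curve reaches the threshold $p$; when the curve never
reaches $p$ within the observation window the entry is *not detected* (ND),
which is itself informative — it is the signature of a resistant target.

## The population model

The package models one well as $M$ cancer subpopulations $y_1,\dots,y_M$ (in
CI units) interacting with active ($x_A$) and exhausted ($x_E$) T cells (in
CI-equivalent units):

$$\dot y_i = r_i y_i\Bigl(1 - \tfrac{\sum_j a_j y_j}{K}\Bigr) - d_i y_i
  - h_i y_i x_A,$$
$$\dot x_A = r_A x_A\Bigl(1 - \tfrac{b_A x_A + b_E x_E}{C}\Bigr)
  - x_A \sum_j l_j y_j,$$
$$\dot x_E = x_A \sum_j l_j y_j - d_E x_E.$$

The assumptions are deliberately minimal.  Cancer cells grow logistically
and compete for space and nutrients through the weighted load
$\sum_j a_j y_j$ against a carrying capacity $K$.  Killing follows mass
action: each encounter between a cancer cell and an active T cell removes
cancer signal at rate $h_i$ and simultaneously pushes T cells toward
exhaustion at rate $l_j$ — active T cells are *consumed* by the killing they
perform, which is what lets a finite effector dose stall against a resistant
target.  Exhausted cells are inert and are cleared at rate $d_E$.  T cells
have their own logistic term (capacity $C$, weights $b_A$, $b_E$) but do not
compete with cancer cells for space, since they are in suspension.  The
observable is $\sum_i y_i(t)$ only.

Heterogeneity matters: real growth curves show multiple growth phases, and a
single logistic population cannot reproduce them.  Three subpopulations
($M = 3$) with staggered saturation levels $K(1 - d_i/r_i)$ are the default
for fitting real traces; every function takes $M$ from the parameter object,
so $M = 1$ is available for controlled synthetic work.

All rates are per hour and capacities are in CI units.  The default search
box used for fitting is wide: $r, d, r_A, d_E \in [0, 50]$,
$a, b \in [10^{-3}, 1]$, $h, l \in [0, 5]$, $K, C \in [1, 100]$.

## Numerics

The system is solved with a classic fourth-order Runge-Kutta scheme with
step-doubling error control: each step is computed once at full size and
twice at half size, the scaled discrepancy $\lVert y_{2h} - y_h \rVert / 15$
is compared against `atol + rtol * |y|` (defaults $10^{-9}$ and $10^{-6}$),
and accepted states take the locally extrapolated fifth-order combination.
Three choices are specific to this model:

* **Nonnegativity.**  The model is only meaningful on the nonnegative
  orthant.  A step whose accepted state would contain a negative component
  is rejected and retried at half size; accepted components with magnitude
  below $10^{-12}$ are floored to zero, so extinct populations are exactly
  extinct.
* **Dense output.**  Accepted steps store state and derivative, and the
  solution is evaluated between them by cubic Hermite interpolation.  The
  maximum step defaults to 1/12 h — the instrument's 5-minute cadence — which
  keeps the interpolation error at the level of the integration tolerance
  (the closed-form checks in the test suite bound the relative error against
  analytic logistic and exponential solutions below $10^{-6}$ on the full
  72-h 5-minute grid).
* **The treatment jump.**  Effector addition is a discontinuity in $x_A$.
  The integrator is stopped exactly at the treatment time and restarted with
  the augmented state, so no step straddles the jump and the cancer
  components stay continuous across it.

Everything is deterministic: identical inputs produce bit-identical
trajectories, which the fitter relies on to cache elite scores.

Two conventions close gaps the experiment leaves open.  The measured initial
CI is split equally across the $M$ subpopulations (configurable via
`fractions`); initial fractions are confounded with the per-population rates
anyway, so any fixed convention is equivalent up to relabeling.  The
CI-equivalent magnitude of the effector bolus is taken as
$x_A(0) = \text{E:T ratio} \times CI(t_{\text{treat}})$, which makes the
interaction rates comparable across wells with different attachment levels.

## The macroevolutionary fitter

Parameters are estimated by minimising the least-squares distance between
the simulated observable and the measured CI over all series and timestamps.
The optimizer maintains a population of $N$ parameter vectors (reference
size $N = 1000$).  Each generation:

1. every vector is scored by least squares (elites keep their cached score);
2. the best 25% survive unchanged;
3. another 25% are perturbed copies of the survivors,
   $p' = p\,(1 + \beta)$ with $\beta \sim U(-0.02, 0.02)$ drawn
   independently per component and clamped to the search box;
4. the remaining 50% are fresh uniform draws from the box.

The wide random refresh keeps exploring the full box while the
perturbation stream fine-tunes the incumbent solutions, which suits the
rugged, ridge-riddled landscapes that ODE least squares produces.
Elitism guarantees the best score is non-increasing — asserted on every run.
Ties rank by insertion order, and the whole run is a pure function of
(data, configuration, seed).  The result retains the best 250 vectors; the
reported fit is the single best, and `top_k_summary()` gives the
component-wise median and interquartile range of the retained set, a cheap
picture of how tightly the data pin each component.

Fitting is staged, mirroring the experimental design.  **Stage 1** estimates
the intrinsic parameters $r_i, d_i, a_i$ and $K$ from effector-free wells
with the T-cell equations removed (reference budget $\tau = 10^4$
generations).  $K$ must be estimated here because the growth model cannot be
simulated without it; it is then frozen.  **Stage 2** fixes the intrinsic
parameters and estimates $h_i, l_i, b_A, b_E, r_A, d_E, C$ from the
co-culture wells, jointly across E:T ratios (reference budget
$\tau = 10^3$).

### Identifiability: what a growth curve can and cannot pin down

For $M = 1$ the growth-only model collapses to
$\dot y = (r - d)\,y - (r a / K)\,y^2$: a single growth trace determines
exactly two combinations — the net growth rate $r - d$ and the logistic
curvature $r a / K$ — while $r$, $d$, $a$ and $K$ individually lie on a flat
two-dimensional ridge.  The fitter will return *some* point on that ridge;
which one is an accident of the search history.  The package's recovery
tests therefore assert the identifiable combinations (and the fitted
trajectory's RMSE), and deliberately document that an assertion on $K$
itself fails for this reason.  Interpretations of fitted single-curve
parameters should be phrased in terms of $r - d$, $r a / K$ and the plateau
level; separating $K$ from $a$ requires either multiple wells at different
seeding densities or an independent capacity measurement.  (For $M > 1$ the
situation is analogous per subpopulation, with the staging of the growth
phases adding partial information.)

## The synthetic-data generator

Because raw RTCA exports are rarely public, the generator emulates the assay
end to end so every stage is testable against known ground truth: sampling
every 5 min (default), a 24-h attachment/growth phase, effector addition at
ratios 0.5/1/2, and a 48-72-h follow-up.  Observations follow
$CI_{\text{obs}} = CI(1 + \varepsilon_m) + \varepsilon_a$ with
$\varepsilon_m \sim N(0, 0.02)$ and $\varepsilon_a \sim N(0, 0.005)$,
floored at zero.  Impedance noise scales with signal, hence the
multiplicative term; the magnitudes are mild defaults, not measurements, and
are configurable.  An optional positive spike (default $0.2 \times CI$, one
sample wide) emulates the transient caused by taking the plate out of the
incubator to add effectors.  It is placed on the first sample *after* the
treatment time — the first reading after the plate is re-docked — so the
normalization reference (the last sample at or before treatment) is always
clean.  Each well draws from its own seed substream; adding a well never
changes the others, and a `record` object regenerates any dataset
bit-exactly.

The generator reproduces the timing, noise structure and phenotypes of the
assay, not the instrument: no baseline drift, no evaporation, no well-edge
effects, no electronic artifacts beyond the single spike.  Passing recovery
tests on synthetic data therefore demonstrates that the estimation machinery
is correct and well-conditioned under the stated noise model — it does not
guarantee the model is adequate for any particular real cell line.

`make_benchmark_suite()` bundles four standing cases: single-population
growth, three-population multi-phase growth, and two co-culture panels — a
"sensitive" truth (high cytolysis rate; reaches 80% cytolysis, finite
$KT_{80}$) and a "resistant" truth (low cytolysis rate, fast exhaustion;
cytolysis plateaus, $KT_{80}$ ND at every ratio).  The pair reproduces the
qualitative contrast between FASN-knockout and parental HAP1 target cells
that motivates the model, and `hap1_reference_parameters()` provides the
corresponding fitted parameter sets for forward simulation.

## Problem sizes and test budgets

The reference budgets ($N = 1000$, $\tau = 10^4/10^3$) are for fitting real
5-minute traces.  The package's own test and acceptance runs use smaller,
fixed configurations chosen once: stage-1 recovery uses $N = 200$,
$\tau = 500$ on a 24 h + 48 h design; stage-2 recovery uses $N = 150$,
$\tau = 300$ on a 15-minute, 24 h + 36 h design; optimizer invariants use
$N = 100$, $\tau = 100$.  At these sizes the identifiable growth
combinations are recovered to a few percent under 2% multiplicative noise
and the stage-2 fit reproduces the noise-free end-point cytolysis to well
under five percentage points.

## Degenerate inputs and edge behavior

Zero states are exact equilibria and stay exactly zero.  A step-size
underflow (tolerance unattainable above the minimum step) raises an error
naming the failure time in direct simulation, and scores the offending
vector as infinitely unfit inside the fitter.  Percent cytolysis is
undefined when the control CI is zero and errors; it may legitimately
exceed zero in both directions and is never clamped below 100.  Negative
cytolysis (effector well outgrowing the control) is reported as computed.
$KT$ at a threshold the curve touches exactly is the first touching sample;
crossings are interpolated linearly between bracketing samples.

## Limitations

The model is deterministic and well-mixed: no spatial structure, no delays,
no stochastic extinction, no direct impedance contribution from T cells,
and no distinction between detachment and death.  The two-stage protocol
inherits stage-1 estimates as fixed truths; stage-2 uncertainty is
conditional on them.  The `top_k` ensemble spread is a search-diversity
diagnostic, not a posterior: it has no calibrated coverage.
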