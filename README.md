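# rtcafit

Tumor/T-cell population dynamics from real-time impedance cytotoxicity
assays.

Impedance-based real-time cell analysis (RTCA, e.g. xCELLigence) reports a
**cell index (CI)** — a proxy for attached cancer cell mass — every few
minutes while effector T cells kill target cells in a culture well.  The
standard readouts are **% cytolysis**,
`(CI_no_effector − CI_effector) / CI_no_effector × 100`, and the **Killing
Time** KT_p, the earliest post-treatment time at which cytolysis reaches a
threshold *p* ("ND", not detected, when it never does).  Those curves hide
kinetic structure: whether a target line resists killing because it grows
faster, tolerates more T-cell pressure, or exhausts its attackers.

`rtcafit` is for researchers who want to go from raw CI traces to
interpretable kinetic parameters.  It models a well as *M* heterogeneous
cancer subpopulations under logistic competition, killed by active T cells
that become exhausted in the process:

    dy_i/dt = r_i y_i (1 − Σ_j a_j y_j / K) − d_i y_i − h_i y_i x_A
    dx_A/dt = r_A x_A (1 − (b_A x_A + b_E x_E) / C) − x_A Σ_j l_j y_j
    dx_E/dt = x_A Σ_j l_j y_j − d_E x_E

with rates in h⁻¹ and capacities in CI units; the measured CI is Σ_i y_i
(suspended T cells are invisible to the electrodes).  Parameters are
estimated by a **macroevolutionary algorithm**: a population of parameter
vectors ranked by least squares, of which 25% survive each generation, 25%
are small multiplicative perturbations of the survivors
(β ∈ U(−0.02, 0.02)), and 50% are uniform redraws within wide bounds.
Fitting is two-staged: intrinsic growth parameters (r, d, a, K) from
effector-free wells first, then the interaction parameters
(h, l, b, r_A, d_E, C) from co-culture wells with the intrinsic set frozen.

The package provides:

* the ODE model with a deterministic adaptive RK4 integrator
  (nonnegativity-preserving, dense output) — `model_parameters()`,
  `simulate_growth()`, `simulate_coculture()`, `observable_ci()`;
* the assay metrics — `normalize_ci()`, `percent_cytolysis()`,
  `killing_time()`, `killing_time_table()`;
* the fitter — `fit_growth_stage()`, `fit_interaction_stage()`, `run_ma()`;
* a synthetic-data generator emulating the assay's timing, sampling, noise
  and spike artifact — `generate_killing_panel()`, `make_benchmark_suite()`;
* an end-to-end pipeline — `run_full_analysis()`.

See the vignette (`vignettes/modeling-impedance-killing-assays.Rmd`) for the
model assumptions, numerical choices and an identifiability discussion.

## Worked example

The package ships a small synthetic killing panel (30-minute sampling, 24 h
growth, effectors added at E:T = 0.5, 1, 2, 24 h follow-up) with its
generating truth alongside:

```r
library(rtcafit)

csv <- system.file("extdata", "synthetic_killing_panel.csv", package = "rtcafit")
panel <- read_series_csv(csv, t_treat = 24)
panel[[2]]
#> Cell-index series: 'effector' (E:T = 0.5), 97 samples, t in [0, 48] h, treated at 24 h

killing_time_table(panel, thresholds = c(20, 50, 80))
#>   et_ratio threshold_pct      kt_h detected
#> 1      0.5            20 0.5664441     TRUE
#> 2      0.5            50 1.2548449     TRUE
#> 3      0.5            80 2.1431985     TRUE
#> 4      1.0            20 0.5000000     TRUE
#> 5      1.0            50 0.7448953     TRUE
#> 6      1.0            80 1.3182525     TRUE
#> 7      2.0            20 0.5000000     TRUE
#> 8      2.0            50 0.5000000     TRUE
#> 9      2.0            80 0.8463369     TRUE
```

Killing is fast and dose-dependent: 80% cytolysis is reached in 2.1 h at the
lowest ratio and 0.85 h at the highest — a sensitive target.  KT values at
the first post-treatment sample (0.5 h) mean the threshold was already
crossed by then.  Fitting the two stages:

```r
ctrl <- Filter(function(s) s$et_ratio == 0, panel)
fit1 <- fit_growth_stage(ctrl, M = 1,
                         config = ma_config(N = 200, tau_max = 300,
                                            top_k = 50, seed = 1))
fit2 <- fit_interaction_stage(panel, fit1,
                              config = ma_config(N = 150, tau_max = 200,
                                                 top_k = 50, seed = 2))
fit2$best
#> Tumor/T-cell model parameters (M = 1 cancer subpopulations)
#>   r   = (42.08) 1/h
#>   d   = (41.49) 1/h
#>   a   = (0.8223)
#>   K   = 29.42 CI
#>   h   = (1.156) 1/h per CI-eq
#>   l   = ( 1.12) 1/h per CI
#>   b_A = 0.02433, b_E = 0.6905
#>   r_A = 1.529 1/h, d_E = 10.67 1/h, C = 48.64 CI-eq

top_k_summary(fit2)[1:2, ]
#>   name     median        q25       q75
#> 1  h_1 1.13800458 1.12747342 1.1472387
#> 2  l_1 1.17115842 1.15788258 1.1856356
```

A nonzero cytolysis rate `h` with a comparable exhaustion rate `l` is the
kinetic signature of effective killing that costs the effectors: active T
cells are consumed by the lysis they perform.  Note that only certain
parameter *combinations* are identifiable from a single growth curve — the
net growth rate `r − d` (here 0.59 h⁻¹) and the curvature `r·a/K` — while
`r`, `d` and `K` individually lie on a flat ridge; the vignette discusses
this, and the `top_k` spread shows which components the data actually pin
down.

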