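# il2cohort

Cohort-level modeling of antigen-driven IL-2 production, consumption and
signaling cross-talk in T cells.

## The problem

Single T cells activate in an all-or-none fashion, yet T-cell populations
report antigen dose in an analog way: the peak concentration of
interleukin-2 a culture accumulates, [IL-2]<sub>max</sub>, scales as a power
law of the antigen dose over more than three orders of magnitude while being
almost independent of the number of T cells present,

&nbsp;&nbsp;&nbsp;&nbsp;[IL-2]<sub>max</sub> ∝ N<sub>Tcell</sub><sup>a</sup> · N<sub>Antigen</sub><sup>b</sup>,  with a ≈ −0.1 and b ≈ +0.8.

The classical IL-2 circuit — TCR-triggered secretion, receptor upregulation,
pSTAT5-mediated shutdown — cannot produce this: it predicts accumulation
proportional to population size that saturates near the ~10 pM signaling
threshold. `il2cohort` implements a stiff ODE model of a cohort of T cells
sharing antigen and IL-2 pools, extended with the two regulatory elements
that generate the law:

* **TCR inhibition of STAT5 phosphorylation** — pSTAT5 per IL-2·IL-2R
  complex is damped by `1/(1 + σ·engagedTCR)`, so strongly engaged cells
  escape pSTAT5 shutdown and keep secreting (a coherent feed-forward loop
  tying production to antigen persistence);
* **an autocatalytic secretion "Boost"** — slow TCR seeding plus logistic
  self-activation of a per-cell store whose active fraction raises the
  secretion rate from 7.5 up to 232.5 molecules/s, rewarding sustained
  engagement.

The package provides the model with ablation variants (classical,
no-cross-talk, no-boost, JAK-blocked), condition sweeps with power-law
exponent fitting (least squares and PLS), two-clone mixed-culture
simulations, cell-to-cell variability analysis (CCVA: receptor-binned Hill
fits of pSTAT5 dose responses), SlopeXtalk antigenicity calibration, and
synthetic flow-like/ELISA-like data generators with known ground truth.
The methods vignette (`vignettes/il2cohort-methods.Rmd`) documents the
equations, parameter units, numerical choices and design decisions.

## Worked example

```r
library(il2cohort)

p <- il2_params()                          # published parameterization
tr <- run_cohort(p, N_Tcell = 1e4, N_Antigen = 1e8, seed = 1)
tr
#> IL-2 cohort trajectory: N_Tcell=10000, N_Antigen=1e+08, 50 cells, 301 points
#>   [IL-2]_max = 2.77e-11 M at tau_max = 39.5 h
```

10⁴ T cells given 10⁸ antigen molecules (≈ 25 nM peptide) peak at ~28 pM
after ~40 h — already above the 10 pM ceiling of the classical circuit —
then lose IL-2 to receptor-mediated consumption. Sweeping the default
condition grids and fitting the scaling law:

```r
sw <- sweep_conditions(p, n_seeds = 5, base_seed = 1)
fit_power_law(sw)
#> [IL-2]_max ~ N_Tcell^-0.071 (SE 0.043) x N_Antigen^+0.791 (SE 0.031)
#>   R^2 = 0.9190 over 60 points (ols)
```

The population-size exponent is small and negative (1,000 cells do slightly
*better* per condition than 100,000) and the antigen exponent is near
unity. Blocking pSTAT5 signaling *in silico* removes the brake on
secretion:

```r
jak <- run_cohort(set_variant(p, "jak"), 1e4, 1e8, seed = 1)
max(jak$il2_molar) / max(tr$il2_molar)
#> JAK-blocked peak: 2.45e-09 M (89-fold over control)
```

Other entry points: `run_two_clone()` (shared-IL-2 mixed cultures),
`secretion_acceleration()` / `producer_integral_curve()` (per-cell
acceleration diagnostics), `gen_flow_events()` + `ccva()` (receptor-binned
signaling analysis with ground-truth recovery), and
`gen_calibration_and_samples()` + `fit_slope_xtalk()` +
`build_calibration()` + `back_calculate_antigenicity()` (the antigenicity
calibration workflow).

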