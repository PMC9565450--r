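# sizecycle

Stochastic gene expression coupled to cell growth, division and size
control, in R.

Most models of stochastic gene expression track molecule *numbers* at
fixed cell volume. Cells, however, grow, replicate their genes, divide,
and often regulate the *concentration* of a gene product — a phenomenon
called concentration homeostasis. `sizecycle` is for quantitative /
systems biologists who want to model or analyse concentration
fluctuations along single-cell lineages (e.g. mother-machine fluorescence
time series): it implements a coupled model of bursty gene expression and
cell-size dynamics, solves its mean-field reduction analytically, and
ships the matching estimators for trajectory data.

## The model

A cell grows exponentially, `V(t) = V_b e^{g t}`, and progresses through
`N` effective cell cycle stages with volume-dependent transition rates
`(a V)^{alpha0}` before gene replication (stage `N0`) and `(a V)^{alpha1}`
after it — `alpha -> 0, 1, Inf` encode timer, adder, sizer size control,
and the two phases may use different strategies. The gene product is made
in bursts at frequency `rho` (`kappa * rho` after replication;
`kappa = 1` is perfect dosage compensation, `kappa = 2` none) with
geometric burst sizes of mean `B V^beta` (`beta = 1` is balanced
biosynthesis), and degrades at rate `d`. At division the volume halves
exactly and molecules partition binomially.

The package provides:

* an **exact event-driven simulator** (full model, mean-field reduced
  model, and a three-stage telegraph/translation variant), with the
  time-inhomogeneous stage hazards sampled by exact inverse transform
  (C++ under the hood);
* the **mean-field reduced model**: typical stage volumes `v_k`, a
  closed factorial-moment recursion
  `m_l = -(sum_{j<l} m_j W_jl) W_ll^{-1}`, per-stage concentration
  statistics, and gamma / negative-binomial **mixture distributions** for
  lineage and population measurements;
* **analytic autocorrelation and power spectra** of concentration
  fluctuations (exact Lorentzian sums via eigendecomposition), the
  off-zero peak height `H`, and the oscillation-onset prefactor
  `C(beta, kappa, w)`;
* **homeostasis metrics**: the decomposition `phi = phi_ext + phi_int`
  of the concentration CV², the accuracy `gamma = phi_ext/phi`, the
  optimal dosage compensation `kappa*(beta, w)`, Hellinger distance to
  the moment-matched gamma, and modality counting;
* **estimators for lineage time series**: Wiener–Khinchin spectra,
  50-piece cell-cycle binning, `gamma`/`phi` estimation, number-volume
  scatter statistics and size-control regression.

## Worked example

```r
library(sizecycle)

# N = 30 stages, replication at stage 12, non-balanced synthesis,
# no dosage compensation, unstable product (eta = d/f = 10);
# rho and a calibrated so <V> = 1 and <n> = 100.
m <- scc_model(g = log(2)/10, rho = 10, kappa = 2, B = 1, beta = 0,
               d = 1, N = 30, N0 = 12, mean_volume = 1, mean_number = 100)
summary(m)
#>   T = 10, f = 0.1, d_eff = 1.069, eta = 10, w = 0.4854
#>   effective size control alpha = 1 (Vd~Vb slope 1)
#> Concentration noise: <c> = 98.3368, phi = 0.04378
#>   phi_ext = 0.0196  phi_int = 0.02418  gamma = 0.4477
#>   Hellinger distance to gamma D = 0.04281
#>   spectral peak height H = 4.544
```

The summary says: the mean concentration is ~98 molecules per unit
volume; the total concentration noise (CV²) is 0.044, of which 45%
(`gamma = 0.45`) is attributable to cell-cycle position — homeostasis is
weak, and correspondingly the power spectrum has a pronounced peak at the
cell cycle frequency (`H = 4.5`) and the concentration distribution
deviates from its gamma approximation (`D = 0.043`).

Simulate a lineage of the *full* stochastic model and re-estimate from
the trajectory:

```r
tr <- simulate(m, seed = 1, t_max = 5000, model = "full")
size_control_fit(tr)$slope      # Vd ~ Vb regression: 1.128 (adder ~ 1)
estimate_gamma(tr)$phi          # 0.057 (full model adds volume noise)
optimal_kappa(beta = 0, w = 0.5)  # 1.4142: dosage compensation that
                                  # restores homeostasis at beta = 0
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/sizecycle.R homeostasis --config cfg.yaml --out out/
Rscript inst/cli/sizecycle.R simulate --config cfg.yaml --tmax 1e4 --seed 1
```

with flat YAML configs named after the `model_params()` arguments.

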