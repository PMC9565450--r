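---
title: "Concentration fluctuations in growing and dividing cells: models and methods"
author: "sizecycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration fluctuations in growing and dividing cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizecycle)
```

## The model

`sizecycle` studies how the *concentration* of a gene product fluctuates in
a single growing and dividing cell. Classical models of stochastic gene
expression track copy numbers at fixed volume; concentrations additionally
require a description of cell size, cell cycle progression, gene
replication and division. The model couples:

* **exponential volume growth**, $V(t) = V_b e^{gt}$ within a cycle;
* **a multi-stage cell cycle**: the cell traverses $N$ effective,
  memoryless stages; the exit rate from a stage is $(aV(t))^{\alpha_0}$
  before gene replication and $(aV(t))^{\alpha_1}$ after it. The power-law
  exponent encodes the size-control strategy: $\alpha \to 0$ is a timer
  (durations independent of size), $\alpha = 1$ an adder (added volume
  independent of birth size), $\alpha \to \infty$ a sizer. Stages are
  phenomenological, not biological phases; their number sets the
  cell-cycle duration variability ($\mathrm{CV}^2 \approx 1/N$);
* **bursty, volume-dependent synthesis**: bursts arrive at frequency
  $\rho$ (before replication) with geometric sizes of mean
  $B' = B\,V(t)^\beta$. $\beta = 1$ is balanced biosynthesis (synthesis
  scales with volume), $\beta = 0$ is non-balanced. The constitutive limit
  $\rho \to \infty$, $B \to 0$ at fixed $\rho B$ is included;
* **replication and dosage compensation**: when the cell leaves stage
  $N_0$ the gene is replicated instantaneously and the total burst
  frequency becomes $\kappa\rho$; $\kappa = 1$ is perfect compensation,
  $\kappa = 2$ none;
* **division** when the cell leaves stage $N$: the volume halves exactly
  and each molecule is kept with probability $1/2$ (binomial
  partitioning); one daughter is followed, giving lineage statistics;
* **first-order degradation** at rate $d$. The effective decay rate is
  $d_\mathrm{eff} = d + g$ (degradation plus dilution), and
  $\eta = d/f$ (with $f = g/\log 2$ the cycle frequency) measures
  product stability.

All eleven parameters are held in `model_params()`; units of time and
volume are the user's own and every formula is unit-consistent. Validation
rejects non-positive rates and warns for $\kappa \notin [1,2]$ and
$\beta \notin [0,1]$; $\alpha = 0$ exactly is rejected (the mean
generalized added volume $M_0 = N_0\alpha_0 g/a^{\alpha_0}$ degenerates) —
a timer is represented by a small value such as $0.01$.

## Exact simulation

Between events all hazards are constant except the stage-transition hazard
$(aV(t))^\alpha$, which grows deterministically with volume. Its waiting
time is sampled by exact inverse transform,
$$\tau = \frac{1}{\alpha g}\log\!\Big(1 + \frac{\alpha g E}{(aV_0)^\alpha}\Big),
\qquad E \sim \mathrm{Exp}(1),$$
so the *generalized added volume* per stage,
$V_0^\alpha(e^{\alpha g\tau} - 1)$, is exponential with mean
$\alpha g/a^{\alpha}$; summed over a phase it is Erlang. No thinning or
time discretization is used anywhere; the chemistry (bursts, degradation)
is raced against the pre-sampled stage time, which is exact because the
stage hazard does not depend on the chemical state. These distributional
consequences — Erlang laws for $\Delta_0 = V_r^{\alpha_0} - V_b^{\alpha_0}$
and $\Delta_1 = V_d^{\alpha_1} - V_r^{\alpha_1}$, their independence from
the birth volume, and the birth-division regression slope $2^{1-\alpha}$
with $\alpha = w\alpha_0 + (1-w)\alpha_1$ — are the simulator's test
invariants.

A three-stage variant (`simulate_three_stage()`) adds gene on/off
switching, transcription at rate $sV^\beta$ per active copy, translation
and mRNA decay. In the fast-switching regimes ($r \gg \rho$ for mRNA,
$v \gg d$ for protein) it collapses to the bursty model; the tests verify
this by comparing stationary distributions. At division the followed
daughter inherits one of the two gene copies uniformly at random — the
model itself does not prescribe gene-state inheritance, and this choice
affects only a vanishing fraction of time for fast switching.

## The mean-field reduced model

The full model is analytically intractable because gene expression is
coupled to both stage-duration noise and stage-volume noise. The reduced
model keeps the former and replaces the volume at stage $k$ by its typical
value
$$v_k = \big[v_1^{\alpha_0} + (k-1)M_0/N_0\big]^{1/\alpha_0}
  \;(k \le N_0), \qquad
v_k = \big[(v_1^{\alpha_0}+M_0)^{\alpha_1/\alpha_0} +
  (k-N_0-1)M_1/N_1\big]^{1/\alpha_1}\;(k > N_0),$$
with the typical birth volume $V_b$ solving
$(V_b^{\alpha_0}+M_0)^{\alpha_1/\alpha_0} + M_1 = (2V_b)^{\alpha_1}$
(closed form when $\alpha_0 = \alpha_1$; a bracketed `uniroot()` at
relative tolerance $10^{-12}$ otherwise — the left-hand side crosses zero
once). Stage-exit rates become constants $q_k = (av_k)^{\alpha}$, burst
sizes $B_k = Bv_k^\beta$, burst frequencies $\rho_k \in \{\rho,
\kappa\rho\}$, and the replication fraction is
$w = \log_2(v_{N_0+1}/v_1)$ — distinct from $N_0/N$ because early (small)
stages last longer. The model has an exact scale symmetry: rescaling $a$
rescales every $v_k$ by $1/a$ and leaves every $q_k$ unchanged, which is
why `calibrate()` can hit a target mean volume in a single exact rescale
and then match a target mean copy number by the (exactly linear) rescale
of $\rho$.

`tune_replication_fraction()` inverts $w$ as a function of $N_0$ and a
common $\alpha$: for equal strengths
$w(\alpha) = \log_2(1 + (N_0/N)(2^\alpha-1))/\alpha$ increases
monotonically from $N_0/N$ to 1, so choosing
$N_0 = \lfloor N(2^w-1)\rfloor$ and solving for $\alpha$ places
replication at any desired cycle fraction exactly. This is how the
replication-timing scans are parameterized.

## Moments, distributions, spectra

For the reduced model the unnormalized factorial moments
$m_{lk} = \sum_n n(n-1)\cdots(n-l+1)\,p_{k,n}$ satisfy a closed recursion:
$m_0$ is the stage occupancy $m_{0k} \propto 1/q_k$, and
$m_l = -\big(\sum_{j<l} m_j W_{jl}\big)W_{ll}^{-1}$, where $W_{ll}$ has
diagonal $-q_k - ld$, superdiagonal $q_k$ and corner $q_N/2^l$ (binomial
partitioning), and $W_{jl} = (l!/j!)\,S\,T^{l-j}$ with
$S = \mathrm{diag}(\rho_k)$, $T = \mathrm{diag}(B_k)$. Each step is one
dense linear solve ($N$ is at most a few hundred); the corner factor makes
$W_{ll}$ nonsingular even at $d = 0$. The recursion is exact for the
reduced model — the test suite confirms it against a direct stationary
solve of the truncated master equation for small systems to better than
0.5%.

Per-stage concentration statistics are $\mu_k = m_{1k}/(m_{0k}v_k)$ and
$\sigma_k^2 = (m_{1k}+m_{2k})/(m_{0k}v_k^2) - \mu_k^2$. The stationary
lineage distributions are approximated by mixtures: a gamma per stage for
concentration (shape $\mu_k^2/\sigma_k^2$, rate $\mu_k/\sigma_k^2$,
weights $m_{0k}$) and a negative binomial per stage for copy number; the
approximation is excellent for $N \gtrsim 15$ and exact per stage in the
quasi-steady-state limit. Components at the Poisson boundary
($\bar\sigma_k^2 \le \bar\mu_k$) are replaced by the Poisson limit;
genuinely underdispersed components are an error, because the bursty model
cannot produce them. A gamma component with vanishing variance is replaced
by a very narrow gamma (CV $10^{-6}$) rather than a point mass so that
density grids and Hellinger integrals stay defined. Density grids cover
$[0, \mu + 10\sigma]$ with 2048 points; count grids run to the
$1-10^{-10}$ quantile.

For population snapshots the weights become $\pi_k \propto
(q_{k+1}+J)\cdots(q_N+J)/(q_k \cdots q_{N-1})$, with the population growth
exponent $J$ the unique positive root of $\prod_k (q_k+J) = 2\prod_k q_k$
(solved in log space; young stages are overrepresented).

The concentration autocorrelation has the closed form
$$R(t) = (m_1+m_2)V^{-1}e^{W_{11}t}V^{-1}\mathbf{1} -
  (m_1V^{-1}\mathbf{1})^2 + \int_0^t m_1V^{-1}e^{W_{00}s}\,S\,T\,
  e^{W_{11}(t-s)}V^{-1}\mathbf{1}\,ds,$$
which the package evaluates by eigendecomposition of $W_{00}$ and
$W_{11}$: every term becomes $e^{\lambda t}$, $e^{\nu t}$ or — for
eigenvalue pairs closer than $10^{-9}$ in relative terms — the confluent
limit $te^{\lambda t}$. The stationary zero mode of $W_{00}$ contributes a
constant that cancels the squared mean analytically; the implementation
folds both into one constant and verifies it is numerically negligible.
The power spectrum $G(\xi) = \int R(|t|)e^{-2\pi i\xi t}dt$ is then an
exact weighted sum of Lorentzians, normalized to $G(0) = 1$, evaluated on
2048 frequencies over $[0, 4f]$ by default. The off-zero peak height $H$
is the excess of $G$ above 1 in the fundamental band $[0.3f, 1.7f]$
(floored at zero; the band isolates the fundamental from the first
harmonic, which is reported separately) — it measures the regularity of
division-induced concentration oscillations.

## Homeostasis metrics

The total concentration noise $\phi = \sigma^2/\langle c\rangle^2$
decomposes exactly into an extrinsic (cell-cycle) part — the occupancy-
weighted CV$^2$ of the stage means $\mu_k$ — and an intrinsic part (the
weighted mean of $\sigma_k^2$ over $\langle c\rangle^2$). The accuracy of
homeostasis is $\gamma = \phi_\mathrm{ext}/\phi \in [0,1]$: zero when the
mean concentration is flat across the cycle.

Three analytic results organize the phenomenology, and all three are
exercised by the tests:

* the oscillation prefactor
  $C(\beta,\kappa,w) = |1 - \kappa 2^{\beta-1} +
  (\kappa-1)2^{(\beta-1)w}e^{2\pi wi}|^2$, which must vanish for the
  spectrum to lack an off-zero peak. $C = 0$ at $\beta = \kappa = 1$
  (perfect homeostasis), or at $\kappa = 2^{(1-\beta)/2}$, $w = 1/2$
  (quasi-perfect homeostasis; for $\beta = 0$ this is
  $\kappa = \sqrt 2 \approx 1.41$);
* the balance condition $\kappa^*(\beta,w) = (1-w)(2^{(\beta-1)w}-1)\,/\,
  [w(2^{\beta-1}-2^{(\beta-1)w})]$ obtained by equating the time-averaged
  mean concentration before and after replication (limit
  $\kappa^* \to 1$ as $\beta \to 1$), which reduces to $2^{(1-\beta)/2}$
  at $w = 1/2$ and agrees with the minimizer of $\gamma$ from the moment
  pipeline;
* the peak height scales as $H \propto N^2\,C(\beta,\kappa,w)$. This is
  an asymptotic statement in the low-intrinsic-noise (large copy number)
  limit; the package verifies the $N^2$ slope at mean copy number
  $10^4$, where the log-log slope over $N \in \{20,40,80\}$ is 2.0,
  while at small copy numbers intrinsic noise flattens the scaling.

Deviations from perfect homeostasis also show up as deviations of the
concentration distribution from a gamma law. `gamma_approximation()`
moment-matches a gamma to $(\langle c\rangle, \sigma^2)$ — moment matching
is the only fitting rule consistent with the perfect-homeostasis closed
form $\mu_k = \rho B/d_\mathrm{eff}$, $\sigma_k^2 = \rho
B^2/d_\mathrm{eff}$ — and the Hellinger distance $D$ quantifies the gap.
Note the closed-form variance is a continuum (large-burst) limit: at
finite burst size the discrete model carries an extra Poissonian term of
relative size $1/B_k$, which the tests account for by checking the law at
large $B$.

Mode counting smooths the density with a moving-average window of about 1%
of the grid (suppressing quadrature ripple; the false-positive rate on
single gammas is tested) and counts strict local maxima, plateaus once.
Across parameter sweeps the concentration distribution never has more
modes than the copy-number distribution.

## Estimators for lineage data

`lineage_analysis` functions work on any uniformly sampled series with
division times, simulated or measured:

* `empirical_spectrum()` averages mean-subtracted truncated-Fourier
  periodograms over consecutive segments of 20 cell cycles (a
  bias/variance compromise) and normalizes by the mean of the 3 lowest
  positive-frequency ordinates — the empirical analogue of $G(0) = 1$,
  since the raw zero ordinate is removed with the mean;
* `bin_by_cycle()` assigns each sample its within-cycle fraction
  $(t - t_b)/(t_d - t_b)$ and pools 50 equal-width bins across cycles;
  `estimate_gamma()` takes $\hat\phi$ as the CV$^2$ of all samples,
  $\hat\phi_\mathrm{ext}$ as the CV$^2$ of the bin means. Because binning
  is by time fraction rather than by hidden stage, the estimator slightly
  blurs sharp stage profiles (e.g. the replication jump at $\beta = 0$ and
  small $N$) and then underestimates $\phi_\mathrm{ext}$; in the
  weak-homeostasis regimes it matches the analytic $\gamma$ to within a
  few percent, which is what the tests assert;
* `number_volume_scatter()` uses 8 equal-occupancy volume bins (equal
  width would leave outer bins nearly empty) plus an ordinary
  least-squares line with $R^2$;
* `size_control_fit()` regresses division on birth volume
  ($\hat\alpha = 1 - \log_2(\mathrm{slope})$) and fits the per-phase
  slopes $2^{w(1-\alpha_0)}$ and $2^{(1-w)(1-\alpha_1)}$;
* `fit_gamma_and_distance()` moment-matches a gamma to a concentration
  sample and reports the histogram-based Hellinger distance.

External data are read as delimited text with columns `time`,
`volume`/size, and signal, plus division times; no instrument format is
parsed.

## Study conditions and what the simulations do (not) show

`fixtures()` collects the named parameter sets used throughout: the
model-comparison family ($f = 0.1$, $\eta = 10$, $\beta = 0$,
$\kappa = 2$, $N_0 = 0.4N$, calibrated to $\langle V\rangle = 1$,
$\langle n\rangle = 100$; adder, sizer-timer and timer-sizer variants),
perfect/quasi-perfect/weak homeostasis regimes, the size-control study set
($N = 50$, $N_0 = 21$, $\rho = 4.7$, $\kappa = 2$, $d = 0.4$, $\eta = 4$)
and a near-timer set. Where a regime is described only qualitatively in
the literature the fixture notes say "regime-matched, not value-matched".

Problem sizes: simulation-based tests use lineages of $10^4$–$10^5$ time
units ($10^3$–$10^4$ cell cycles) sampled every 0.1–0.2 time units, enough
to pin distributional distances to ±0.005–0.01 and regression slopes to
±0.02; the replication-timing landscape uses a $11\times 17$
$(\kappa, w)$ grid at $N = 100$; the master-equation oracle uses $N \le 5$
and copy numbers capped at the $1-10^{-10}$ quantile.

Two deliberate emphases deserve note. First, the mean-field model drops
stage-volume fluctuations, whose CV decays like $N^{-1/2}$ (about 10% at
$N = 30$ for the adder, and more slowly for strongly mixed two-layer
strategies). Copy-number distributions of the full and reduced models
agree very closely already at $N = 15$; concentration distributions retain
a variance gap of order $\mathrm{CV}_V^2$, so their Hellinger distance
decreases with $N$ but remains of order 0.04–0.1 in the $N = 15$–$30$
range at these study conditions. Second, the synthetic trajectories
emulate idealized measurements: no measurement noise, no segmentation
error, perfectly symmetric division, constant growth rate, a single
non-interacting gene, and no mitotic transcriptional silencing — passing
tests demonstrate internal consistency of the theory and estimators, not
that real data satisfy the model.

## Known limitations

Multiple or overlapping replication rounds (bacteria at fast growth),
growth-rate fluctuations, volume-dependent degradation, asymmetric
division and parameter inference from data are out of scope. The
gamma/negative-binomial mixtures are approximations whose error is not
bounded analytically; they are validated numerically against simulation
and against exact small-system solves.
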