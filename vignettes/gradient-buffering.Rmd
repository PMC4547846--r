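---
title: "Methods: modelling and measuring a buffered cortical kinase gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and measuring a buffered cortical kinase gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomgrad)
```

This vignette is the package's account of its science and of the numerical
and design choices behind it: the models, the estimators, every tunable
parameter with its default and rationale, what the synthetic data generator
does and does not emulate, and the package's known limitations.

## 1. The models

All concentrations are in arbitrary fluorescence intensity units (GFP
signal is linear in protein concentration, so intensity is a valid linear
proxy and no molar units are ever attached); lengths in µm, time in
minutes. The cortex is a 1D arclength coordinate `x ≥ 0` from the pole tip.

**Trans-phosphorylation model.** If the kinase phosphorylates other
membrane-bound molecules of its own species, the per-molecule detachment
rate is proportional to the local concentration, giving a quadratic decay
term:

$$\partial_t P = D\,\partial_x^2 P - \alpha P^2 + S(x).$$

With a point influx $S$ at the pole (flux condition $-D P'(0) = S$) the
steady state on the half-line is

$$P(x) = \frac{C}{(x+x_0)^2},\qquad C=\frac{6D}{\alpha},\qquad
x_0=\Big(\frac{12 D^2}{\alpha S}\Big)^{1/3},$$

derived by substituting the power-law ansatz into $DP'' = \alpha P^2$
(which fixes $C$) and balancing the boundary flux (which fixes $x_0$).
Every closed form in the package is gated behind a test against the
independent numerical solver before being relied on. Consequences, all
exposed as functions and all tested:

* amplitude $A = C/x_0^2 \propto S^{2/3}$ (`steady_state_summary`);
* decay length at threshold fraction $f$:
  $\lambda = x_0(f^{-1/2}-1) \propto A^{-1/2}$ at fixed $C$
  (`decay_length_from_x0`);
* cortical total $P_{tot} = C/x_0 = \sqrt{C A}$;
* a concentration-threshold position shifts by
  $\Delta x = x_0(1-k^{-1/3}) < x_0$ under a $k$-fold source change
  (`threshold_shift`), i.e. positional information is buffered against
  arbitrarily large input fluctuations.

**Cis model** (`cis_steady_state`): linear decay $-\alpha P$, exponential
steady state with $\lambda=\sqrt{D/\alpha}$ independent of $S$ and
$A \propto S$. This is the unbuffered reference.

**Cluster model**: the alternative buffering hypothesis in which high
local concentration forms slow-diffusing clusters. We implement the
simplest decreasing diffusion law with a Hill form,
$D(P) = D_0/(1+(P/P^*)^h)$, default $h = 2$, in flux form
$\partial_x(D(P)\partial_x P)$ with linear decay. The functional form of
the concentration dependence is a modelling choice; accordingly the
package only ever asserts the *sign* of this model's ratio-slope
prediction, never magnitudes. The **combined model** couples the cluster
diffusion law with the quadratic trans decay.

**Detailed N-state model** (`rhs_detailed`, `solve_to_steady_state`): the
kinase has multiple phospho-sites, at least 6 of which control membrane
affinity, so the biological default is N = 6 states beyond the
unphosphorylated one. State populations $P_i$ obey

$$\partial_t P_0 = D\partial_x^2 P_0 + S(x) - \beta P P_0 - \kappa_0 P_0,$$
$$\partial_t P_i = D\partial_x^2 P_i + \beta P (P_{i-1} - P_i) - \kappa_i P_i,$$
$$\partial_t P_N = D\partial_x^2 P_N + \beta P P_{N-1} - \kappa_N P_N,$$

with $P=\sum_i P_i$. Phosphorylation only moves mass between states, so
the summed rates equal $D\partial_x^2P + S - \sum\kappa_iP_i$ exactly (a
tested identity). Two choices were genuinely open and are documented
here: the top state has no further phosphorylation loss (molecules at
maximal phosphorylation can only detach), and $\kappa_0 = 0$ by default
(fully dephosphorylated kinase does not detach) — both configurable via
`kappa`. The detachment-rate profile is likewise open; the default is
linear, $\kappa_i = i\kappa$, the weakest profile under which the
coarse-grained approximation holds, with a superlinear option in
`run_gamma_study`.

**Effective exponent γ.** Summing the N-state equations coarse-grains the
decay into $\alpha_\gamma P^\gamma$. `fit_effective_gamma` measures γ as
the slope of $\log_{10}$ detachment-flux density
$d(x)=\sum\kappa_iP_i(x)$ against $\log_{10} P(x)$ over nodes where
$P > 1\%$ of the amplitude. Two exact controls calibrate the estimator:
constant κ gives $d=\kappa P$, hence γ = 1, and substituting the
simplified trans model ($d=\alpha P^2$) gives γ = 2. In the strong
trans-phosphorylation regime (we calibrate β so that $\beta A
\approx 5\kappa$ at the pole, via `calibrate_beta`) the fitted γ lies in
(1.5, 2]: the far field is phosphorylation-limited (locally γ → 2), the
pole region is saturated by ladder climbing (locally γ ≈ 1.5), and the
single-exponent fit lands between, at γ ≈ 1.69 with R² ≈ 0.97 for the
default configuration. One numerical caveat matters: the regression's own
1% amplitude cutoff must lie *inside* the domain. On a short domain the
profile never reaches the cutoff, the steep tail is under-represented and
γ is biased down (to ≈ 1.37 at L = 7 µm). All γ analyses therefore use
L = 16 µm, where the cutoff is reached and the estimate is
domain-independent.

## 2. Numerics

`solve_to_steady_state` integrates any model variant on a uniform grid
(zero-flux boundaries at both ends) until the maximum nodal rate of
change, relative to the profile maximum, falls below `rel_tol` (default
10⁻⁶ min⁻¹). Two schemes:

* **explicit** Euler, with dt bounded by the diffusion stability limit —
  simple, used as a cross-check (both schemes must agree, a tested
  invariant);
* **semi-implicit** (default): diffusion and the *linearized* decay term
  are implicit (tridiagonal Thomas solve, coefficients lagged one step),
  gains and source explicit. The fixed point of this iteration satisfies
  the exact discrete steady-state equations, so dt affects only the
  convergence path, never the answer; this makes amplitudes of 10⁴ (the
  k = 10⁶ threshold-shift check) tractable. On blow-up the wrapper halves
  dt and restarts before raising a stability error.

**Source representation.** Closed forms assume a point influx; the solver
uses a half-Gaussian band of width `source_width` (default 0.3 µm,
mimicking the Tea4 cap), normalized so its integral is S. The band is a
regularization: a band of width $w$ loses less mass near the pole than a
point source and shifts the outer power law by $O(w/x_0)$. Narrowing the
band converges to the closed form (a tested, monotone invariant). Two
practical rules follow, both applied internally:

* in source-strength sweeps (`model_sweep`) the band is scaled with the
  gradient, $w = x_0(S)/10$, so the perturbation is the same at every
  sweep point and cannot tilt fitted exponents;
* pole quantities of a band-source solution are read off by matching the
  outer power-law form (`fit_power_profile`: least squares on log P,
  profiled over $x_0$), not from the flattened pole values; the
  half-line cortical total adds the analytic tail closure $C/(L+x_0)$
  beyond the domain.

**Domain truncation.** The power-law gradient has a fat tail, so a
zero-flux far boundary at L = 7 µm (half a cell length) reflects a small
percentage of the influx. The along-curve quantities (λ vs A, A vs
P_tot) are immune — a perturbation of $x_0$ moves points along the
predicted curve — and the oracle-equivalence tests use domains of
40 x₀ with the comparison window ending at L/2, where agreement with the
half-line closed form is better than 1%.

## 3. The synthetic population generator

`sample_population` emulates the *output* of cortical-profile
quantification from two-colour microscopy — not the micrographs. Defaults
(`population_spec`) encode the study conditions:

* 97 cells × 4 pole profiles = 388 profiles, sampled every 0.1 µm over
  0–4 µm (pole to mid-cell);
* per-pole Tea4 source strengths: log-normal with `tea4_log_sd = 0.35`
  (several-fold spread across the population), times a within-cell factor
  drawn uniform-in-log from [1/2, 1] for secondary poles — together
  producing the observed two- to four-fold within-cell amplitude
  differences;
* generative model for Pom1 given S: trans model with D = 1 µm²/min and
  α = 0.6 (C = 10), median S = 1.3, chosen so the median half-maximum
  decay length is ≈ 1 µm — the scale observed for this gradient — with
  amplitudes of order unity in intensity units;
* measurement noise: multiplicative log-normal per sampled position with
  CV 0.1 (fluorescence shot/speckle noise is scale-dependent), plus a
  constant additive background of 0.1 on both channels. No spatial
  autocorrelation of the noise is modelled in this version;
* per-cell cytoplasmic Pom1 metadata: log-normal with σ(ln) = 0.18,
  giving the observed "slightly above twofold" range across a ~100-cell
  population (metadata only — the model's S is independent of the
  cytosolic pool, since pole amplitude and cytoplasmic concentration are
  uncorrelated in the data the model describes).

The Tea4 channel is the half-Gaussian cap of width `source_width` with
amplitude proportional to the drawn S (proportionality constant 1), and
carries the same noise and background. For trans and cis generative models the
noiseless Pom1 profile is the closed form; other kinds go through the
numerical solver.

What passing tests on these data do **not** show about real data: the
generator draws independent log-normal sources with no cell-cycle
structure, no correlated pole-to-pole geometry, no bleaching or focus
gradients, and its noise is position-independent in CV. Recovery of the
generative exponents under this noise model validates the estimator
pipeline, not the microscopy.

## 4. The measurement pipeline

`analyze_population` mirrors a standard profile-quantification chain.
Defaults and their reasons:

* **Smoothing**: centred moving average, window 0.3 µm with edge
  truncation. Exponent estimates move by < 0.05 across windows
  0.1–0.5 µm (sensitivity-checked); a constant profile, a linear ramp and
  the profile integral are preserved.
* **Background**: constant override when known (synthetic tables carry
  the generator's constant in their metadata and the analysis uses it
  automatically); otherwise the per-cell minimum of the smoothed profile.
  On 4-µm windows the per-cell minimum still contains the profile's own
  tail, which biases decay lengths — a known limitation of short imaging
  windows rather than of the estimator.
* **Amplitude**: mean of the smoothed, background-subtracted profile over
  the first 0.3 µm.
* **Decay length**: first linearly-interpolated crossing of
  `fraction × amplitude` (default fraction 0.5; the threshold fraction is
  a convention — all scaling exponents are fraction-independent, so
  half-maximum is chosen for robustness to noise). Profiles that never
  cross within range are *censored*: excluded from regressions, counted
  and reported, because extrapolating beyond the data would bias λ.
* **Batching**: poles sorted by Tea4 amplitude, split into contiguous 5%
  batches (388 poles → 20 batches of 19–20, larger batches first);
  per-batch means and SEMs.
* **Regression**: weighted least squares of log₁₀ y on log₁₀ x with
  inverse-variance-of-the-mean weights,
  var(log₁₀ y) ≈ (sem/(y ln 10))²; equal weights with a warning when SEMs
  are missing (singleton batches). Regressions are run on batch means —
  each point is one averaged profile — with per-pole regression available
  as an option (`per_pole = TRUE`).

The slopes these estimators recover from power-law profiles on a finite
4-µm window are mildly attenuated: the 0.3-µm amplitude band averages
over a region where the profile has already fallen, compressing the
dynamic range of log A. With the default generative regime (x₀ ≈ 2.5 µm)
the attenuation is a few percent of the slope — seed-averaged recoveries
are ≈ −0.45 for the λ–A exponent and ≈ 0.63 for the Pom1–Tea4 exponent,
against model values −1/2 and 2/3 — and the two buffering signatures
remain unambiguous. Narrower bands reduce the bias at the cost of noise.

The auxiliary statistics follow the same conventions: `cv_vs_distance`
(SD/mean across poles per position, non-increasing over the first 2 µm
for trans-generated populations — profiles converge toward the
S-independent far field), `compare_exponential_powerlaw` (individual
profiles constrain functional form weakly; the test asserts only that the
RMS ratio stays within [1/2, 2] on noisy trans profiles, which is why
model discrimination uses population-level scaling), and
`bartlett_compare` on log amplitudes (variance on the log scale is
relative variability; trans-generated populations show CV(Tea4) >
CV(Pom1) because the 2/3 power compresses the output distribution).

## 5. Problem sizes used by the test suite

Chosen so every numerical claim is tested at a resolution where the
discretization error is far below the asserted tolerance: prediction
sweeps use 15 source strengths over two decades on L = 7 µm, dx = 0.01 µm;
oracle-equivalence comparisons use L = 40 x₀ with dx = x₀/120 and
rel_tol = 10⁻⁹; γ analyses use L = 16 µm (see §1); population recoveries
average 10 seeds of 388 profiles. The full suite runs in about a minute.

## 6. Known limitations

* 1D mean-field only: no 2D/3D cell geometry, no stochastic
  single-molecule dynamics, no cytoplasmic compartment ODE.
* The cluster diffusion law is a minimal stand-in; only sign-level
  predictions are made with it.
* The effective-exponent γ is a regression summary of a genuinely
  non-power-law detachment field; its value depends (weakly) on the fit
  range convention, which is why the convention (nodes above 1% of
  amplitude, domain long enough to contain them) is fixed and tested.
* Short imaging windows bias cortical totals low relative to the
  half-line model quantity; the model-level A–P_tot scaling is therefore
  asserted on sweeps, not on 4-µm synthetic profiles.
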