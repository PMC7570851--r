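---
title: "Models and methods behind ionsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ionsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ionsense couples a physics-based simulator of an ion-selective electrode
(ISE) array with the chemometric pipeline that turns its readings into
eight simultaneous ion concentration estimates. This vignette explains the
models, the default parameter choices and their rationale, the numerical
decisions, and what the synthetic benchmark does and does not demonstrate.

## 1. The electrode forward model

Each of the six ISEs follows the Nikolsky–Eisenman equation on the
concentration scale (mg/L, natural log):

$$E_j = b_j + s_j \frac{T + 273.15}{298.15}
  \ln\!\Big(\max\big(c_j + \textstyle\sum_i K_{ji}\, c_i^{z_j/z_i},\; c_{0,j}\big)\Big)
  + d_j + \varepsilon_j$$

* $s_j$, $b_j$ — slope (mV per ln-decade at 25 °C) and intercept. Defaults
  are published working-curve coefficients of commercial electrodes of each
  type (nitrate −22.86/208.47, ammonium 22.92/−253.87, potassium
  23.07/−237.03, calcium 11.06/−76.90, sodium 19.76/−186.22, chloride
  −23.02/192.33). Anion electrodes have negative slopes by convention.
* The factor $(T+273.15)/298.15$ is the Nernstian proportionality of the
  slope to absolute temperature; it can be disabled per electrode.
* $K_{ji}$ — dimensionless selectivity coefficients. Interference enters
  with the charge-ratio exponent $z_j/z_i$; a zero-concentration interferent
  contributes nothing even when that exponent is negative (the limit is
  taken as 0 rather than a singularity). Cross-charge terms with
  $|z_j/z_i| \ne 1$ are kept out of the defaults because mg/L-scale powers
  of large concentrations are physically meaningless; the divalent-on-
  monovalent exponent 1/2 is the one fractional case used.
* $c_{0,j}$ — detection floor (1 mg/L): the log argument is clamped, which
  makes the rinsed-water baseline sit at the bottom of the linear range.
* $d_j$ — session drift; $\varepsilon_j$ — Gaussian measurement noise.

Concentrations, not thermodynamic activities, enter the log term — this is
the fitted form practitioners actually obtain from mixture calibrations.
An ionic-strength correction is deliberately absent from the default model
(see Limitations).

**Default selectivity structure.** Cross terms among the six electrode ions
are small, order $5\times10^{-3}$–$10^{-2}$, reflecting decent modern
membranes. Two ions — dihydrogen phosphate and magnesium — have no
electrode of their own, and the array is configured so they remain
inferable by fusion: the anion electrodes carry a weak phosphate response
(0.05), the pH channel responds strongly to phosphate acidification, the
monovalent cation electrodes carry weak magnesium terms (0.05 with exponent
1/2), and the calcium electrode behaves like a divalent hardness sensor
with $K_{\mathrm{Ca,Mg}} = 0.3$. The EC channel couples to everything. All
values are config-overridable (`default_array_config()`, YAML round-trip
via `write_array_config()`).

The choice $K_{\mathrm{Ca,Mg}} = 0.3$ balances two requirements that pull
in opposite directions: a larger coefficient injects more magnesium signal
into the array but contaminates calcium (at 0.5 the cross-validated calcium
R² drops below 0.9, at 0.7 below 0.8), while a smaller one starves
magnesium of information. Section 7 quantifies what is and is not
recoverable at this setting.

**pH and EC transducers.** The physical array measures pH and EC, but a
response model must be supplied here: EC ($\mu$S) is the sum of
$\Lambda_i c_i / M_i$ with equivalent conductances $\Lambda_i$ (S cm²/mol)
and molar masses $M_i$; pH is $6.5 - 0.8\ln(1 + c_{\mathrm{H_2PO_4}}/50)$,
i.e. phosphate acidifies the matrix. Noise defaults: 0.3 mV per ISE
(stabilized benchtop reading), 20 µS, 0.02 pH.

## 2. Drift and the two measurement protocols

Drift is one Gaussian offset per channel per measurement cycle
(`drift_sd`, default 3 mV, scaled into pH/EC units by 0.017 pH/mV and
10 µS/mV), constant within the cycle. This encodes the assumption that
matters for standard addition: drift varies *between* cycles but not within
the 1–5 minutes of one baseline/sample pair.

* `measure_msam()` draws the offset once and applies it to both the
  baseline phase `U0` and the sample phase `Ux`, so it cancels in
  `Ux − U0` (exactly, up to floating-point rounding of the two sums —
  about $10^{-13}$ of the stored values).
* `measure_dcm()` is the single-phase direct immersion; the offset stays in
  the reading. `measure_dcm_series()` models a long direct-calibration
  session in which the offset performs a random walk between consecutive
  immersions. The protocol contrast — per-cycle re-referencing versus
  accumulating drift — is what makes the standard-addition calibrations
  fit better than direct ones on simulated series; the time structure itself
  is this package's modeling choice, since real drift is rarely
  characterized beyond its slow, cumulative nature.

The rinsed-water baseline holds every panel ion at 1 mg/L (the detection
floor) and is measured at the sample temperature.

## 3. The mixture design

`factorial_design()` uses a modular (Graeco-Latin-style) construction: for
$L^2$ runs indexed by $(i,k)$, factor $f$ receives level
$\alpha_f i + \beta_f k \bmod L$. Coefficient pairs are fixed per $L$ so
that every pairwise determinant is a unit mod $L$ wherever possible; exact
pairwise orthogonality for all 15 factor pairs is mathematically impossible
at $L = 6$ and $L = 10$ (no complete sets of mutually orthogonal Latin
squares exist at those orders), so a few pairs are only near-uniform. The
package therefore guarantees *exact per-factor balance* (each level appears
$n/L$ times, tested exhaustively) and *near-uniform two-factor projections*
(every pairwise chi-square below $2.5L^2$; the worst deterministic values
are 72 at $L=6$, 64 at $L=8$, 100 at $L=10$, 0 at $L=3$). The 27-run case
uses the classic three-index fraction $i, j, k, i{+}j, i{+}k, j{+}k$
(mod 3), which is fully pairwise-uniform; it spans all six designed ions,
resolving the level/factor ambiguity in favour of six factors.

When fewer than 10 levels are requested, the concentrations are an evenly
spread subset of the 10-level table (`round(seq(1, 10, length.out = L))`).
Phosphate (6–678 mg/L), magnesium (6–125 mg/L) and temperature (15–35 °C)
are drawn uniformly per sample — linear-scale uniform by default, with a
log-uniform flag — because the design treats them as background factors to
be randomized, not controlled.

## 4. Features and scaling

`enrich()` maps a record to 17 ordered features: the 8 sample-phase
channels, the 8 differences `Ux − U0`, then temperature. The raw block is
kept alongside the differences because both carry information — the
difference block is drift-invariant (tested both ways: the raw block must
*not* be invariant), while the raw block anchors the absolute response.
The sample phase (not the baseline phase) is used as the raw block since it
carries the concentration signal.

Min-max scaling to $[-1, 1]$ is fitted on training folds only; constant
features map to 0 (avoiding 0/0), and out-of-range test values extrapolate
without clipping. `select_pc_count()` chooses the smallest principal-
component count of the scaled training features reaching 98 % explained
variance; on default data this is 8, and it sets the width of the feature
layer handed to the GP heads.

## 5. The three regressors

All three back ends implement one contract: scaled features in, eight mg/L
predictions out. Targets are fitted on the natural mg/L scale by default
(matching how the comparison reports slopes and intercepts); a log-scale
option exists for single-electrode-style use. Internally the GP and DKL
heads standardize each ion (a zero-mean target matches the zero-mean GP
prior); the network model min-max-scales targets to $[0,1]$ so its ReLU
output layer is feasible.

**Network (`ann`).** Full-batch backpropagation with Adam (default) or SGD,
mean-squared-error loss, Glorot initialization, inverted dropout applied
only in training mode, and best-epoch selection on a 10 % validation split.
Dropout intensities are parameterized as *keep*-probabilities throughout
(a "rate" of 0.99 keeps 99 % of units — the reading under which wide
layers remain functional; dropping 99 % would destroy them).
Gradients are hand-derived and verified against central finite differences
at $10^{-5}$ relative tolerance. Scaled-down default: 64–32 tanh hidden
layers, ReLU output, 400 epochs at rate 0.01.

**Gaussian process (`gp`).** Zero prior mean; RBF
($k(x,x') = e^{-|x-x'|^2/2l^2}$), dot-product, or spectral-mixture kernel.
The spectral-mixture weights multiply unit-value Gaussian-cosine envelopes
so that $k(x,x) = \sum_q a_q$ (the normalization constant is folded into
the weights; $Q = 2$ by default). Hyperparameters maximize
$-y^\top(K+\sigma^2I)^{-1}y - \log|K+\sigma^2I|$ — analytic gradients and
L-BFGS for the RBF case, numerical gradients otherwise; the RBF length
scale initializes at the median pairwise distance. Factorizations use a
Cholesky jitter ladder ($10^{-8}$ to $10^{-4}$ of the mean diagonal) before
raising an error. Posterior means and variances are tested against a direct
matrix-inversion oracle at $10^{-10}$.

**Deep kernel learning (`dkl`).** One shared feature network
$g(x, w): \mathbb{R}^{17} \to \mathbb{R}^{8}$ (width from the
explained-variance rule) under eight independent GP heads; all network
weights and per-head kernel parameters ascend the *summed* log marginal
likelihood jointly (full-batch Adam). The multi-output coupling — a shared
map with independent heads trained on the summed objective — is this
package's design for a question the method leaves open. Three details
matter in the small-sample regime:

* *Initialization.* The feature map starts near the leading principal-
  component projection: the first tanh layer embeds a scaled identity
  (gain 0.4, well inside tanh linearity on $[-1,1]$ inputs), intermediate
  layers relay it, and the last layer holds the leading loadings. Training
  therefore begins from the same subspace the sizing rule reasons about
  instead of from an information-destroying random projection; random
  (Glorot) initialization remains available. The scaled-down default uses
  one 32-unit tanh layer and a *linear* feature layer; a deeper
  tanh/ReLU stack in the published-architecture style is configurable via
  `activations`.
* *Epoch selection.* Likelihood gradients come from a 90 % split; the epoch
  with the best held-out posterior-mean error is kept, and the final heads
  re-condition on all rows at those parameters. Joint likelihood ascent
  otherwise overfits the weakly-identified ions at $n \approx 90$.
* *Clamps.* Per-head $\log l$ and $\log\sigma^2$ are clamped to
  $[10^{-2}, 10^{3}]$ and $[10^{-4}, 10^{4}]$ — wide enough never to bind
  in healthy fits, tight enough to stop a head from collapsing to exact
  interpolation.

A supervised warm start (train the network on targets by MSE, then ascend
the likelihood) is implemented (`pretrain_epochs`) but disabled by default:
at $n \approx 90$ it overfits before the joint objective can correct it.
Two exact reductions are tested: an identity feature map reproduces the
plain GP to $10^{-10}$, and the joint objective gradients match finite
differences.

**Calibration baseline.** `calibrate_array()` fits the log-linear working
curve per electrode. Standard-addition datasets are fitted on the
sample-phase potential `Ux` against the sample concentration (the phase
that carries the concentration signal; the difference `Ux − U0` is a
feature for the learners, not the calibration response), direct-immersion
series on their single reading. Natural log is the default to match the
fitted working-curve form; a decadic option serves Nernstian-slope
reporting.

## 6. Evaluation

RMSE, R² and the replicate coefficient of variation follow their standard
definitions; R² uses the total sum of squares about the mean of the actual
values (the one printed form whose denominator would be degenerate for
perfect predictions is treated as a typographical slip). CV is the
per-sample standard deviation (denominator $N-1$) of three replicate
predictions — three fresh measurements of the same solutions — divided by
the grand mean, in percent, averaged over samples. Degenerate-input
conventions (zero-variance actuals, zero grand mean, constant calibration
responses) raise errors or return 0 as documented per function.

`kfold_cv()` (k = 10) shuffles samples with a seed, keeps fold sizes within
one of each other, and fits the scaler and the feature-width rule inside
each training fold only. `compare_models()` repeats the whole experiment —
new sample realizations, new measurements, three measured replicates — for
each of five seeds and reports per-ion medians. Model failures are recorded
per cell rather than aborting the report.

**Problem sizes.** The default benchmark is 100 samples, 10 folds, 3
measured replicates and 5 seeds; one full run takes about six minutes on a
single CPU, and the unit suites run on 27-sample designs or toy sets. These
sizes are the study conditions themselves (100 training mixtures is the
protocol the design emulates), not a truncation of them.

## 7. What the benchmark does and does not show

The generator emulates: log-linear electrode responses with secondary-ion
interference, Nernstian temperature scaling over 15–35 °C, session drift,
EC/pH transduction, measurement noise, and recipe-independent mixture
compositions from a balanced factorial design.

It does *not* emulate: activity versus concentration non-ideality at high
ionic strength, electrode response-time transients and hysteresis,
membrane aging, correlated drift across channels, or — importantly — the
recipe correlations of real hydroponic samples, whose ions co-vary through
shared stock dilutions. Passing the synthetic benchmark therefore
demonstrates correctness of the pipeline and the advantage of the deep
kernel under these idealized conditions; it does not certify accuracy on
real solutions.

**Magnesium.** The defaults make magnesium inferable *in principle*:
propagating the channel noise through the inverse Jacobian of the full
8-ion forward map bounds the attainable R² near 0.9 at the default
couplings. But realizing that bound requires the precise nonlinear
inversion (exponentiating six electrode curves, correcting by temperature,
and solving the hardness/EC system), and no generic learner reconstructs it
from 100 independent-design samples — cross-validated R² for magnesium
stays near 0 for the network, the GP, the deep kernel, and for stronger
off-package probes, even with noise switched off. This is a sample-
complexity limit, not an implementation defect; with recipe-correlated
real samples the effective problem is far easier, which is the regime where
strong magnesium recovery has been reported. Phosphate, by contrast, has a
quasi-direct channel (pH) and is recovered at R² ≈ 0.98.

## 8. Known limitations

* GP storage and time are $O(n^2)$–$O(n^3)$; the pipeline targets
  $n \le$ a few hundred samples and provides no inducing-point
  approximations.
* The spectral-mixture kernel is available for plain GP regression but not
  for joint deep-kernel training (RBF and dot-product are).
* The BFGS optimizer tag applies to GP hyperparameter fits; network
  training offers Adam and SGD only.
* Calibration inversion (`invert_calibration()`) is single-electrode and
  ignores interference by construction — it is the baseline, not the
  method.
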