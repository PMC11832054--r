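---
title: "MAP T1 mapping, SIR fitting and patch calibration: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MAP T1 mapping, SIR fitting and patch calibration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapt1)
```

# Overview

`mapt1` implements a quantitative T1-relaxometry stack for
magnetization-prepared rapid gradient-echo imaging: the MP2RAGE/MP3RAGE
steady-state forward model, classical lookup-table T1 estimation with
voxelwise B1+ correction, a Monte-Carlo maximum a posteriori (MAP) T1
estimator with posterior-standard-deviation uncertainty maps, a two-pool
selective inversion recovery (SIR) model with voxelwise nonlinear
least-squares T1 fitting, and a patch-based residual CNN that calibrates
MP2RAGE-style T1 maps to multi-TI inversion-recovery values. A seeded
digital phantom makes every stage testable end to end without external
data.

# The forward signal model

An MP2RAGE cycle applies an adiabatic inversion (efficiency `eff`, default
0.84), waits, plays K blocks of `n` low-flip excitations (one gradient-echo
readout per block, at inversion times measured to the block center), and
relaxes until the next inversion. Within the longitudinal-magnetization
approximation every step is an affine map `Mz -> A*Mz + B`:

* inversion: `Mz -> -eff * Mz`;
* free recovery over `t`: `Mz -> Mz * e + (1 - e)` with `e = exp(-t/T1)`;
* one excitation period: `Mz -> Mz * cos(b1*alpha) * E1 + (1 - E1)` with
  `E1 = exp(-TR_exc/T1)`, where `b1` is the unitless transmit-field
  correction factor multiplying the nominal flip angle.

A run of `m` periods composes in closed form (geometric series), so the
whole cycle is one affine map whose fixed point `B/(1 - A)` is the periodic
steady state. Signals are read at the block center, `(n/2)*TR_exc` after
block start; the half-block exponent may be fractional (112.5 for the
default protocol). `M0` is normalized to 1 — the uniform image is
scale-invariant, so signals are unitless. The explicit per-excitation cycle
iteration is retained purely as a test oracle: the suite checks that the
fixed point matches 60 iterated cycles to 1e-10 across a 500-point T1 grid.

The timing decomposition (`derive_block_timing()`) converts block-center
inversion times into the pre-block delay TA, inter-block gaps, and tail
delay TD; for the default protocol (TI 1010/3683/6355 ms, TR 6 ms, n = 225,
cycle 8.25 s) these are 0.335, 1.323/1.322 and 1.220 s, summing exactly to
the cycle duration. Negative components indicate an impossible protocol and
raise an error naming the offending gap.

Two readouts combine into the uniform T1-weighted image
`S = Re(conj(g1)*g2) / (|g1|^2 + |g2|^2)`, bounded in [-0.5, 0.5] by the
AM-GM inequality, with 0/0 defined as 0. The beta-regularized variant
(`robust_uniform_signal()`, beta = 0.25 times the volume-mean sum of squared
magnitudes by default) suppresses background noise for
registration-support imagery only; it is never used for fitting because it
breaks the lookup relation.

# Point-estimate and MAP T1 inference

The classical estimator tabulates `S(T1)` on a fine grid (500 points over
(0, 5] s), restricts it to the largest strictly monotone branch containing
T1 = 1.5 s, and inverts by monotone interpolation; per voxel the curve is
linearly interpolated between tables at the two B1 grid factors bracketing
the voxel's `b1` (41 linearly spaced factors over [0, 2]). Signals outside
the branch are masked invalid, never clipped.

The MAP estimator simulates the acquisition: for each T1 on the prior grid
it draws Gaussian noise (standard deviation `noise_sigma`, default 0.005 in
signal units) independently on the real and imaginary part of every
readout, forms S1,2 (and S1,3 in joint MP3RAGE mode), and histograms the
values into 100 bins over [-0.5, 0.5] (a 100 x 100 2-D histogram in joint
mode). Sampling is stratified — an equal number of trials per grid point —
which realizes the uniform T1 prior on (0, 5] with exact per-row
normalization. Row normalization of the counts gives the likelihood;
column normalization gives the posterior by Bayes' theorem. Per signal bin
the package precomputes the posterior argmax (ties broken toward the
smaller T1, a documented determinism convention) and the posterior standard
deviation, which becomes the voxelwise uncertainty map. Empty bins mark a
voxel invalid rather than interpolating.

Three design points deserve emphasis:

* **Posterior T1 grid: 100 points over (0, 5].** The histogram has 100
  signal bins, and the measured slope of S1,2 in T1 for the default
  protocol is 0.12-0.33 per second, so one 0.01-wide signal bin spans up to
  about 0.08 s of T1. A much finer T1 grid cannot add information — the
  argmax within a bin becomes an essentially arbitrary choice among
  indistinguishable grid points — so the grid step (0.05 s) is matched to
  the signal resolution. The point-estimate lookup, which is not
  bin-limited, keeps the finer 500-point grid.
* **Noise units.** The noise level is a signal-domain standard deviation
  (unitless, like the GRE signals); when estimated from data
  (`estimate_noise_roi()`) the measured SD — the maximum over the real and
  imaginary channels of all readouts in a homogeneous region of interest —
  is rescaled by the ratio of the modeled ideal-signal range (T1 in
  [0.5, 5] s) to the acquired magnitude range inside the brain mask, so the
  contrast-to-noise ratio carries over to simulation units. The range-ratio
  rule is a documented choice; the noise level is treated as globally
  fixed.
* **Reproducibility.** One user seed expands into per-(B1, T1-grid-point)
  substreams through a counter-mixing scheme, so tables are bit-identical
  regardless of the order in which B1 factors are processed, and posterior
  caches embed a fingerprint that rejects stale files.

# Two-pool SIR fitting

The SIR model couples free-water (f) and macromolecular (m) longitudinal
pools with equal relaxation rates `R1f = R1m = R1`:
`dM/dt = -(R1*I + X)(M - Minf)` with exchange generator
`X = [[kfm, -kmf], [-kfm, kmf]]`, `kfm = psr*kmf`, and equilibrium
`Minf = (m0f, psr*m0f)`. `X` is rank one, so the recovery has the
closed-form eigen-rates `R1` and `R1 + kmf*(1 + psr)`; this closed form is
the normative model here and is validated against adaptive numerical ODE
integration (1e-6 relative over random parameter draws). The sequence model
assumes complete saturation after each readout: both pools start at zero,
recover over the pre-delay `td`, are scaled by the inversion coefficients
`(sf, sm)`, and recover over `ti` where the free-pool signal is read.

Defaults: the 13 printed inversion times from 6 ms to 8 s; `td` = 2.5 ms as
printed — an unusually short SIR pre-delay, so it is configurable and
flagged as suspect rather than hard-coded; bounds r1 in [0.1, 5] 1/s, psr
in [0, 0.5], kmf in [0, 100] 1/s, sf in [-1, 0]. The fit runs
Levenberg-Marquardt over `{r1, psr, kmf, sf, m0f}` with `sm` fixed from a
B1-indexed lookup (simulating the inversion pulse to derive Sm(B1) is out
of scope; the table is clamped at its endpoints), optional three-start
deterministic multi-start, and reports `T1 = 1/r1`. Signals are fit with
sign; degenerate (constant) voxels and non-converged fits are flagged, not
raised.

# Patch-based calibration network

The calibrator regresses the multi-TI IR T1 value at a voxel from the
P x P in-plane patch of the MP2RAGE-side T1 map centered there (optionally
with the posterior-SD map as a second channel). Patches are strictly 2-D
axial; in-plane borders use reflect padding and invalid neighbors are
replaced by the center value; only WM/SGM/CGM centers produce samples. The
network is an 18-weight-layer residual topology — 3x3 stride-1 stem, four
stages of two basic blocks with widths `width_base * (1, 2, 4, 8)`, global
average pooling, scalar affine head — with one adaptation: a stage opens
with stride 2 only while the incoming spatial extent is at least 4, because
a stock configuration would collapse a 5 x 5 input to nothing. Training
minimizes mean squared error with adaptive-moment gradient descent (the
optimizer identity and input normalization are open choices; inputs are fed
in seconds without standardization since inputs and targets share units and
range), seeded batch shuffling, validation every 50 steps, and early
stopping after 1000 steps (20 evaluations) without a new best validation
loss; the best-validation checkpoint is returned. Cross-validation rotates
the test subject (train 2 / validate 1 / test 1 for four subjects), with
subject-disjointness asserted inside the fold builder.

The engine itself is written in vectorized R (channels-first matrices,
im2col gathers, BLAS multiplies, exact population-statistics batch norm)
and its backward pass is verified against numerical differentiation in the
test suite.

**Benchmark scale.** The stock width (64, i.e. widths 64/128/256/512),
learning rate 1e-5, batch 256 and 10,000-step budget remain the package
defaults. The built-in synthetic benchmark runs a reduced schedule chosen
for a single CPU: `calib_config_reduced()` keeps the topology but uses
width base 4, batch 64, learning rate 1e-3 (raised to compensate for the
shorter schedule), a 2000-step cap, and caps validation evaluations at
2000 seeded samples. These are problem-size choices, set once and
documented here; the calibration-efficacy margins observed in the tests do
not depend on them being at the edge of feasibility.

# The digital phantom

Each subject is a 48 x 48 x 5 grid (five axial slices) of concentric
shells: CSF core, subcortical gray ring, white-matter bulk, cortical gray
shell, background outside — the simplest geometry containing all four
tissues with shells thick enough to survive 3-voxel cube erosion. Tissue
truths are the multi-TI IR tissue means used as configured ground truth
(WM 1.48, SGM 1.74, CGM 2.05 s); CSF is a 4.3 s placeholder inside the
prior support and excluded from metrics. Subjects differ by a seeded
+/- 2 percent per-tissue T1 jitter. The B1+ field is a smooth low-order
in-plane polynomial (range within [0.7, 1.3]), constant across slices,
mirroring the axial-equivalence assumption of slice-wise B1 mapping; it is
also identical across subjects, which real cohorts would not be. GREs are
simulated from the forward model with quadrature Gaussian noise
(background voxels are pure noise); SIR volumes use literature-typical
placeholder pool parameters per tissue (WM psr 0.12, GM psr 0.06, kmf 10
1/s, sf -0.95) that are configuration values, not asserted constants.

The MP2RAGE-vs-IR discrepancy is emulated by `inject_tissue_bias()`:
per-tissue multiplicative factors (WM 0.828, SGM 0.891, CGM 0.953 — the
observed relative values) times a smooth 2 percent spatial modulation that
is demeaned within each tissue, so the measured per-tissue relative value
equals the configured factor by construction (a closure test of the
metric-plus-injection plumbing). What passing the calibration benchmark
shows is therefore that the network can undo a smooth, tissue-structured
multiplicative bias in the presence of realistic estimator noise; it does
not certify performance on real anatomy, partial-volume mixtures,
registration error, or scanner-to-scanner differences — the latter being an
explicit limitation of patch calibrators trained on small cohorts.

# Agreement metrics

Per tissue the package reports RMSE, relative value (ratio of tissue means
in percent, per subject, averaged across subjects; a voxelwise-ratio
variant sits behind a flag), and a Bland-Altman decomposition: bias (mean
voxelwise error), population SD of the error, limits of agreement
`bias +/- 1.96*SD`, and error variance. The population-variance convention
makes `rmse^2 = bias^2 + variance` exact to machine precision, which the
suite asserts at 1e-12. All comparisons run on the intersection of
validity masks with voxel counts reported. Erosion of a label by an odd
cube (default: CGM by 3 voxels, mitigating CSF partial-volume voxels)
matches brute-force morphology in the tests. Fold-level error vectors are
compared with a classical paired two-sided t-test at alpha 0.05;
zero-variance differences are flagged degenerate instead of erroring.

# Problem sizes used by tests and the acceptance script

Monte-Carlo tables use 1e5-1e6 trials in the suite (the 1e7 default
remains available); the uncertainty-vs-noise sweep runs the five noise
levels 0.001-0.02 at 1e6 trials; SIR recovery is checked on seeded
60-voxel-per-tissue subsamples; the calibration benchmark runs the full
four-fold rotation at the reduced schedule plus one two-channel fold for
the uncertainty-input comparison. The acceptance script reproduces the
same quantities from scratch under a caller-supplied seed.

# Known limitations

* The forward model ignores T2*, B0, radio-frequency spoiling imperfections
  and pulse-shape effects; inversion efficiency and the macromolecular
  inversion coefficient are consumed as inputs, not simulated.
* The noise level is global; locally varying noise fields are out of scope.
* MAP resolution is bounded by the 100-bin signal histogram; posterior SD
  at high noise saturates toward the uniform-prior spread (5/sqrt(12) s).
* The phantom's geometry and subject-invariant B1 field are idealized;
  conclusions about real-data calibration transfer are limited accordingly.
* Registration, segmentation and skull stripping are assumed done upstream;
  all inputs must be co-registered.
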