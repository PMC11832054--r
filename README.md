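# mapt1 — MAP T1 mapping for MP2RAGE/MP3RAGE with SIR cross-calibration

Quantitative T1 mapping with MP2RAGE acquires two complex gradient-echo
readouts (GREs) per inversion cycle and combines them into the uniform
image `S = Re(conj(g1)·g2) / (|g1|² + |g2|²) ∈ [−0.5, 0.5]`, which is
inverted through the sequence's steady-state signal model to give T1 per
voxel. `mapt1` implements that stack in R, for researchers comparing and
harmonizing T1 maps across acquisition protocols:

* **Forward model** — closed-form steady state of the inversion cycle
  (affine propagation of longitudinal magnetization through inversion,
  free recovery and excitation trains), for 2- and 3-readout (MP3RAGE)
  protocols with per-voxel B1+ flip-angle scaling.
* **Point-estimate T1** — the classical monotone lookup-table inversion of
  `S(T1)`, interpolated across a grid of B1+ correction factors.
* **MAP T1 with uncertainty** — a Monte-Carlo posterior
  `P(T1 | S)` built by simulating the acquisition under quadrature
  Gaussian noise (Bayes' theorem with a uniform T1 prior on (0, 5] s),
  yielding the posterior-argmax T1 and a posterior-SD uncertainty map;
  the joint mode uses both T1-weighted images (S₁,₂, S₁,₃) of a
  three-readout acquisition.
* **Two-pool SIR fitting** — biexponential selective-inversion-recovery
  model (free water and macromolecular pools, shared R1, exchange kmf,
  pool-size ratio), voxelwise Levenberg–Marquardt fits reporting
  T1 = 1/R1f.
* **Patch-based calibration** — an 18-layer residual CNN (implemented in
  vectorized R, gradient-checked) regressing the IR-reference T1 at a
  voxel from the 5×5 in-plane patch of the MP2RAGE-side map, with
  leave-one-out cross-validation, early stopping and an optional
  uncertainty input channel.
* **Phantom and metrics** — a seeded digital brain phantom (tissue labels,
  ground-truth T1, smooth B1+ field, simulated GRE/SIR volumes, injected
  tissue-dependent bias) plus per-tissue RMSE, relative values,
  Bland-Altman bias/variance decomposition (`rmse² = bias² + variance`
  exactly) and paired t-tests. Volumes are NIfTI-1 throughout.

See the methods vignette (`vignettes/map-t1-methods.Rmd`) for the models,
assumptions and design decisions.

## Worked example

```r
library(mapt1)

protocol <- default_protocol()      # TI 1010/3683/6355 ms, 8.25 s cycle
spec <- phantom_spec(inter_subject_jitter = 0, noise_sigma = 0.001, seed = 6)
ph <- make_phantom(spec, subject_index = 1)
gres <- simulate_mp3rage(ph$true_t1, ph$b1, protocol, sigma = 0.001, seed = 6)

cfg <- mc_config(n_trials = 1e6, noise_sigma = 0.001, seed = 6)
mp <- map_t1_volume(gres, ph$b1, protocol, cfg, mode = "pair")
mp
#> T1 map (map_mp2rage): 11403/11520 valid voxels, median T1 = 1.850 s

for (t in c("WM", "SGM", "CGM")) {
  vox <- ph$labels == tissue_codes[t]
  cat(sprintf("%-3s  truth %.2f s   MAP mean %.3f s   median sigma %.3f s\n",
              t, spec$tissue_t1_s[[t]], mean(mp$t1_s[vox]),
              median(mp$sigma_t1_s[vox])))
}
#> WM   truth 1.48 s   MAP mean 1.484 s   median sigma 0.060 s
#> SGM  truth 1.74 s   MAP mean 1.738 s   median sigma 0.078 s
#> CGM  truth 2.05 s   MAP mean 2.053 s   median sigma 0.101 s
```

The MAP tissue means recover the configured ground truth to a few
milliseconds at this noise level, and the posterior-SD map quantifies the
voxelwise uncertainty (larger at longer T1, where the signal curve
flattens). Injecting the tissue-dependent bias and training the calibrator
(`synth_subjects()`, `loo_cv()`) then demonstrates the full
compare-and-calibrate workflow; `run_pipeline()` chains every stage and
writes NIfTI maps plus JSON/CSV reports, and `inst/cli/mapt1.R` exposes the
same stages as shell subcommands.

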