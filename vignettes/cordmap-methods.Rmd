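---
title: "Methods: cerebro-spinal somatotopy from resting-state connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebro-spinal somatotopy from resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The cervical spinal cord is organized in rostro-caudal segments (C1–C7)
whose nerves innervate distinct body territories, and the sensorimotor
cortex (SMC) maps those same territories somatotopically. If both
structures encode the same body map, spontaneous (resting-state) BOLD
fluctuations of a given cord segment should correlate preferentially with
the cortical territory it serves. `cordmap` implements the full analysis
chain needed to test this on paired brain + cervical-cord fMRI:

1. quality control (framewise displacement, temporal SNR);
2. physiological-noise modelling and denoising;
3. data-driven network extraction by innovation-driven co-activation
   patterns (iCAPs);
4. seed-to-voxel functional connectivity (FC) from cord segments to the
   cortex, with winner-take-all (WTA) somatotopic labelling;
5. connectivity-based parcellation of the cord from its FC profiles with
   the SMC.

Because every stage is a potential failure point, the package ships a
synthetic phantom generator with a *planted* somatotopic coupling, so each
stage — and the chain end to end — is testable by parameter recovery.

## The phantom: planted study conditions

`phantom_config()` emulates the acquisition this kind of study uses:
TR = 1.55 s, 230 volumes, 7 cord segments. One subject consists of a cord
grid (default 6 × 6 × 42, segments stacked along the third axis, gray
matter a central in-plane block surrounded by a CSF ring) and a cortical
slab (default 42 × 14 × 3) whose sensorimotor strip is tiled by 7 patches
along its first axis.

The generative model, per subject:

- each segment *s* has a spontaneous event train `e_s` (Bernoulli per
  volume, rate 0.05 — roughly one event per 30 s, a pragmatic choice since
  spontaneous-event statistics of real cord data are not well
  characterized) convolved with a canonical double-gamma HRF into the
  neural signal `n_s`;
- cord gray-matter voxels of segment *s* carry `n_s` plus i.i.d. Gaussian
  noise scaled so that sd(signal)/sd(noise) equals `coupling_snr`
  (default 1: shared fluctuation at the same scale as voxel noise, the
  order of magnitude seen in resting-state BOLD);
- cortical voxels of patch *p* carry the mixture
  `sum_s 0.3^|p-s| n_s` — a geometric falloff that creates a *graded*
  somatotopic gradient the winner-take-all must resolve, not a trivial
  block structure — plus noise under the same SNR rule;
- all tissue voxels receive cardiac (1 Hz) and respiratory (0.3 Hz)
  sinusoids sampled at the TR (so the cardiac component is aliased), CSF
  voxels carry *only* physiological signal, drift and white noise;
- slow drift is a random linear + half-cosine trend per voxel;
- motion is a bounded random walk (6 brain parameters, 2 in-plane cord
  translations); its framewise displacement modulates image intensity
  multiplicatively. This keeps the phantom analytic — no resampling — and
  is a documented limitation: real motion also blurs and displaces tissue
  boundaries.

Physiological traces are generated at 100 Hz and subsampled at volume
times, so RETROICOR phase estimation operates on realistic high-rate
inputs; cardiac peak times are known analytically and stored.

What passing recovery tests on this phantom shows: the pipeline's
estimators are consistent under the stated generative model. What it does
not show: robustness to distortion, partial voluming, non-stationary
physiology, or template misregistration, none of which the phantom
contains.

## Quality control

Framewise displacement uses the sum-of-absolute-backward-differences
convention with a 50 mm rotation radius for the brain's six parameters;
the cord's slice-wise realignment yields two in-plane translations, so
cord FD is the mean of |Δx| and |Δy|. The first volume has FD 0, and runs
with mean FD above 0.3 mm are flagged. tSNR is mean over population
(ddof = 0) standard deviation; zero-variance voxels are reported as 0 with
a degeneracy count rather than NaN.

## The nuisance model and denoising

The design combines, with per-column provenance tags:

- **RETROICOR**: 3 cardiac + 4 respiratory harmonics as `{sin, cos}` pairs
  plus one multiplicative order expanded as `{sin, cos}` of the phase sum
  *and* difference — 6 + 8 + 4 = 18 regressors. Cardiac phase is linear
  between pulse peaks in `[0, 2π)`; respiratory phase uses the
  histogram-equalized amplitude transfer signed by the belt derivative
  (range `(-π, π]`).
- **CompCor**: leading principal components over time of the demeaned,
  variance-normalized CSF voxel series (12 brain / 5 cord by default),
  unit-norm, deterministic sign (largest-magnitude voxel loading
  positive).
- **DCT**: the 5 lowest-frequency non-constant DCT-II vectors for
  detrending.
- **Motion**: the realignment parameters themselves.

`denoise()` removes the design by least-squares projection applied
*orthogonally to* a band-pass filter: the filter is a zero-phase
frequency-domain mask with inclusive edges [0.01, 0.17] Hz, and the
regressors are filtered with the same mask before the projection, so
filtering cannot reintroduce removed confounds. The order of operations
is: demean, filter both sides, project, demean, standardize. The
deconvolution path uses `apply_bandpass = FALSE` (projection only),
because hemodynamic deconvolution wants the full-spectrum signal.
Rank-deficient designs are repaired by dropping dependent columns with a
warning. Gaussian smoothing is separable with FWHM given in mm per axis
(3 × 3 × 6 mm for the cord, 6 × 6 × 6 mm for the brain by default),
kernels truncated at 3.5 σ, zero-padded at the boundary.

## iCAPs: deconvolution, frame selection, temporal clustering

**Deconvolution.** Per voxel we solve

    min_a 0.5 ||y − H a||² + λ TV(a)

where `H` is causal convolution with the double-gamma HRF and `TV` the
total variation of the activity signal `a` — sparsity on temporal
transitions, so `a` is piecewise constant and its jumps are the
*innovations*. Numerics that matter:

- a free per-voxel baseline is absorbed by projecting the constant out of
  both the data and the columns of `H`; without this, the causal onset
  transient forces a spurious early jump to fit the demeaned baseline;
- the solver is a monotone accelerated proximal-gradient scheme whose
  proximal map is the *exact* 1-D TV denoiser (Condat's direct algorithm,
  compiled); each voxel's penalized objective is non-increasing by
  construction. Note the natural Lyapunov function of a regularized
  scheme is the penalized objective, not the data-fit residual alone;
- convergence requires both the monotone iterate and the raw prox iterate
  to stabilize (relative change < 1e-6), with an iteration cap of 2500 —
  the operator is singular (the HRF starts at zero), and the cap is sized
  so that default-condition phantoms converge rather than being an active
  constraint;
- λ defaults to a per-voxel robust noise estimate,
  `mad(diff(y))/√2 · √(2 log T)`, times a global multiplier of 0.5
  calibrated once on planted step/spike fixtures and phantom event
  recall.

**Frame selection.** Each voxel's innovation series is compared with
phase-randomized surrogates of itself; the per-voxel two-sided threshold
is the 1 − α surrogate amplitude quantile (α = 0.05, 100 surrogates). A
frame is retained when at least `min_active_fraction = 0.05` of voxels
are suprathreshold. An empty selection is an error with a diagnostic, not
an empty result.

**Clustering.** Selected frames are thresholded (subthreshold voxels
zeroed) and *rectified to their dominant transition polarity*: a frame
records one event's rise or fall, and opposite-sign voxels belong to
other events' concurrent transitions — keeping them was observed, on the
phantom, to scatter single-event frames across clusters. K-means then
uses cosine distance with polarity folding (a frame and its negation are
equivalent), kmeans++-style seeding, best of 20 restarts by within-cluster
dispersion; K = 7 for the cord (the segmental levels in the field of
view) and K = 10 for the brain. Cluster maps are z-scored means of
sign-aligned member frames. Consensus clustering (Monti-style: 50
subsamples of 80 % of frames, co-assignment frequency among subsamples
containing both frames) scores each cluster's stability in [0, 1]; a
single subsample is flagged uninformative with trivial scores of 1.

## Seed FC and winner-take-all

Seeds are the cord segments (ground truth on the phantom, an atlas, or
binarized iCAP maps at z ≥ 1.5 — a configuration choice). Seed series are
unweighted means of *unsmoothed* denoised member voxels. Per seed, the
Pearson correlation with every cortical voxel is Fisher-transformed
(`atanh`, input clamped to ±(1 − 1e-7)), averaged across subjects, and
the winner-take-all labels each voxel with the seed of maximal z — signed
z by default (a `positive_only` switch masks voxels whose maximum is
non-positive), exact ties to the lowest seed index with a reported count
(ties have measure zero on real data; the rule exists for determinism on
synthetic integers). The per-subject reproducibility table counts, within
each group-level winner mask, the voxels each subject assigned to each
level; fitting the mixed model on that table is downstream statistical
software's job, not this package's.

## Connectivity-based parcellation

The feature matrix Z (cord voxels × SMC voxels, Fisher z) yields a
similarity matrix as the row-wise Pearson correlation of FC profiles
(each row centered and scaled — the "cross-correlation of Z"), averaged
across subjects. Average-linkage (UPGMA) hierarchical clustering of
D = 1 − S is cut at K = 7 and neighbours (±2). Cluster labels are matched
to atlas levels by maximum-weight bipartite matching with Dice weights
(voxel overlap available as an option), and agreement is summarized as
mean ± sd Dice. Stability across participants is (i) the per-voxel mean
correlation of similarity profiles over subject pairs (own diagonal entry
excluded), and (ii) per-subject clusterings aligned to the group solution
through size-normalized contingency matrices and the same matcher, with
heatmaps counting subjects covering each voxel. Cluster fingerprints are
means of member-voxel FC maps (not FC of the mean series — the two differ
under Fisher z), averaged across subjects, with a WTA over the K
fingerprints.

## Design choices where the design was open

- *Coupling SNR grid for degradation checks*: c(1, 0.2, 0.1, 0.05),
  chosen to span the regime from ceiling recovery through the transition
  to near-chance, so monotone degradation is expressed rather than
  saturated.
- *Interaction term*: one multiplicative order contributes 4 columns
  (sum and difference phases), which is what makes the total 18 given
  6 + 8 harmonic columns.
- *Matching weight*: Dice, because Dice is the reported agreement
  statistic; overlap counts are available.
- *Similarity "cross-correlation"*: row-wise Pearson, consistent with the
  FC-fingerprint literature; a raw inner product is available behind a
  flag.
- *Group clustering input*: the group-mean similarity matrix; per-subject
  clusterings reuse identical settings.
- *Unsmoothed series* for seed extraction and the feature matrix;
  smoothed series only for the deconvolution path.

## Problem sizes used in the shipped tests

The test-suite and acceptance runs use the default study conditions
(8 subjects, 230 volumes, 7 segments, coupling SNR 1) for recovery
claims, 20 single-subject phantoms for calibration-style properties, and
reduced grids (4 segments, 120 volumes) where only contracts — not
recovery — are being exercised.

## Known limitations

- The phantom's motion model modulates intensity but does not resample;
  motion-induced geometric distortion is out of scope.
- The deconvolution is per-voxel TV-regularized with a fixed canonical
  HRF; it does not implement the spatially regularized generalized
  forward–backward solver of the full Total Activation literature, and is
  isolated behind the `activity_signals` contract so such a solver could
  be swapped in.
- Event trains are Bernoulli with unit amplitude; real spontaneous
  activity has unknown amplitude and duration statistics.
- All stages assume pre-aligned data; registration, motion correction and
  segmentation are upstream tools' responsibility.
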