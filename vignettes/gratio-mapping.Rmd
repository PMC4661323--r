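---
title: "MR g-ratio mapping: model, calibration, and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR g-ratio mapping: model, calibration, and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gratiomap)
```

## The voxel fiber-geometry model

A white-matter voxel is modelled as a bundle of parallel annular cylinders
seen in cross-section: fiber $j$ has outer radius $R_{O,j}$ (axon plus
myelin) and g-ratio $g_j = R_{I,j}/R_{O,j} \in (0, 1]$, with $g_j = 1$
meaning an unmyelinated axon. Only cross-sectional *areas* enter the
theory, so `fiber_population()` enforces the aggregate packing constraint
$\sum_j \pi R_{O,j}^2 \le A$ rather than any geometric placement. The
fiber (FVF), myelin (MVF) and extra-axonal (EVF $= 1-\mathrm{FVF}$)
volume fractions are plain sums over the stored fiber list; storing
explicit draws instead of binned probability distributions makes every
expectation a finite sum that is exact per realisation, which is what the
identity tests rely on.

Two voxel-level aggregates matter:

* the **microscopic mean** $\bar g = \tfrac1N \sum_j g_j$ — what electron
  microscopy histograms estimate, and
* the **area-weighted RMS** $\sqrt{\sum g_j^2 R_{O,j}^2 / \sum R_{O,j}^2}$
  — what the imaging estimate $\sqrt{1-\mathrm{MVF}/\mathrm{FVF}}$ equals
  *identically*, for any fiber list.

The identity is algebraic, so the test suite checks it to $10^{-12}$ on
randomly sampled populations, including two-pool mixtures with an
unmyelinated fraction at $g = 1$. Two consequences worth keeping in mind
when interpreting maps: by Jensen's inequality the RMS aggregate is biased
upward relative to the area-weighted mean whenever g varies within the
voxel, and an unmyelinated pool drags the MR g-ratio above the myelinated
pool's typical g.

`conduction_velocity_factor()` implements Rushton's classical result that
at fixed outer diameter conduction velocity scales as
$f(g) = g\sqrt{\ln(1/g)}$, with its unique maximum at $1/\sqrt e \approx
0.607$. We adopt Rushton's form because it is the standard closed-form
choice; other classical treatments give the same optimum region but no
simple factor, and we deliberately do not attach a number to how fast
velocity falls off away from the optimum.

## MT saturation and R1 from the FLASH triplet

The MPM protocol acquires PD-weighted, T1-weighted and MT-weighted
multi-echo FLASH volumes (flip angles 5°/29°/9°, TR 25.25/25.25/29.25 ms,
eight echoes of which the first six are averaged for SNR — the package
default averages six and is configurable). Map computation uses the
small-flip-angle rational approximation of the spoiled gradient-echo
steady state,

$$S = A\,\alpha\,\frac{R_1 TR}{\alpha^2/2 + \delta + R_1 TR},$$

where $\delta$ is the extra per-TR saturation produced by the MT
pre-pulse. `fit_r1_a()` inverts the PDw/T1w pair for $R_1$ and the
apparent amplitude $A$; `fit_mt_sat()` then solves the MTw signal for
$\delta$, reported in percent units so that healthy white matter sits
near 2 p.u. Under the forward model above all three inversions are exact
(verified to machine precision in the round-trip tests), so residual
error on real data comes from the model, not the algebra. Design
choices: maps are fitted everywhere and masked downstream; negative MT
saturations are flagged but never clipped, so artefacts stay visible;
B1+ (flip-angle inhomogeneity) correction is out of scope and nominal
angles are used.

## Tensor fit and the fiber-density proxy

`fit_tensor_wls()` is a log-linear weighted least-squares tensor fit: an
OLS pass on log-signals followed by one reweighting with weights equal to
the squared predicted signals. The low-b volumes (b = 100 s/mm²) enter
the design matrix with their true b-value — the protocol acquires b = 100,
not b = 0, and treating them as unweighted would bias the fit.
Non-positive signals are excluded per voxel; a voxel needs at least 7
usable measurements. Negative eigenvalues are flagged, not clipped, and
excluded from the density proxy.

True fiber-density estimation (fiber-conservation PDE solvers) is out of
scope; such maps can be supplied via `load_external_density()`. The
built-in stand-in is the tensor's linear-anisotropy coefficient
$c_l = (\lambda_1-\lambda_2)/(\lambda_1+\lambda_2+\lambda_3)$, clamped at
zero and divided by its white-matter mean so the mask mean is exactly 1.
Any proportionality error between this proxy and the true FVF is a single
per-subject scale — precisely the "global factor" that the g-ratio
calibration constant absorbs, which is why a proxy is admissible here at
all. The proxy is invariant to global signal scaling and to global
diffusivity scaling (it is a ratio), which the tests assert.

## Calibration and the g-ratio map

`calibrate_alpha()` solves for the single constant $\alpha$ in
$g = \sqrt{1-\alpha\,\mathrm{MT}/\mathrm{density}}$ by anchoring a
reference ROI to a literature value ($g = 0.7$ for the splenium, from
ex-vivo electron microscopy of large-diameter axons). The anchored
statistic is the ROI mean of voxel-wise g ("mean-of-g", a monotone 1-D
root find over the interval of $\alpha$ that keeps every ROI radicand
non-negative); a "ratio-of-means" mode (g formed from ROI-mean MT and
ROI-mean density, closed form) is selectable because the published
description does not distinguish the two. One subject's $\alpha$ is then
fixed for the cohort.

`compute_g_map()` evaluates the formula on the diffusion-resolution grid
(the coarser, rate-limiting map; MT is resampled down with world-space
trilinear interpolation via `resample_to_grid()`). Voxels with
non-positive density or a negative radicand are **masked, never clipped**:
implausible $g \approx 1$ values at structure edges are the diagnostic
signature of MT/diffusion misalignment, and clipping would hide exactly
the artefact a user needs to see.

### Susceptibility displacement

EPI susceptibility distortion displaces diffusion data along the
phase-encode axis, misaligning the density map against the undistorted MT
map. `displacement_field()` and `apply_displacement()` implement a 1-D
pull warp with linear interpolation (optionally Jacobian-modulated);
`invert = TRUE` applies the negated field, the first-order correction that
is exact for locally constant fields. `distortion_demo()` reproduces the
edge-bias phenomenon on the phantom: an uncorrected two-voxel shift
produces hundreds of invalid / near-1 voxels inside white matter, and
inverse correction removes ≥ 90 % of them (100 % in the noiseless case).

## Group statistics

`group_summary()` computes voxel-wise cohort mean, sample SD (n−1) and
CoV over valid subjects; `cov_threshold_mask()` applies the strict
CoV < 0.3 reliability cut used before ROI analyses (fiber-density proxies
are unreliable toward white-matter edges, which is where the CoV
concentrates). `parcellate_cc()` splits a corpus-callosum mask into 8
equidistant anterior–posterior intervals *in world millimetres* (the
affine decides which voxel axis carries A–P); `tract_roi()` forms the
conjunction of a probabilistic tract map thresholded inclusively at 50 %
with the CoV mask, flagging ROIs under 100 voxels. `roi_statistics()`
follows the subject-then-group convention — within-ROI SD per subject
first, then averaged — to match how ex-vivo comparisons are tabulated.
`tract_contrasts()` runs a one-way ANOVA on subject-level tract means and
one-sided Welch t-tests against a reference tract at an uncorrected
p < 0.05, the published convention; its type-I error is verified against
the nominal rate by a 1000-replicate null simulation.
`mt_density_correlation()` correlates subject-wise ROI means of MT and
density per ROI (Pearson, two-sided).

Boundary conventions are explicit and configurable: CoV threshold strict
(`cov = 0.3` excluded), probability threshold inclusive (`p = 0.5`
included).

## The synthetic phantom

`phantom_spec()` defines the study conditions; the defaults *are* the
conditions under which the package validates itself:

| parameter | default | why |
|---|---|---|
| diffusion grid | 32³ @ 2.3 mm (48³ for the cohort recovery runs) | protocol resolution; 48³ keeps a 10-subject cohort within desk-scale runtime |
| MPM grid | 2× refinement (1.15 mm) | finer-than-diffusion MT, boundary-aligned (below) |
| gradient scheme | 60 Fibonacci-sphere directions at b = 1000 + 6 at b = 100 s/mm² | the single-shell protocol |
| FLASH protocol | 5°/29°/9°, TR 25.25/29.25 ms, 6 echoes | the MPM protocol |
| structures (FVF, g) | background (0.10, 0.95), CC (0.65, 0.70), CST-like (0.60, 0.72), SLF-like (0.55, 0.62) | white-matter-typical fractions; CC at the splenium anchor value |
| between-subject SD | g 0.02, FVF 0.03 | a few percent, the scale of healthy-cohort variability |
| SNR | diffusion 20, MPM 50 | typical single-shell dMRI; multi-echo FLASH is higher-SNR |
| MT per MVF (κ) | 6.7 p.u. | gives WM MT ≈ 2 p.u.; κ is a free synthetic parameter, not a biological constant, and calibration absorbs it |
| λ₁, anisotropy scale | 1.7×10⁻³ mm²/s, c_l = 0.92·FVF | healthy-WM axial diffusivity; keeps the proxy inversion feasible for all FVF |

Ground truth is built per structure and per subject
(MVF = FVF·(1−g²) identically, so the geometry identity holds on every
generated map), FLASH signals are forward-simulated with the same
rational model the fit inverts, and the diffusion tensor's minor
eigenvalues are solved so its linear-anisotropy coefficient equals the
target density — making the density-proxy inversion exact and noiseless
end-to-end recovery well-posed. Rician noise is simulated by adding
complex Gaussian noise and taking magnitudes (first-order bias
σ²/2S, asserted on flat patches); noise seeds derive hierarchically from
the cohort seed (`seed + 104729·subject + modality`), so cohorts are
bit-reproducible and subjects independently regenerable.

Two grid choices deserve explanation. First, the MPM grid is an exact 2×
refinement whose voxel *boundaries* coincide with diffusion voxel
boundaries; the trilinear sample at a diffusion voxel centre then
averages only MPM voxels inside that diffusion voxel, so resampling a
piecewise-constant map is exact and interpolation error cannot masquerade
as (or hide) a mapping error. Second, the splenium-like reference ROI is
the posterior-most of 8 CC parcels intersected with the one-voxel
interior of the CC mask — erosion against the tissue boundary, where
partial-volume effects live, not against the internal parcel faces.

### What the phantom does and does not show

The phantom has piecewise-constant microstructure, single-tensor
diffusion, no R2\* echo decay, no B1+ inhomogeneity, nominal coil
uniformity, and identity registration between modalities. Passing tests
therefore demonstrate that the *estimation chain* is correct — forward
models invert exactly, the calibration solves its anchor, distortion
correction removes the bias it models — not that the proxies are
biologically accurate on real tissue, where MT is not exactly
proportional to myelin, tensors do not capture crossing fibers, and
registration is imperfect.

### Calibration transfer and the recovery criteria

With a truth-anchored calibration the noiseless chain recovers ground
truth to ~10⁻¹⁴; the noiseless cohort check therefore anchors each
subject at its own true reference-ROI mean, isolating chain exactness.
Reusing one subject's α across a cohort — the realistic protocol — adds
an irreducible error of order the between-subject spread of mean
white-matter FVF (~2 % here), because the density proxy is renormalised
per subject while α is not. This is the known global-factor limitation of
per-subject-normalised density measures, and it is why the noisy cohort
check (single α, anchor 0.7, SNR 20) is held to a median absolute error
of 0.05 rather than machine precision; measured medians are ≈ 0.02–0.04.

## Numerical conventions

Computation is double precision; NIfTI output is float32. World
coordinates follow RAS+ with 0-based voxel indices; on write only the
sform is set (it takes precedence on read). Degenerate inputs error
loudly rather than returning silent zeros: empty ROIs, all-invalid
subject rows (dropped with a warning), zero-anisotropy density masks,
displacement beyond the field of view, unreachable calibration anchors.
Distribution sampling truncates g to (0, 1] and radii to positive values
by resampling rejected draws, keeping population invariants intact.
Problem sizes used by the validation suite — 48³ voxels × 10 subjects for
cohort recovery, 1000 replicates for the null simulation, n = 37 for the
CoV sampling check — were chosen as the smallest sizes at which the
statistical assertions have comfortable power.

## Known limitations

* The fiber-density proxy is a stand-in: it shares only the scale-free
  contract of real fiber-density solvers, and real TFD maps should be
  supplied externally when available.
* No eddy-current/motion correction, denoising, or registration search:
  inputs are assumed co-registered up to the modelled phase-encode
  displacement.
* The MT↔MVF relation is treated as linear with an unknown scale; any
  tissue-dependent deviation propagates directly into g.
* Group analyses assume maps already share a common space; template
  construction is out of scope.
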