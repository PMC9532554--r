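---
title: "Progressive self-calibrating deformable registration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive self-calibrating deformable registration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(progreg)
```

## The registration problem

Deformable image registration (DIR) aligns the anatomy of a moving 3D volume
$M$ onto a fixed volume $F$ through a dense non-linear transformation. The
package assumes both volumes have already been globally (linearly)
pre-aligned, so what remains is the residual non-linear deformation — which
can still be large when the pre-alignment is imperfect. The transformation is
parameterized by a displacement vector field (DVF) $u$ giving, for every
voxel $x$, a displacement in voxel units; the deformation field is
$\phi(x) = x + u(x)$ and is never stored separately. Warping is *backward*:
$\mathrm{warped}(x) = M(x + u(x))$, evaluated with trilinear interpolation,
which is the sampling direction used by spatial-transformer resampling
layers.

An unsupervised network $G$ with parameters shared across all uses predicts
$u = G(M, F)$ and is trained by minimizing

$$\mathcal{L} = -\mathrm{LNCC}(M \circ \phi,\, F) \;+\; \lambda\,
\mathcal{S}(u),$$

where LNCC is local normalized cross-correlation and $\mathcal{S}$ is the
mean squared spatial gradient of the field. Because $\mathcal{S}$ penalizes
differences between neighbouring displacements, a single prediction cannot
represent large deformations well; the progressive strategy below decomposes
a large deformation into several small ones without paying the usual price
of cascaded approaches.

## Progressive registration with aggregate flows

At pass $k$ the shared-weight network registers the *previous pass's output*
to the fixed image, producing a new small field $u_k$. Rather than warping
the warped image again (a sequential cascade), the new field is composed onto
the running total with the aggregate-flow operator

$$u_{\mathrm{total}}(x) = u_k(x) + u_{\mathrm{prev}}(x + u_k(x)),$$

i.e. the earlier field is resampled at the positions displaced by the newer
one and added. One warp of the *primary* moving image with
$u_{\mathrm{total}}$ is then equivalent, up to interpolation error, to the
sequential cascade — but the output has been interpolated exactly once. This
matters because every trilinear resampling of an already-resampled image
low-pass filters it; after three or more passes of a conventional cascade,
structure boundaries visibly blur ("information loss"). The package tracks
this mechanically: every `volume` carries an interpolation depth, every
`registration_result` reports `interp_count`, and the invariant
`interp_count == 1` is asserted in the test suite for the progressive and
hierarchical paths (the provided `cascade_infer()` baseline deliberately
violates it, with depth equal to the pass count, for the sharpness
comparison).

Training is *self-calibrating*: the input of pass $k$ is the pass-$(k-1)$
result, so the network learns to correct its own residual error. Each pass
evaluates the objective on the once-warped primary image, with the
smoothness penalty applied only to the newest per-pass field $u_k$ — never
to the aggregate, which legitimately accumulates a large deformation.

### Update granularity

The per-pass objective is written as a loss of the $n$-th iteration, applied
after the network completes that iteration. Two readings are possible: one
optimizer update per pass, or one update after the full sweep of `n_train`
passes. Both are implemented (`update = "per_pass"` / `"sweep"` in
`train_config()`); per-pass is the default because it matches the
per-iteration formulation, keeps memory flat (earlier passes are detached
from the gradient), and we observed no benefit from the sweep variant on the
synthetic fixtures. Gradients never flow through previous passes: the
previous warped image and the running aggregate enter each pass as data. The
newest field still receives gradient through three routes — its additive
term, the resampling positions of the previous aggregate, and the sampling
positions of the warp itself — all of which are differentiated exactly
(verified against finite differences in the development tests).

### Pass indexing

`n_train` and `n_test` count *total* network passes, so `n = 1` is the
one-shot, non-progressive baseline. The counts are independent: a model
trained at one count may be evaluated at any other, which is what the grid
search sweeps.

## The shared-weight backbone

The flow predictor is a UNet operating on the 2-channel concatenation of
(moving, fixed), both jointly rescaled to $[0, 1]$ by one affine map so the
relative contrast between the pair is preserved across passes. The encoder
applies one 4×4×4 stride-2 convolution per resolution stage; the decoder
applies nearest-neighbour ×2 upsampling, concatenates the matching encoder
feature (the raw input at full resolution), and applies 3×3×3 stride-1
convolutions — two of them in each of the final two stages for finer
estimation of detail. Every convolution is followed by a LeakyReLU
(negative slope 0.2) except the final 3-channel head, which is linear and
initialized near zero (sd $10^{-5}$) so an untrained network starts at the
identity transform. Channel widths default to `enc = (16, 32, 32, 32)`,
`dec = (32, 32, 32, 16, 16)` with 4 levels — a VoxelMorph-family scale that
trains on a CPU at $32^3$–$64^3$ — and are configurable; the architecture
constraints (one stride-2 conv per encoder stage, doubled final decoder
stages, linear head) are fixed. Convolution arithmetic runs in single
precision through BLAS-backed im2col matrix products; everything else is
double precision.

## Hierarchical (two-scale) cascade

The full method trains two networks of identical structure. The low-scale
network sees 2× average-pooled pairs and handles the coarse, large
deformation quickly; its aggregate is upsampled trilinearly to the doubled
grid with displacements multiplied by 2 (the voxel-unit rescaling that makes
a coarse-voxel displacement mean the same physical shift on the fine grid)
and becomes the *initial value* of the original-scale chain. The upsampled
field is part of the total aggregate, so the single-interpolation guarantee
survives the cascade. Training is sequential: phase 1 trains the low scale;
phase 2 freezes it and trains the original scale with every step initialized
by the frozen coarse output. Flow upsampling uses cell-centered resampling
(fine voxel $i$ maps to coarse coordinate $(i + 0.5)/2 - 0.5$), which is
exact for constant fields and consistent with average-pool downsampling;
boundary voxels are clamp-extrapolated.

At full working resolution the grid-searched optima are 5 training / 3 test
passes for the low scale and 9 / 2 for the original scale; those are the
defaults of `hierarchical_infer()`. The desk-scale studies below use 3/3 and
3/2 — the same qualitative regime (several passes, fewer test passes at the
fine scale) at a size where a full study runs in minutes on one CPU core.

## Losses and numerical choices

**LNCC.** At every voxel a cubic window (truncated at the borders, so window
membership is symmetric and the operator is self-adjoint) contributes the
signed normalized cross-correlation
$\mathrm{cc} = \mathrm{cov}/\sqrt{(\sigma_a^2 + \varepsilon)(\sigma_b^2 +
\varepsilon)}$ with guard $\varepsilon = 10^{-5}$; the score is the mean over
windows. The signed (not squared) form is used; it is bounded in $[-1, 1]$
and invariant to positive affine intensity maps wherever local variance
dominates $\varepsilon$. The window is 9 voxels at full working resolution
and 5 for $\le 32^3$ fixtures (a 9-window at $32^3$ spans more than a
quarter of the volume and washes out locality).

**Smoothness.** Sum of squared forward differences of the field over voxels,
components, and axes, divided by the number of summed terms. The mean (not
raw-sum) normalization makes $\lambda$ comparable across resolutions; the
printed form of the penalty is a sum, so our $\lambda$ is not numerically
interchangeable with a sum-normalized one. $\lambda = 1$ is the desk-scale
default, chosen once for the synthetic fixtures (the full-scale tuned values
are not published).

**Out-of-bounds policy.** All samplers clamp coordinates to the volume
(clamp-to-edge). This avoids injecting zeros into composed flows near
boundaries, at the cost of a flat extrapolation; composition and sequential
warping therefore disagree within ~2 voxels of the border, and the
equivalence tests exclude that margin. Nearest-neighbour label warping
rounds with `floor(x + 0.5)` (ties toward the larger index).

**Optimization.** Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), batch 1,
learning rate $10^{-4}$ at the full 30,000-step scale; the desk-scale runs
use $10^{-3}$ for 150–300 steps, a choice made once so that convergence is
visible within the fixture budget. Divergence (a non-finite objective)
raises a classed error carrying the pass index.

## Synthetic study conditions

The generator emulates the setting the method targets — pre-aligned
same-modality brain volumes with labeled anatomical structures and residual
non-linear deformation — without any external data:

* **Phantom**: one outer ellipsoidal "brain" (semi-axes 0.42 of each extent,
  tissue intensity 80 on a 0–255 scale) containing `n_structures = 4`
  non-overlapping ellipsoidal structures (semi-axes 5.5–11% of the smallest
  extent, distinct labels, intensities evenly spread over 130–245), then
  Gaussian-blurred with $\sigma = 1$ voxel. Default grid $32^3$.
* **Deformation**: white noise smoothed with a Gaussian ($\sigma = 3$ for
  the presets), generated on an extended grid and cropped so the field is
  stationary, then rescaled so the maximum displacement norm equals the
  requested amplitude.
* **Severity** is calibrated, not hard-coded: the amplitude is bisected
  until the initial Dice of the smallest structure falls in a target band.
  The "large" preset targets (0.30, 0.55), safely below the 0.6 overlap
  criterion for small structures that separates large from small
  deformations; "small" targets (0.70, 0.90).
* **Cohort**: all pairs share one fixed template (as in atlas-based
  pipelines); each moving image is the template warped by an independent
  field at the calibrated amplitude. The desk study uses 12 pairs — 8 for
  training, 4 held out — with everything a pure function of one seed.

What passing on these fixtures does **not** show: robustness to intensity
non-stationarity between subjects, to anatomy that is not a deformation of
the template (topology change), to multi-modal contrast, or to anisotropic
voxels. The phantoms are textureless inside structures, so registration is
driven almost entirely by boundary contrast — harder than textured real
data in one respect (no interior guidance), easier in another (no noise).

## Desk-scale experiment sizes

The bundled studies (test suite and `scripts/acceptance.R`) run at $32^3$
with the low scale at $16^3$: 150 steps per scale with 3 training passes,
LNCC window 5, $\lambda = 1$, Adam $10^{-3}$. The pass-count grid search
sweeps `n_train` ∈ {1, 3, 5} × `n_test` ∈ {1, 2, 3} at the low scale with 50
steps per cell — a scaled-down analogue of the 1–11 × 1–5 full-resolution
sweep. These sizes were chosen so the whole study retrains from scratch in
minutes on a single core while still showing the phenomena of interest:
recovery of large deformations, monotone benefit of progressive passes, and
the sharpness gap between single-warp aggregation and sequential cascading.

## Known limitations

* No diffeomorphism guarantee: composed fields may fold; only the smoothness
  penalty discourages it (no inverse-consistency or anti-folding terms, no
  velocity-field parameterization).
* Registration operates in voxel space; physical-space (mm) registration,
  oblique affines, and anisotropy-aware smoothing are out of scope.
* Exactly two scales; the low-scale flow is always aggregated into the
  total, which is required for the single-interpolation guarantee.
* Mono-modal similarity only (LNCC); multi-modal registration would need a
  different similarity term.
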