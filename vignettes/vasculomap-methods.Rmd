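---
title: "Methods: white-matter vasculature mapping with vasculomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: white-matter vasculature mapping with vasculomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculomap)
```

## The measurement model

An ultrasmall iron-oxide contrast agent confined to the blood pool raises
blood R2\* in proportion to local vascular volume. With a mono-exponential
signal model per voxel,

$$S(TE) = S_0 \, e^{-R_2^* \cdot TE},$$

the pre/post difference $\Delta R_2^* = R_{2,\mathrm{post}}^* -
R_{2,\mathrm{pre}}^*$ (1/s) is the vascular-volume proxy used throughout.
TE is millisecond at every interface (the protocol convention: ten
equidistant echoes, 3.4–25.0 ms, interval 2.4 ms by default) and is
converted to seconds internally, so rates are always 1/s — this single
convention prevents the most common unit bug in relaxometry code. Negative
$\Delta R_2^*$ values are retained, never clipped: downstream parcel
medians are robust to them, while clipping would bias every parcel
statistic upward.

Two estimators are provided. The log-linear estimator is OLS on
$\log S$; it is exact on noise-free data and fast. The `nls` estimator is
a vectorized Levenberg–Marquardt refinement initialized from the
log-linear solution; the log transform skews noise at late echoes, so the
nonlinear estimator has smaller bias at low SNR (the test suite verifies
this on a 10^4-voxel Monte-Carlo at SNR 50). Voxels with fewer than three
positive-signal echoes are flagged invalid rather than raising an error.

## Laminar geometry

Cortical analyses are performed on surfaces. Between corresponding white
and pial meshes, the equivolumetric rule places the boundary enclosing
cumulative volume fraction $\alpha$ at relative depth

$$r(\alpha) = \frac{-A_w + \sqrt{\alpha A_p^2 + (1 - \alpha) A_w^2}}{A_p - A_w},$$

with $A_w, A_p$ the local white/pial vertex areas and the equidistant
limit $r = \alpha$ when they agree. This follows the standard equivolume
construction, which models the column cross-section as linearly
interpolating $A_w \to A_p$ with depth; the oracle tests integrate exactly
that area profile. It is an external convention, not a result of this
package. Twelve layers are named EL1a…EL6b from pial to white, echoing
anatomical laminae. Non-positive areas (mesh rim, degenerate vertices)
fall back to equidistant spacing with a warning.

The superficial white matter is sampled on a surface displaced 0.32 mm
inward along the white-surface normal; flipped faces after displacement
are detected and counted, not repaired.

Ribbon-constrained volume-to-surface mapping averages voxel values inside
the wedge between corresponding inner/outer vertex positions, weighting
each voxel by fractional wedge occupancy estimated from $2^3$ sub-voxel
corner points. The wedge is modelled as the capsule around the
inner-to-outer segment with radius $\sqrt{A/\pi}$ from the vertex area —
the spec-level notion of "patch" made concrete; empty or degenerate wedges
fall back to the nearest voxel and are flagged. Surface gradients are the
per-triangle linear-interpolant gradients (tangent-plane vectors),
area-averaged onto vertices; penetrating vessels appear as compact rings
("circular" gradients), tangential vessels as elongated ridges.

## B0 orientation bias

Gradient-echo relaxation depends on the angle between tubular structure
and the static field; the package models the dependence empirically as a
$\cos^2\theta$ term. Estimation regresses $\Delta R_2^*$ on
$\cos^2\theta_{\mathrm{normal},B_0}$; a negative slope is *read* as
vessels predominantly perpendicular to the cortical surface and a positive
slope as parallel. That is a documented sign convention, not asserted
physics: static-dephasing theory for extravascular spins around cylinders
predicts maximal $\Delta R_2^*$ perpendicular to B0, so the phantom
generator exposes the modulation as a signed free parameter
(`angular_modulation`, default −0.5) rather than hard-coding either sign.

Correction subtracts the fitted component mean-free,
$y - \hat\beta(\cos^2\theta - \overline{\cos^2\theta})$: the global mean
is preserved exactly, the corrected metric is exactly uncorrelated with
$\cos^2\theta$ (OLS orthogonality), and the operation is idempotent.
Whether the original analysis removed the term per layer, per hemisphere,
or jointly is not stated in the source methods; this package residualizes
globally over whatever vertex set is passed and is applied **per layer**
in the pipeline — the choice is visible in the configuration, not buried.

## Frangi vesselness

Second derivatives are computed by separable convolution with sampled
Gaussian-derivative kernels (reflect padding, so edge behavior is
reproducible), scale-normalized by $\sigma^2$; the second-derivative
kernel's residual DC component is removed so constant volumes map exactly
to zero. Eigenvalues ($|\lambda_1| \le |\lambda_2| \le |\lambda_3|$) give

$$V = \left(1 - e^{-R_A^2/2\alpha^2}\right) e^{-R_B^2/2\beta^2}
      \left(1 - e^{-S^2/2\gamma^2}\right),$$

zeroed where the tube-polarity condition fails; dark tubes (the
post-contrast appearance) are handled by negating the volume. The
structureness cutoff $\gamma$ defaults to half the maximum Frobenius norm
per scale — the common convention, chosen because the original analysis
names the filter but no constants; the value actually used is logged in
the output metadata. The final response is the per-voxel maximum over
scales with the argmax scale recorded.

A resolution caveat the tests make explicit: cylinders with radius at or
below one voxel produce a diffuse, weak response, and no Hessian filter
can recover their volume accurately. Volume-recovery tests therefore run
in the resolvable regime (radius ≈ 1.5 voxels); with the
ground-truth-Youden threshold the recovered volume is within 25% there.

## Tract profiles

Streamlines are resampled to 20 equidistant nodes by arc length
(endpoints preserved). Outlier cleaning scores each streamline by its
node-averaged normalized Euclidean deviation from the per-node mean
position (node scale = coordinate-averaged positional SD) and removes
scores above 3 SD, iterating once — a scalar simplification of the
per-node Gaussian model of automated fiber-tract quantification (AFQ).
Bundles keeping fewer than six streamlines are flagged invalid. Profiles
take the per-node **median** across streamlines (robust to streamlines
clipping a macrovessel), with trilinear volume sampling and a flagged
nearest-voxel fallback outside the grid.

Relative distance runs from 0% at the white-surface end to 100% where the
streamline crosses the midsagittal plane, interpolating by arc length —
arc length (not Euclidean distance) is a deliberate convention, flagged
here because the source methods do not state it. Non-crossing streamlines
are excluded from the calibration and flagged.

## Depth models and model comparison

The depth-model family is $y = -a\,e^{-b d} + c$ with $d$ in percent, so
rates print on the familiar per-percent scale. Internally the signed-$a$
convention is kept; the reporting layer prints the positive-amplitude
display form $A e^{-bd} + c$, $A = -a$, to avoid sign confusion between
the formula and the printed curves (decaying metrics print positive
amplitudes; growing ones, like neurite density with depth, print negative
amplitudes). Fitting is by variable projection: for each candidate rate
$b$ the amplitude and offset are the exact linear solution, and the
profiled RSS is minimized over $b$ on a multi-start grid (including
0.005–0.1 per %) followed by golden-section refinement — exact on
noise-free data, and strictly more robust for this family than generic
multi-start descent. Constant data leave the rate unidentifiable; the fit
is flagged and returns the constant.

Alternatives: linear and quadratic closed-form least squares, and a
3-parameter logistic $L/(1 + e^{-r(d - d_0)})$ with **no separate
offset**, so all non-linear families carry equal complexity ($k = 3$).
Consequence (documented, intentional): the offset-free logistic cannot
absorb an additive shift of $y$, so criterion-ordering shift-invariance
holds among the offset-bearing families only.

Comparison uses Gaussian-likelihood criteria with the noise variance
counted, $k' = k + 1$. A known small-sample fact quantified by the
acceptance suite: on linear-generated 21-node data, plain BIC/AICc
selection overfits with irreducible probability ≈ 12% (quadratic alone
wins with probability $P(\chi^2_1 > \ln 21) = 8.1\%$), so "linear wins
over all four families" plateaus near 88% — while "linear preferred over
the exponential" exceeds 90%. The acceptance test asserts the stricter
bound and is honestly red there; the diagnostic output prints both rates.

## Stepwise vascular model and cross-validation

The prediction model for node-wise $\Delta R_2^*$ treats NDI and ODI as
linear terms and relative distance through $A e^{-r d}$ with no separate
offset (the model intercept plays that role). Forward selection starts
from intercept-only, refits every candidate model in full at each step
(the exponential rate is re-optimized every time, not frozen at first
inclusion), adds the largest BIC decrease, and stops when no candidate
decreases BIC; ties break by the fixed candidate order (ndi, odi,
exp-distance) and are logged. Leave-one-bundle-out CV refits the selected
*form* per fold and pools held-out predictions into a single Pearson r.

A statistical property the null-simulation tests surfaced: under a null
response the cross-validated correlation is *negatively biased* (refit
coefficients anti-correlate with held-out noise; mean pooled r ≈ −0.09 at
6 bundles × 21 nodes, persisting with more bundles). The meaningful null
guarantee is therefore one-sided — essentially never does the null
produce positive skill beyond $2/\sqrt{N}$ — and that is what the test
asserts.

## The synthetic world: what it emulates, what it does not

`make_cortical_phantom()` builds a single sinusoidal gyrus (analytic
normals, enough folding to spread $\cos^2\theta$ across vertices), a
white/pial mesh pair in vertex correspondence, and two vessel
populations: radial cylinders along the local normal spanning the cortex,
and tangential vessels following the superficial-white-matter sheet.
Ground-truth $\Delta R_2^*$ is *imposed*, not simulated from field
perturbations:

$$\Delta R_2^{*,\mathrm{true}} = k_{vvf} \cdot \mathrm{vvf} \cdot
  (1 + m \cos^2\theta_{\mathrm{vessel},B_0}),$$

with vvf the sub-voxel-sampled vessel volume fraction and $m$ the signed
angular modulation. Echo stacks follow the mono-exponential model with
additive Gaussian noise on magnitude (the Rician regime is ignored at the
SNRs used — a documented simplification). Vessel seeds are Poisson-disk
sampled, mirroring the minimum-spacing character of penetrating vessels
without modelling real angioarchitecture. All randomness flows from one
integer seed per call; no global RNG state is touched or disturbed.

Default parameter choices, with reasoning:

* `voxel_size_mm = 0.23`, ten echoes 3.4–25.0 ms — the high-resolution
  vessel-imaging protocol scale.
* `tissue_r2star_pre` = 30/25/20 1/s (GM/SWM/deep WM) — typical
  high-field baseline rates; `delta_r2star_per_vvf = 40` 1/s puts
  fully-occupied voxels at a plausible post-contrast increment.
* `vessel_radius_mm = 0.25` — at the resolution limit, deliberately:
  these are the smallest macrovessels the protocol claims to see.
* `vessel_density_gm = 0.5`, `vessel_density_swm = 0.15` per mm² —
  chosen so vessel-touched voxels are ~10–15% of tissue, the range
  reported for Frangi masks of real white matter. Two regimes are used in
  tests: this sparse macrovessel regime for vesselness work, and a dense
  regime (3 and 0.6 per mm²) for orientation-bias statistics, where power
  comes from many vessels and tube resolvability is irrelevant.
* `angular_modulation = −0.5` — with radial GM vessels and tangential SWM
  vessels on the folded sheet this reproduces the observed sign pattern
  (GM slope negative, SWM positive) by construction.
* Bundle metrics default to the three group-level depth models
  ($\Delta R_2^*$: $11.64 e^{-0.05 d} + 19.13$; ODI:
  $0.30 e^{-0.02 d} + 0.07$; NDI: $-0.32 e^{-0.01 d} + 0.87$) with node
  noise 0.5 (1/s) and 0.02 (unitless); bundle scatter is independent
  node-level jitter projected transverse to the bundle trunk. Both parts
  of that choice matter for outlier cleaning: a correlated
  whole-streamline offset defeats the node-averaged 3-SD score directly,
  and isotropic jitter perturbs each streamline's arc length, which
  equidistant resampling converts back into a coherent along-trunk shift
  of a few SD for tail streamlines. Transverse jitter removes the effect
  to first order; the residual quadratic effect shrinks with the jitter
  scale, so "coherent bundle" tests use tight scatter (0.1 mm).
* Outlier planting displaces by a random direction with **fixed**
  magnitude $\sqrt{3} \times$ `outlier_displacement_sd` (the RMS norm of
  the corresponding Gaussian), so "planted at 10×SD" is deterministic in
  size and 100%-sensitivity claims are well-posed.
* Parcel tables: Gaussian copula at n = 103 areas with target
  correlations r(ΔR2\*, receptor) = 0.50, r(ΔR2\*, myelin) = 0.32,
  r(ΔR2\*, neuron) = 0.10 — the reported cross-area relationship
  magnitudes — rescaled to plausible means/SDs.

What a green test does **not** establish: the phantom has no real
angioarchitecture, no arterial/venous distinction, no susceptibility
forward model, no Rician noise floor, no registration or segmentation
error, and its bundles carry metrics directly at nodes rather than
through a diffusion model. Green means the *computational chain* is
correct against a world whose truth is known — not that the biological
effect sizes would replicate.

## Numerical choices and degenerate inputs

* Bootstrap tests resample pairs; two-tailed
  $p = 2\min(P(r^* \le 0), P(r^* \ge 0))$, clipped to $[2/n_{boot}, 1]$
  (percentile form), bit-reproducible given (seed, n_boot). At
  $n_{boot} = 1000$ the Monte-Carlo granularity of the min inflates null
  rejections to ~7%; at 5000 the intrinsic calibration (~5.6%) is
  revealed — acceptance runs at 5000.
* Zero-variance inputs: correlation and bias fits flag `undefined`
  instead of erroring; correction then returns its input unchanged.
* Exponential rates are searched on $b \in [10^{-4}, 1]$ per %;
  collinear bases (rate ≈ 0) are detected by reciprocal condition number
  and collapse to the offset-only fit.
* All volumes share an axis-aligned scanner-mm frame (isotropic voxels,
  0-based world origin at the first voxel centre); surfaces live in the
  same frame, so no affine bookkeeping is needed in the synthetic world.
* On-disk formats are plain text (CSV/JSON): the execution environment
  provides no NIfTI/GIFTI/TCK reader, and hand-rolling binary parsers was
  out of scope. Volumes and meshes are first-class in-memory objects; the
  high-density "656k mesh" upsampling of surface pipelines is replaced by
  a generic `mesh_subdivide()`.

## Known limitations

* No multi-compartment or complex-valued R2\* models; no B0/B1 field-map
  corrections (upstream concerns).
* No tractography, FOD estimation or SIFT; synthetic bundles substitute.
* No centerline extraction or artery/vein classification.
* No spatial-autocorrelation-aware null models for parcel correlations.
* The paper-scale real-data statistics (e.g. prediction r = 0.79 on
  macaque data, vessel volumes of thousands of mm³) require the original
  scans; this package validates the machinery on synthetic ground truth
  and reproduces sign patterns and parameter-recovery claims only.
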