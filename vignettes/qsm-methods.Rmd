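---
title: "Quantitative susceptibility mapping with qsmr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative susceptibility mapping with qsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qsmr)
```

# The problem

Tissue iron, myelin and calcium perturb the static field of an MR scanner
in proportion to their magnetic susceptibility, and the perturbation is
read out as the phase of a gradient-recalled-echo (GRE) acquisition.
Quantitative susceptibility mapping (QSM) inverts that relationship: from
a single-echo magnitude + wrapped-phase volume it reconstructs a map of
tissue susceptibility chi in parts per million (ppm), suitable for
regional group comparisons — for example between patients with a
neurodegenerative condition and matched controls, where iron accumulation
in deep grey nuclei such as the putamen is the expected signal.

`qsmr` implements the full processing chain as a library plus a thin CLI:

1. **Phase unwrapping** (Laplacian-based),
2. **Background-field removal** by projection onto dipole fields (PDF),
   with SWI-style homodyne filtering as a comparison arm,
3. **Regularised dipole inversion** (L2 Tikhonov-like, or L1/MEDI-style),
4. **Reference normalisation** and **regional nonparametric statistics**
   (exact Wilcoxon rank-sum).

Because no MRI data ship with the package, a synthetic phantom module
generates brain-like susceptibility scenes with analytic magnetostatic
oracles, and every stage is validated against those oracles.

# Forward model

A susceptibility distribution chi(r) (ppm) induces a fractional field
shift whose Fourier representation is a pointwise multiplication with the
unit dipole kernel

    D(k) = 1/3 - (k . b0)^2 / |k|^2,

under the Lorentz-sphere convention (a uniform sphere shows zero internal
shift). The phase accrued at echo time `te` is
`phi = phase_sign * gamma * B0 * dB * te`, with `gamma` the proton
gyromagnetic ratio; defaults emulate a 3 T acquisition with te = 20 ms,
where 0.1 ppm corresponds to about 1.6 rad.

Numerical choices:

* **DC bin.** D is singular at k = 0: the global field offset — hence
  absolute susceptibility — is unobservable. We impose D(0) = 0, making
  every reconstruction *relative*; downstream, maps are re-baselined to a
  reference region at 0 ppm. This is why `SusceptibilityMap` values only
  mean anything relative to the named reference.
* **Padding.** Phantom forward simulation zero-pads to twice the grid so
  the circular convolution cannot wrap dipole tails back into the field
  of view; the solvers operate on the unpadded acquisition grid, exactly
  as they must on real data (one cannot pad a measurement). The PDF stage
  also runs on the unpadded grid: padding would quadruple every FFT for
  no benefit when the modelled sources lie inside the FOV.
* **Discrete operators.** The Laplacian is applied spectrally as the
  eigenvalues of the 7-point finite-difference stencil (not the continuum
  -|k|^2), which makes `inverse_laplacian(fourier_laplacian(v))` exact off
  the DC mode — a property the unwrapping tests rely on. Gradients are
  forward differences with replicate boundary, and `divergence()` is
  defined as the exact negative adjoint, so the solvers' gradients are
  exact to machine precision.
* **Voxelwise impulse response.** The k-space-sampled kernel's response
  to a *single voxel* deviates from the continuum point-dipole formula
  (a known property of discrete dipole kernels; the low-|k| bins sample
  the kernel's directional discontinuity too crudely). Any *extended*
  source reproduces the analytic solution: a 10 mm sphere on a 64-cube
  matches the Lorentz-sphere oracle to < 0.1% RMS away from the
  interface. Validation therefore always uses compact extended sources.

# The synthetic phantom

`default_phantom_spec()` emulates a 64 mm field of view containing a
0.42-FOV spherical "brain" with:

* a **putamen analogue** (6.9 mm sphere, chi = 0.10 ppm) with *no*
  magnitude contrast — its chi boundary is invisible to the edge mask, as
  for iron-rich nuclei with weak T2* magnitude contrast, so it exhibits
  the classic attenuation-versus-lambda behaviour;
* a **pallidum analogue** (5.6 mm sphere, chi = 0.15 ppm) that is
  magnitude-dark (0.75), hence edge-protected and tightly recovered;
* a **reference cylinder** at 0 ppm (CSF-like, magnitude 1.3) standing in
  for the posterior ventricular reference region;
* an **extra-cerebral source** (chi = 2 ppm) just outside the brain,
  standing in for air/tissue interfaces after shimming — it dominates the
  measured field near the inferior brain, as real background fields do;
* a multiplicative low-order polynomial **bias field** (ground truth
  retained, so bias correction is exact division — N4-style estimation is
  out of scope), a smooth deterministic magnitude **texture** (so
  gradient quantiles are continuous), and **complex Gaussian noise**
  whose phase SD scales as noise/magnitude — the premise of the
  weighting matrix.

Deep-nuclei analogues are deliberately *small relative to the brain
radius*. The far tail of a source of radius `a` inside a brain of radius
`b` overlaps the space of interior harmonics — what exterior dipole
fitting can absorb — by roughly `2.3 (a/b)^1.5`; keeping `a/b ~ 0.15`,
as for real deep nuclei, is what makes background removal well posed.
Conversely, what the phantom does **not** emulate: realistic cortical
anatomy, veins and flow effects, coil sensitivity, motion, or unwrap
failures at very steep (> pi/voxel) phase gradients. Passing tests show
the chain is self-consistent under its stated physics, not that it is
robust to every in vivo artefact.

A cohort layer (`make_cohort`, `cohort_truth_stats`) adds per-region
between-subject jitter (SD 0.005 ppm) and an optional group-B offset in
named regions (0.05 ppm in the putamen analogue for power studies,
matching the scale of reported disease effects), with 8 vs 8 subjects by
default.

# Phase unwrapping

MRI phase is only known modulo 2 pi. We use the Laplacian identity

    lap(phi) = cos(phi) lap(sin(phi)) - sin(phi) lap(cos(phi)),

whose right-hand side is invariant under wraps, followed by the inverse
Laplacian. With the spectral stencil pair the round trip is exact off the
DC mode, so the estimate is zero-mean; the inverse also annihilates
harmonic components, which removes part of the background field along
with the offset. The identity is exact only while neighbouring-voxel
phase differences stay below pi — beyond that (immediately adjacent to
very strong sources) the unwrap degrades gracefully into a smooth,
largely harmonic error that the subsequent PDF stage absorbs.
Unwrapping runs on the full rectangular volume (it is a global spectral
identity); masking happens downstream. Only single-echo data are
supported, matching the single-te protocol the pipeline models.

# Background removal: PDF

The measured field is total = background + local, with background
contributions from outside the brain that are orders of magnitude
stronger than tissue fields. PDF fits an exobrain dipole distribution
`chi_ext` minimising

    || W o (b_meas - D (Mc o chi_ext)) ||_2

where `Mc` is the brain-mask complement and W the magnitude weighting
(zero outside the brain). Implementation decisions:

* **CGLS.** We solve the normal equations by conjugate gradient with the
  adjoint applied explicitly (the operator is self-adjoint since D is
  real and even). CGLS guarantees a monotone non-increasing least-squares
  residual history; the stopping rule is applied to the *normal-equation*
  residual norm falling below `rel_tol` (default 1e-3, "a thousandth") of
  its value at `chi_ext = 0`. On the standard external-source phantom
  this terminates in a few hundred iterations; non-convergence within
  `max_iter` returns a flagged result, never a silent success.
* **Source support.** Exobrain sources live in the complement of the
  *full anatomical* brain mask, while W lives on the 6-voxel-eroded mask.
  Letting sources occupy the eroded shell (3 voxels inside the true
  boundary) lets them hug the tissue and absorb interior dipole tails;
  keeping them outside the anatomical boundary preserves the
  interior/exterior field orthogonality PDF relies on.
* **Semi-convergence is the safety net.** The exobrain space has far more
  degrees of freedom than the brain has voxels, so an exact interior fit
  exists in the limit; CG reaches the smooth, genuinely-exterior
  components first and stagnates on the rest, and the residual-based
  stopping rule halts it there.

The homodyne (Hanning-window) high-pass filter is provided purely as the
comparison arm: it crushes smooth background phase (> 99% energy removal
for low-order polynomials) but also attenuates local dipole patterns that
PDF preserves — the package's tests assert exactly that ordering.

# Dipole inversion

The estimator minimises

    E(chi) = lambda * || W o (D chi - dB) ||_2^2  +  || M_G o grad chi ||_p

with p = 2 (squared norm) or p = 1 (MEDI-style, smoothed as
`sqrt(g^2 + eps)`, eps = 1e-6). Note the parameterisation: **lambda
multiplies the data-fidelity term**, so lambda = 200 is heavy
regularisation and lambda = 1e4 effectively unregularised. The edge mask
M_G (the 30% highest magnitude-gradient voxels excluded) confines the
regulariser only — susceptibility boundaries coincide with magnitude
edges, where the gradient penalty would otherwise smooth real structure.
The solution support is confined to the brain mask; the exterior is
pinned at zero rather than left to float as an implicit extra
background-fitting layer.

The minimiser is Polak–Ribière nonlinear conjugate gradient with a
backtracking line search (shrink 0.5, Armijo constant 1e-4); the initial
step is the exact quadratic line minimiser (p = 2) or a majoriser
curvature estimate (p = 1), so backtracking rarely triggers and the cost
history is non-increasing by construction. Iterations stop when the cost
decrease falls below `rel_stop` times the data-fidelity term after the
first iteration.

**Choice of `rel_stop`.** The natural-looking default of 1e-2 stops the
solver after ~8 iterations and attenuates the lambda = 1250 L2 solution
by ~17% even on a perfect noiseless local field — inconsistent with the
behaviour the stopping rule is meant to reproduce (essentially
unattenuated solutions at the optimal lambda). The default is therefore
`rel_stop = 1e-4` (~30 iterations at 64^3), at which the 0.10 ppm sphere
benchmark is recovered to ~1% by the inversion alone and ~5% end-to-end.
Neither the fidelity nor the regulariser term is normalised by voxel
count; lambda values therefore transfer across grid sizes only
approximately.

**The fidelity-versus-lambda curve.** `lambda_sweep()` tabulates the
fidelity residual and region medians over the standard ten-value grid
(200 ... 1e4). With a stable, convergent solver this curve is *monotone
non-increasing* in lambda — necessarily so for exact minimisers (envelope
argument), and empirically also for stopped iterates of this
implementation at every tolerance we tested. A concave curve with an
interior minimum, sometimes taken as the signature of the optimally
constrained reconstruction, can only arise from solver non-convergence or
instability at scale (severe streaking in strongly under-regularised
runs); this implementation does not reproduce it, and the package
documents the monotone behaviour as the correct desk-scale result. The
attenuation diagnostic (`attenuation_curve()`) behaves as expected:
median susceptibility in an edge-unprotected region is non-decreasing in
lambda, with heavy attenuation below lambda ~ 500.

**L1 vs L2.** The smoothed-l1 penalty (chosen over IRLS because it drops
straight into the same CG + line-search scheme) promotes gradient
sparsity: at matched region medians (via `calibrate_matching_lambda()`,
which refuses to extrapolate outside the swept range and breaks ties
toward the smaller lambda) the L1 solution's total variation never
exceeds the L2 solution's.

# Weights, masks, reference

* `compute_weight_map()`: W = brain-masked magnitude / mean over the
  reference region (exact unit mean there, by one double-precision
  division). Phase noise SD is proportional to 1/magnitude, so this is
  inverse-variance weighting up to a global scale, to which the solvers
  are invariant.
* `compute_edge_mask()`: the per-voxel score is the l1 sum of absolute
  forward differences ("sum of gradients" read literally; the vector
  magnitude alternative differs immaterially at this fraction). The
  threshold is the (1 - 0.30) within-brain quantile with strict
  inequality, so a uniform magnitude yields 0% edges rather than an
  arbitrary 30%.
* `erode_mask()`: 6x6x6 cubic kernel, full-support convolution; for even
  widths the cube is offset by half a voxel (offsets -2..3).
* `reference_normalize()`: subtracts the reference-region *mean* (median
  available via an argument); mean is the default for linearity — the
  normalised map is an exact global shift, preserving every voxel
  difference.

# Regional statistics

Per-region summaries are medians (regional distributions are skewed);
histograms use fixed 0.005 ppm bins over [-0.3, 0.3] ppm so they are
comparable across subjects. Group comparison uses the two-tailed
Wilcoxon rank-sum test computed by *full enumeration* of all
choose(n1+n2, n1) assignments when n1 + n2 <= 20 — 12,870 assignments for
the 8 vs 8 design, making the test exhaustive rather than sampled — with
mid-ranks for ties; larger samples use the tie-corrected normal
approximation with continuity correction. Significance is tiered at
P < 0.05 (lenient) and P < 0.005 (the Bonferroni per-test level for a
family alpha of 0.05 over 10 regional tests). Under the null the exact
8 vs 8 test attains a rejection rate of 4.99% at the 0.05 level, which
the type-I simulation (200 null cohorts) reproduces; a 0.05 ppm
single-region effect with 0.005 ppm between-subject SD is detected at
P < 0.005 essentially always (the groups separate completely, giving the
extreme P = 2/12870).

Statistical simulations run on cohort *truths* (region medians from the
generated susceptibility maps, 32^3 grids) rather than through thousands
of full reconstructions; the reconstruction chain's accuracy is
established separately by the recovery benchmarks, and the statistics
layer only consumes per-subject medians.

# Pipeline, I/O, reproducibility

`run_pipeline()` chains unwrap, field conversion, mask conditioning, PDF,
subtraction, inversion (per lambda and norm), normalisation and regional
statistics, recording per-stage iteration counts and residuals in a
manifest (written atomically as JSON). Runs are deterministic given the
config seed; volumes are float32 on disk (NIfTI-1, voxel sizes in the
header) and double precision in memory. Problem sizes used by the
package's own validation: 64^3 for oracle and recovery benchmarks, 32^3
for regularisation diagnostics and cohort statistics — chosen as the
smallest grids on which the interfaces of interest span several voxels.

# Known limitations

* Single echo, single orientation; no multi-echo fitting, no COSMOS.
* No skull stripping or bias-field *estimation* — masks are inputs, and
  phantom bias is divided out with known truth.
* The voxelwise discrete-kernel impulse response differs from the
  continuum dipole (see above); single-voxel sources are not a valid use
  of the forward model.
* Streaking-prone, strongly under-regularised settings (lambda >> 3250)
  terminate by stagnation rather than reproducing clinical-scale
  streaking morphology.
* Anisotropic voxels are supported throughout but validated only lightly;
  anisotropic/tensor susceptibility models are out of scope.
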