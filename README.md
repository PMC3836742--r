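# qsmr — quantitative susceptibility mapping from gradient-echo phase

Tissue iron, myelin and calcifications shift the local magnetic field of
an MR scanner in proportion to their magnetic susceptibility, and that
shift is encoded in the phase of a gradient-recalled-echo (GRE)
acquisition. **Quantitative susceptibility mapping (QSM)** inverts this
relationship to produce voxelwise maps of tissue susceptibility χ (in
ppm, relative to a reference region), enabling regional group
comparisons — e.g. iron accumulation in deep grey nuclei such as the
putamen in neurodegenerative disease.

`qsmr` implements the complete single-echo QSM chain for researchers who
want a transparent, fully tested reference implementation in R:

1. **Laplacian phase unwrapping** — via the wrap-invariant identity
   ∇²φ = cos φ · ∇²sin φ − sin φ · ∇²cos φ, inverted spectrally;
2. **Background-field removal by projection onto dipole fields (PDF)** —
   conjugate-gradient fitting of extra-cerebral dipole sources
   ‖W ∘ (b − D(M_c ∘ χ_ext))‖₂ → min, stopping when the CG residual
   falls below 10⁻³ of its starting value (SWI-style Hanning homodyne
   filtering is included as the comparison arm);
3. **Regularised dipole inversion** — minimising
   E(χ) = λ‖W ∘ (Dχ − δB)‖₂² + ‖M_G ∘ ∇χ‖_p with the Fourier dipole
   kernel D(k) = 1/3 − (k·B̂₀)²/|k|², noise weighting W (magnitude-
   proportional, unit mean over the reference region), edge-exclusion
   mask M_G (top 30% magnitude gradients), p = 2 (Tikhonov-like) or
   p = 1 (MEDI-style), solved by nonlinear conjugate gradient with
   backtracking line search;
4. **Reference normalisation** — maps are relative (the kernel's k = 0
   singularity leaves the offset undetermined) and baselined at 0 ppm
   over a ventricular-like reference region;
5. **Regional statistics** — per-region medians, exact two-tailed
   Wilcoxon rank-sum tests by full enumeration (12,870 assignments for
   the 8-vs-8 design), significance tiers at P < 0.05 and P < 0.005
   (Bonferroni 0.05/10).

No MRI data ship with the package: a synthetic phantom module generates
brain-like susceptibility scenes (deep-nuclei compartments, an
extra-cerebral background source, bias field, complex noise) with
analytic Lorentz-sphere oracles, and every stage is validated against
them. See the methods vignette (`vignettes/qsm-methods.Rmd`) for the
models, parameter choices and known limitations.

## Worked example

Reconstruct a 64³ synthetic phantom (3 T, te = 20 ms; 0.10 ppm
putamen-like and 0.15 ppm pallidum-like spheres, 2 ppm extra-cerebral
source, 0 ppm reference cylinder):

```r
library(qsmr)

spec <- default_phantom_spec(n = 64, noise_sigma = 0, seed = 11)
ph   <- make_susceptibility_phantom(spec)
acq  <- acquisition_params()                      # 3 T, te = 20 ms
sim  <- simulate_acquisition(ph$chi_total, acq, spec)

g       <- spec$grid
b_total <- phase_to_field(unwrap_laplacian(sim$wrapped_phase), acq, g)
eroded  <- erode_mask(ph$brain_mask, 6)           # 6-voxel cubic erosion
ref     <- phantom_reference_mask(ph)
magc    <- sim$magnitude / sim$bias               # bias-corrected magnitude
w   <- compute_weight_map(magc, eroded, ref)      # mean 1 over reference
mg  <- compute_edge_mask(magc, eroded, 0.30)      # 30% edge exclusion

kern <- build_dipole_kernel(g)
fit  <- pdf_fit(b_total, ph$brain_mask, w, kern)
fit
#> PDF background fit: 173 CG iterations, final relative CG residual 0.000927 (converged)

b_local <- subtract_background(b_total, fit$b_bg, eroded)
inv <- dipole_inversion(b_local, w, mg, kern,
                        solver_config(norm_p = 2, lam = 1250))
inv
#> Regularised dipole inversion (L2, lambda = 1250)
#>   28 iterations (converged), fidelity residual 0.0001155
#>   chi range in brain: [-0.01488, 0.1452] ppm

chi <- reference_normalize(inv$chi, ref)
extract_region_stats(chi, ph$labels)$stats[, c("region", "median_ppm", "n_voxels")]
#>      region    median_ppm n_voxels
#> 1   putamen  9.171407e-02      160
#> 2  pallidum  1.433750e-01       88
#> 3 reference -1.972891e-06      320
```

The putamen analogue (truth 0.10 ppm, no magnitude contrast, hence
regularised across its boundary) is recovered at 0.092 ppm; the
edge-protected pallidum analogue (truth 0.15 ppm) at 0.143 ppm; the
reference region sits at 0 ppm by construction. `dipole_inversion()`
returns a classed fit supporting `print`, `summary`, `coef` (the χ
array), `fitted` (the implied field), `residuals` and `plot`.
`lambda_sweep()` reproduces the regularisation diagnostics over the
standard grid λ ∈ {200, …, 3250, 10⁴}, and `make_cohort()` /
`compare_groups()` run the two-group (8 vs 8) regional statistics.

`run_pipeline(pipeline_config(...))` chains all stages with a
reproducible manifest; `inst/cli/qsm.R` exposes the verbs
`phantom | unwrap | pdf | masks | invert | stats | pipeline` for shell
use on NIfTI volumes.

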