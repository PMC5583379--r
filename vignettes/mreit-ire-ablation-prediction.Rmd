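---
title: "Predicting IRE ablation zones from current-density imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting IRE ablation zones from current-density imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Irreversible electroporation (IRE) ablates tissue nonthermally by exposing it
to trains of short high-voltage pulses. Whether a given cell dies depends on
the local electric field *and* on the exposure (pulse count and duration), so
treatment monitoring wants the in-tissue field distribution *during* pulse
delivery — something post-treatment imaging cannot give. Magnetic resonance
electrical impedance tomography (MREIT) obtains it: the pulse current
perturbs the scanner's static field, the perturbation `B_z` is read out as an
image phase shift (current-density imaging, CDI), Ampère's law turns the
measured `B_z` into a current-density map, an iterative reconstruction turns
current density into conductivity, and Ohm's law yields the field map. A
cell-survival model then converts field into death probability, and
thresholding the probability map yields a predicted ablation area that can be
compared against a reference (histological) area.

This package implements that whole chain in 2D, together with a synthetic
phantom generator and forward simulator, so every stage — and the chain
end-to-end — is testable without scanner data.

## Geometry and conventions

All maps live on a square grid (default 64 × 64 pixels over a 30 mm field of
view, the emulated acquisition). Pixel centers sit at `(i − 0.5)·pixel_mm`
from the lower-left corner; matrices are indexed `(row = y, col = x)`. Two
needle electrodes (0.5 mm diameter, 1.2–3.3 mm apart, 700 V between them) are
perpendicular to the slice and are modeled in-plane as disks — at the default
resolution each disk is a single pixel, a deliberate 2D idealization.
Internally everything is SI (V/m, A/m², T); fields convert to kV/cm only at
presentation, because the survival-model constants are published in kV/cm.
Because the model is z-invariant, "current" means current per meter of slice
(A/m).

## Forward model

`solve_potential()` discretizes `∇·(σ∇u) = 0` with 5-point finite
differences, harmonic averaging of σ at cell faces (flux continuity across
conductivity jumps), Dirichlet values on electrode pixels and insulating
outer boundaries. The sparse symmetric system is solved directly; the
relative residual is checked against `tol` (default 1e-8) and a violation is
an explicit failure carrying the residual. `compute_fields()` forms
`E = −∇u` by central differences and `J = σE`.

`biot_savart_bz()` synthesizes the measurable flux perturbation with the 2D
(infinite-line) kernel

  `B_z(r) = (μ0/2π) ∬ [ j_x (y−y′) − j_y (x−x′) ] / |r−r′|² dA′`,

evaluated exactly by FFT convolution with the singular self-pixel zeroed.
`synthesize_cdi_phase()` encodes `φ = γ_p B_z t_c` with `γ_p = 2.675e8`
rad s⁻¹ T⁻¹ and adds Gaussian noise of SD `max|φ|/SNR`. The encoding time
default is `t_c = 400 µs`: the sequence fits four 100 µs pulses inside the
encoding window, and only current-on time accumulates phase. Phase
unwrapping is acquisition-specific and not modeled; synthesis refuses
phases outside (−π, π] (synthetic phantoms at the default grid stay near
0.7 rad).

## What a single B_z can and cannot see

A central methodological point, easy to miss: the single-component Ampère
inversion `j_x = (1/μ0) ∂B_z/∂y`, `j_y = −(1/μ0) ∂B_z/∂x` recovers only the
**solenoidal** (curl-bearing) part of the in-plane current. For needle
electrodes in near-homogeneous tissue the current is almost entirely
curl-free (`J = −σ∇u` with smooth σ), and the monopole-pair source field
produces *identically zero* `B_z` — by rotational symmetry each source's
contribution cancels. A bare `bz_to_current()` round trip on such a phantom
therefore returns nearly nothing, no matter how accurate the discretization
(we verify the kernel against the straight-wire closed form to <3% and the
inversion on solenoidal fields to ~1%).

This is precisely why MREIT reconstruction takes the electrode geometry and
potentials as inputs alongside the CDI data. `cdi_current()` implements the
standard model completion: solve the potential problem on a homogeneous
reference conductivity, scale its current to the measured drive current
(recorded by a current probe during treatment; synthetically,
`line_current()` integrates the exact face fluxes), and invert only the
*deviation* of the measured `B_z` from the reference prediction:

  `J = J_ref + (1/μ0) curl⁻¹(B_z − B_z(J_ref))`.

On a homogeneous phantom this recovers `J` essentially exactly; on a
two-region phantom to ~10%. Conductivity perturbations whose induced current
is itself curl-free remain invisible — see Limitations.

## Conductivity reconstruction

`j_substitution()` alternates a potential solve on the current conductivity
iterate with the pointwise update `σ ← |J|/|∇u|`. Holding the electrode
potentials as Dirichlet data pins the simulated electrode-to-electrode
voltage to the applied value at every iteration, so the conductivity scale
is fixed by the known drive and the explicit voltage rescale is identically
1 in this formulation. Bare J-substitution is unstable where `|∇u|`
stagnates, so `|∇u|` is floored at 1e-9 V/m and σ is clamped to
[1e-4, 1e2] S/m each sweep (clamped pixel counts are logged). Iteration
stops when the relative L2 update falls below `tol` (default 1e-4, max 50
sweeps); a non-converged result is returned with `converged = FALSE` rather
than raised, since stalling at the data-inconsistency floor is the expected
behavior on measured (completed) data while exact forward data converges
(homogeneous: 2 sweeps; two-region: 35, with monotone updates).

Electrode-adjacent pixels (disk plus a 2-pixel annulus,
`electrode_exclusion_mask()`) are excluded from quantitative error metrics;
current density is singular there. `reconstruct_efield()` is pointwise Ohm's
law `|E| = |J|/σ`.

## Cell-death model

The Fermi survival curve

  `S(E) = 1 / (1 + exp((E − E_c)/k))`,  `D = 1 − S`

with `(E_c, k)` depending on pulse number and duration. The bundled
calibration table carries the in-vitro pair for the emulated protocol
(N = 8 pulses of 100 µs): `E_c = 2.344` kV/cm, `k = 0.2677` kV/cm; at
`E = E_c` exactly half the cells die. Unknown `(N, t_p)` pairs raise an
error listing available calibrations — no silent extrapolation; users can
extend the table from CSV. The predicted ablation region at level `p` is the
inclusive super-level set `D ≥ p` with no connected-component filtering
(areas, not component counts, are the endpoint), and its area is the pixel
count times the pixel area.

## Agreement statistics

`fit_regression()` regresses predicted on reference areas (OLS with
intercept by default; both the predictor role and a through-origin variant
are available since published comparisons do not always state either
choice). `bland_altman()` reports the mean difference, its n−1 SD, the
±1.96 SD limits of agreement, and the Pearson correlation of differences
against pairwise means (flagged not-computable when either is constant at
machine precision). `select_best_level()` picks the level with the highest
R², breaking exact ties by the smaller |mean difference|. Both formulas are
verified against independently coded normal-equation and direct-formula
oracles to 1e-10.

## The synthetic validation study

`synthetic_study()` mirrors the emulated experiment: nine phantoms with
electrode gaps spanning 1.2–3.3 mm and tumor radii growing with the gap
(gaps track tumor size), 700 V, the default pulse protocol. Reference
("histology-like") areas are the true-field death map thresholded at
p = 0.2, plus Gaussian area noise of SD 0.1 mm²; predicted areas come from
the full measurement-and-reconstruction chain at levels {0.1, 0.2, 0.3}.
One hundred noise replicates re-run the agreement module; the fraction
selecting the constructed level and the noise-free regression at that level
are the calibration endpoints (selection ≈ 99/100, slope ≈ 0.94,
R² ≈ 0.95, mean difference ≈ 0.05 mm² at seed 42 — all recomputed by the
test suite and `scripts/acceptance.R`, never stored).

Design choices a reader should know:

* **Two-region phantoms by default.** The validation phantoms are
  piecewise-constant (background 0.2 S/m, tumor 0.4 S/m — assumed values;
  no measured conductivities exist for the emulated system). With smooth
  intratumoral heterogeneity the perturbation current is largely curl-free
  and thus partly invisible to single-`B_z` CDI; reconstructed fields bias
  low, and the best-agreeing level shifts *downward* (at 20% heterogeneity
  the study selects 0.1 instead of 0.2). The two-region design isolates
  what the calibration verifies — the agreement and selection machinery on
  an invertible chain. The downward shift under heterogeneity parallels the
  in-vivo observation that model agreement peaks at lower death
  probabilities than in-vitro calibrations suggest.
* **Heterogeneity generator.** `add_heterogeneity()` multiplies σ by a
  log-normal smooth field (Gaussian-filtered white noise, rescaled in the
  log domain to the target coefficient of variation, mean-preserving,
  strictly positive); correlation length defaults to 1.5 mm. The emulated
  tissue class varies by up to ~20%, which is the cv the generator tests
  exercise.
* **Area noise 0.1 mm²** emulates reference-measurement variability
  (section registration, observer tracing) and is below one pixel area
  (0.22 mm²), so reference areas remain anchored to the constructed level.
* **Problem sizes.** Validation runs at the acquisition geometry
  (64 × 64 / 30 mm); solver cross-checks against the two-line-source closed
  form use 128 × 128 / 60 mm so the insulating boundary barely perturbs the
  free-space solution, and the area-extraction oracle runs at 256 × 256
  where the 0.5 mm electrodes are resolved.

## Numerical choices and degenerate inputs

* Direct sparse solves (LU on the 5-point system); residual verified
  post-hoc against `tol`, failure carries the residual.
* Central differences everywhere, one-sided at the outer boundary; the
  discrete divergence of `J` is below 1e-3·max|J| per pixel beyond ~8 pixels
  from the needles.
* Thresholding is inclusive (`≥`), keeping the constant-map-at-`p` case
  non-empty; `predict_area()` requires `p ∈ (0,1)` while the ground-truth
  helper also accepts `p = 0` (entire domain).
* Degenerate agreement inputs (fewer than 3 pairs, zero predictor variance,
  constant differences) raise errors or not-computable flags rather than
  returning misleading numbers.
* Maps are typed (`kind` + units); the I/O layer refuses kind mismatches,
  NaN pixels (reported with indices), and CSV grids without a JSON sidecar,
  because mm² areas must never rest on a guessed pixel size. NIfTI carries
  the spacing in its header and round-trips float64 exactly.

## Known limitations

* **Resolution near the needles.** At 64 × 64 the p = 0.2 threshold contour
  sits 1–2 pixels from the single-pixel electrodes; the extracted area is
  about half the grid-converged value (2.2 vs 4.2 mm² on the reference
  homogeneous case). Like-for-like comparisons (predicted and reference
  areas from the same grid, as in the emulated study) are unaffected, but
  absolute areas at this resolution are not converged.
* **Single-`B_z` information loss.** Curl-free conductivity-perturbation
  currents are invisible; only the model completion supplies them. Strongly
  heterogeneous tissue therefore reconstructs with a systematic low bias.
* **2D idealization.** Infinite-line Biot–Savart kernel, z-invariant
  currents, no slice-profile or 3D return-path effects; no phase
  unwrapping; no thermal effects or conductivity dynamics during pulsing.
* Passing the synthetic suite shows the chain is self-consistent under
  these idealizations; it does not certify accuracy on real tissue, where
  heterogeneity, 3D effects and registration dominate the error budget.
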