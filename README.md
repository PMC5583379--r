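# mreitire

Predicting irreversible-electroporation (IRE) ablation zones from magnetic
resonance current-density imaging.

IRE ablates tumors nonthermally with trains of high-voltage pulses; the
outcome depends on the electric field each cell sees *during* pulse delivery
together with the exposure (pulse count N and duration t_p). This package
implements the full monitoring chain for a two-needle treatment imaged in a
single slice:

1. **CDI measurement model** — pulse currents perturb the scanner field; the
   perturbation `B_z` is encoded as image phase `φ = γ_p B_z t_c`.
2. **Ampère inversion with model completion** — a single measured `B_z`
   component determines only the solenoidal part of the in-plane current
   `J`; the curl-free remainder is supplied by a reference solve with the
   known electrode geometry, potentials and measured drive current
   (`cdi_current()`).
3. **J-substitution MREIT** — iterate `∇·(σ∇u) = 0` with electrode Dirichlet
   data and the pointwise update `σ ← |J|/|∇u|` to reconstruct conductivity,
   then recover the field by Ohm's law `|E| = |J|/σ`.
4. **Peleg-Fermi cell death** — survival `S(E) = 1/(1 + exp((E − E_c)/k))`,
   death `D = 1 − S`, with the bundled in-vitro calibration
   `E_c = 2.344 kV/cm`, `k = 0.2677 kV/cm` for N = 8 pulses of 100 µs.
   The predicted ablation region at probability `p` is the super-level set
   `D ≥ p`; its area is compared against reference (histology-like) areas.
5. **Agreement statistics** — per-level linear regression and Bland–Altman
   analysis (mean difference ± 1.96 SD limits of agreement), and selection
   of the death-probability level that agrees best.

A synthetic phantom generator and forward simulator (finite-difference
potential solver, 2D Biot–Savart flux synthesis, phase encoding) make every
stage — and the chain end-to-end — testable without scanner data. See the
methods vignette (`vignettes/mreit-ire-ablation-prediction.Rmd`) for the
models, assumptions and design decisions.

## Worked example

Nine synthetic tumors (electrode gaps 1.2–3.3 mm, 700 V, 8 × 100 µs pulses)
pushed through the full measurement-and-reconstruction chain, with reference
areas built from the true-field 20% death-probability region plus 0.1 mm²
of area noise:

```r
library(mreitire)
st <- synthetic_study(seed = 42, n_replicates = 100)
st
#> <synthetic_study> 9 cases; best level (noise-free) 0.2; selection rate at 0.2: 99%
st$level_stats_noise_free[, c("p_level", "slope", "r_squared", "mean_diff")]
#>   p_level    slope r_squared   mean_diff
#> 1     0.1 1.147727 0.3929507  1.12304688
#> 2     0.2 0.937500 0.9548611  0.04882812
#> 3     0.3 1.125000 0.8839286 -0.09765625
```

Reading this: across the probability levels analyzed, the predicted areas
agree best with the references at the 20% level — the level the references
were built from — with a near-unit regression slope (0.94), R² = 0.95 and a
mean predicted-minus-reference difference of 0.049 mm² (about a fifth of a
pixel). The replicate selection rate (99/100) is the calibration check that
the best-level search reliably finds the constructed truth under reference
noise.

Single maps work the same way at any stage, e.g.

```r
ph  <- make_phantom(electrode_gap_mm = 2.2, seed = 1)   # conductivity phantom
u   <- solve_potential(ph$sigma_true, ph$electrodes)    # potential (V)
fl  <- compute_fields(u, ph$sigma_true)                 # E (V/m), J (A/m^2)
bz  <- biot_savart_bz(fl$current)                       # measurable B_z (T)
d   <- death_map(fl$e_mag, lookup_params(pulse_protocol()))
predict_area(d, p = 0.2)$area_mm2
field_summary(fl$e_mag, thresholds_kvcm = 1.8)
```

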