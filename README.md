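# pmfdecomp

Free-energy-profile decomposition along a folding coordinate for
coarse-grained chain molecules in implicit solvent.

`pmfdecomp` is for computational biophysicists who want to know *why* a
chain folds: it computes the potential of mean force F(R) along the
end-to-end distance R and splits it exactly into the competing
contributions

- F(R) = F_vac(R) + mu_ex(R) — intramolecular versus solvent-induced,
- F_vac(R) = E_intra(R) − T S_intra(R) — energy versus conformational
  entropy,
- mu_ex(R) = mu_nonpol(R) + mu_pol(R) — hydrophobic-like versus
  electrostatic solvation,

together with temperature-difference profiles, pressure-difference
profiles, unfolding free energies ΔF_u and the partial molar volume change
ΔV = (∂ΔF_u/∂P)_T.

The machinery is the interesting part:

1. **Umbrella sampling + WHAM** reconstructs F_GB(R) under a generalized
   Born / surface-area (GB/SA) continuum solvent, with bootstrap errors.
2. **A bidirectional dielectric-ladder FEP** estimates the excess chemical
   potential of the GB solvent, mu_ex^GB(R) = Σ_steps [Δμ(forward) −
   Δμ(reverse)]/2, stepping the dielectric from 80 (water) to 1 (vacuum)
   through twelve intermediates, which yields F_vac = F_GB − mu_ex^GB
   without ever sampling the (glassy) vacuum landscape directly.
3. **Exponential reweighting to a pluggable hydration backend** corrects
   GB hydration to any per-conformation model: Δμ_ref^GB(R) =
   −k_BT ln ⟨exp(−(ΔG_hyd − ΔG_solv^GB(80))/k_BT)⟩, giving
   F = F_GB + Δμ_ref^GB. Backends can be in-memory closed forms or TSV
   tables of externally computed hydration free energies.

Everything is exposed tidyverse-style: profiles are tibbles with
metadata, results have `tidy()`/`glance()` methods and `autoplot()`
figures, and the pipeline chains with the pipe.

## Worked example

A charged harmonic dumbbell (two beads, bond k = 1000 kJ mol⁻¹ nm⁻²,
r0 = 0.5 nm, charges ±0.8 e) has a closed-form profile, so the full
pipeline can be checked end to end. With the self-consistent GB backend
the reference correction must vanish and F must equal F_GB:

```r
library(pmfdecomp)

toy <- harmonic_dumbbell(k_b = 1000, r0 = 0.5, charges = c(0.8, -0.8), gamma = 0.02)
cfg <- run_config(
  R_min = 0.44, spacing = 0.02, n_windows = 18,
  ladder = dielectric_ladder(intermediates = c(20, 5, 2)),
  protocol = sampling_protocol(n_equil = 1000, n_frames = 2000, stride = 10, seed = 7),
  fep_grid = c(0.5, 0.6, 0.7), R_ref = 0.5, n_boot = 20, fixed_mode = "exact")

dec <- decompose_pipeline(toy$topology, gb_backend(80, sa = TRUE), cfg)[["1"]]
glance(dec)
#> # A tibble: 1 × 7
#>   temperature pressure R_ref n_grid closure_F closure_mu closure_Fvac
#>         <dbl>    <dbl> <dbl>  <int>     <dbl>      <dbl>        <dbl>
#> 1         298        1   0.5      3  7.11e-15          0            0

td <- tidy(dec)
td[td$component %in% c("F", "F_vac", "mu_ex"), ]
#> # A tibble: 9 × 4
#>   component     R  value stderr
#>   <chr>     <dbl>  <dbl>  <dbl>
#> 1 F_vac       0.5   0     0.464
#> 2 F_vac       0.6   1.80  0.375
#> 3 F_vac       0.7   7.51  0.377
#> 4 F           0.5   0     0.464
#> 5 F           0.6 -10.2   0.375
#> 6 F           0.7 -13.0   0.377
#> 7 mu_ex       0.5   0     0    
#> 8 mu_ex       0.6 -12.0   0    
#> 9 mu_ex       0.7 -20.6   0

unfolding_free_energy(dec$profiles$F, folded_R = 0.5, seed = 1)
#> # A tibble: 1 × 5
#>     dFu stderr   p_folded temperature pressure
#>   <dbl>  <dbl>      <dbl>       <dbl>    <dbl>
#> 1 -13.1  0.616 0.00000206         298        1
```

Reading the numbers: the closure residuals are machine-precision — the
thermodynamic cycle is assembled, not fitted. All profiles are in k_BT,
shifted to zero at R = 0.5 nm. For this ion-pair dumbbell the
intramolecular leg F_vac rises with R (the bond and the Coulomb attraction
resist stretching) while the solvent leg mu_ex falls steeply (separated
charges are far better solvated), so the solvent wins: F decreases with R,
the "unfolded" state is more stable by ~13 k_BT (ΔF_u = −13.1 ± 0.6), and
the analytic profile (−10.31 and −13.15 k_BT at 0.6 and 0.7 nm) lies
within one standard error of the recovered values. `autoplot(dec)` draws
the decomposition; `delta_P_profiles()` and `delta_T_profiles()` compare
thermodynamic states, and `thermo_summary()` collects ΔF_u and ΔV across
conditions.

A thin command-line layer wraps the same functions for shell use
(`inst/scripts/pmfdecomp`, subcommands `toy`, `sample`, `wham`, `fep`,
`decompose`, `report` over a YAML config, with manifests and resumable
on-disk artifacts).

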