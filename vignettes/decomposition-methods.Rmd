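---
title: "Decomposing free-energy profiles along a folding coordinate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing free-energy profiles along a folding coordinate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfdecomp)
```

## The problem and the model

The thermodynamic stability of a chain molecule in water is conveniently
summarised by its free-energy profile $F(R)$ along the end-to-end distance
$R$ between its two terminal beads, a common measure of molecular
dimensions. `pmfdecomp` computes $F(R)$ for coarse-grained bead chains and
decomposes it into the contributions that compete to fold or unfold the
chain:

$$F(R) = F_\mathrm{vac}(R) + \mu_\mathrm{ex}(R),$$

where $F_\mathrm{vac}$ is the profile the isolated molecule would have in
vacuum (intramolecular interactions plus conformational entropy) and
$\mu_\mathrm{ex}$ is the excess chemical potential profile, i.e. the
solvent-induced part: the reversible work of transferring the molecule from
vacuum into solvent at fixed $R$, *including* conformational relaxation
during the transfer. Two further exact splits complete the picture:

$$F_\mathrm{vac}(R) = E^\mathrm{intra}_\mathrm{vac}(R) - T S^\mathrm{intra}_\mathrm{vac}(R),
\qquad
\mu_\mathrm{ex}(R) = \mu_\mathrm{nonpol}(R) + \mu_\mathrm{pol}(R).$$

The nonpolar part is measured on a charge-zeroed copy of the solute, so it
upper-bounds the hydrophobic contribution; the polar part is the remainder.

Because direct vacuum sampling of a hydrogen-bond-riddled chain is
impractically slow, the package takes the route through a continuum
solvent. All sampling happens under an effective Hamiltonian
$U_\mathrm{intra} + \Delta G^\mathrm{GB}_\mathrm{solv}(\varepsilon_r)$,
where the generalized Born / surface area (GB/SA) solvation free energy of
each conformation acts as a potential term. Three measured legs assemble
the cycle:

1. **Umbrella sampling + WHAM** gives $F_\mathrm{GB}(R)$, the profile in
   the GB solvent at $\varepsilon_r = 80$.
2. **A bidirectional dielectric-ladder free-energy perturbation (FEP)**
   gives $\mu^\mathrm{GB}_\mathrm{ex}(R)$, the excess chemical potential of
   the GB solvent itself, by stepping $\varepsilon_r$ from 80 down to 1
   (vacuum) through intermediate states and averaging forward and reverse
   exponential estimators at each rung. Then
   $F_\mathrm{vac} = F_\mathrm{GB} - \mu^\mathrm{GB}_\mathrm{ex}$.
3. **Exponential reweighting to a hydration backend** corrects the GB
   description of hydration to any per-conformation hydration free-energy
   model $\Delta G_\mathrm{hyd}$ evaluated on the $\varepsilon_r = 80$
   ensemble:
   $\Delta\mu^\mathrm{GB}_\mathrm{ref}(R) = -k_BT\,\ln\langle
   \exp[-(\Delta G_\mathrm{hyd} - \Delta G^\mathrm{GB}_\mathrm{solv}(80))/k_BT]
   \rangle_R$. Then $F = F_\mathrm{GB} + \Delta\mu^\mathrm{GB}_\mathrm{ref}$
   and $\mu_\mathrm{ex} = \mu^\mathrm{GB}_\mathrm{ex} +
   \Delta\mu^\mathrm{GB}_\mathrm{ref}$, so $F = F_\mathrm{vac} +
   \mu_\mathrm{ex}$ holds bin-for-bin by construction.

The backend is a plug point (`hydration_backend()`): the package ships a
self-consistency backend (GB itself, closing the cycle exactly), a toy
reference backend with explicit temperature and pressure dependence, and a
table backend that ingests externally computed per-frame hydration
energies, so molecular-level liquid-state theories can drive the correction
without being reimplemented here.

## The coarse-grained model

Chains are beads with harmonic bonds, optional harmonic angles,
Lennard-Jones and Coulomb nonbonded terms (1–2 pairs excluded, interior
dielectric 1). Units are kJ mol⁻¹, nm, elementary charges, K, with
$k_B = 0.0083144621$ kJ mol⁻¹ K⁻¹; profiles are reported in $k_BT$.

The GB flavour is a Still-style pairwise formula,
$f_{ij} = \sqrt{r_{ij}^2 + B_iB_j\exp(-r_{ij}^2/4B_iB_j)}$, over all charge
pairs including self terms, with prefactor $-(1 - 1/\varepsilon_r)/2$.
Effective Born radii $B_i$ come from a Coulomb-field-approximation pairwise
descreening integral that is exact for non-overlapping spheres; overlapping
pairs are evaluated at contact distance, which caps the descreening
smoothly. An isolated bead recovers the Born ion energy exactly. The
nonpolar term is a per-bead solvent-accessible surface area from pairwise
spherical-cap burial (probe 0.14 nm) scaled by per-bead surface-tension
coefficients — analytic, fast and adequate at toy resolution; no
triangulation. The variant is deliberately kept behind the
`solvation_free_energy()` interface so other radius prescriptions can be
swapped in. The decomposition machinery itself is resolution-agnostic; the
coarse-grained model exists to exercise it against closed-form answers.

## Sampling

The default integrator is Metropolis Monte Carlo with single-bead Gaussian
displacements — the surface-area term has derivative kinks that an MC
sampler is indifferent to, and no force evaluation is needed. Runs are
bit-for-bit reproducible from a recorded seed. Fixed-$R$ ensembles (needed
for every FEP leg) come in two modes: a stiff auxiliary restraint (default
$k = 18750$ kJ mol⁻¹ nm⁻², ten times the reference umbrella constant) with
the residual spread reported, and an exact mode that freezes the two
terminal beads, preserving $R$ to machine precision. Exact holonomic
constraints inside a dynamical integrator would be disproportionate for toy
chains; the two modes are validated against each other in the test suite.
Ladder states are sampled sequentially from $\varepsilon_r = 80$ down to 1,
each run seeded with the final conformation of the previous one, so
neighbouring states start well equilibrated relative to each other.

The reference protocol mirrors production-scale practice for a small
peptide: umbrella force constant 1875 kJ mol⁻¹ nm⁻², window spacing
0.0125 nm with 208 windows, a dielectric ladder with twelve intermediates
(40, 20, 10, 5, 4.2, 3.5, 2.9, 2.4, 2.0, 1.7, 1.4, 1.2), ensembles of 5000
frames, and five-block standard errors. Toy-scale runs in the examples and
tests use 18–20 windows and 10³–5·10³ frames per ensemble, chosen so that
the entire validation suite completes in minutes on one CPU while leaving
every statistical check well resolved.

## WHAM

`wham_solve()` iterates the self-consistent weighted-histogram equations in
log space (log-sum-exp throughout) until the window constants move by less
than $10^{-8}\,k_BT$ (cap $10^5$ iterations). Bins with zero pooled counts
are reported as missing, never interpolated; windows that fail to cover a
contiguous $R$ range raise an error naming the gap. Standard errors come
from a multinomial frame-level bootstrap within each window, re-solving
WHAM per replicate (warm-started from the full-data solution) and shifting
every replicate to the common reference before taking per-bin standard
deviations.

Two discretisation points deserve note. The bias factor is evaluated at
bin centres, so bins should be narrow compared with the scale on which the
bias varies; the default bin width equals the window spacing, which is
adequate when profile errors are a few tenths of $k_BT$, while
high-precision oracle comparisons in the tests use bins several times finer
than the spacing. Second, a binned estimator's expectation is the
bin-integrated Boltzmann weight, not the profile value at the bin centre;
the validation tests therefore integrate the analytic density over each bin
before comparing — with steep profiles the distinction is measurable.

Profiles are shifted so the value is zero at a reference distance
(`profile_shift()`, default $R_\mathrm{ref} = 0.5$ nm); every downstream
quantity depends only on profile differences, and the gauge invariance is
asserted in the tests.

## FEP estimators

All exponential averages use log-sum-exp; raw exponentials never appear.
Each one-step estimator reports the exponential-weight effective sample
size $n_\mathrm{eff} = (\sum w)^2 / \sum w^2$ and flags results below a
configurable floor (default 50) — the literature gives no overlap
criterion, so this is a package choice, and the reweighting leg is exactly
where it matters: the correction is only trustworthy if the sampled
ensemble overlaps the reference description. Standard errors use
contiguous-block decomposition (default five blocks) of the per-frame
exponent series.

The ladder sum is assembled in the hydration direction: for each adjacent
pair the step is (sampled at the lower $\varepsilon_r$ targeting the
higher, minus the reverse, over two), summed from vacuum to water. The
index convention at the endpoints is otherwise ambiguous; this choice makes
the telescoped total equal $\Delta G_\mathrm{solv}(80) - \Delta
G_\mathrm{solv}(1)$, so $\mu^\mathrm{GB}_\mathrm{ex} = F_\mathrm{GB} -
F_\mathrm{vac}$ becomes an exact identity (asserted to machine precision on
rigid systems, where every step telescopes regardless of ladder
resolution). The surface-area term stays on for every ladder state except
the final true-vacuum state, so the endpoint difference is the full (polar
plus nonpolar) solvation free energy.

The nonpolar route samples the charge-zeroed solute at $\varepsilon_r = 1$
(vacuum) and $\varepsilon_r = 80$ (surface term only — the polar term
vanishes without charges) and takes the single bidirectional step between
them, plus the charge-zeroed backend correction;
$\mu_\mathrm{pol} = \mu_\mathrm{ex} - \mu_\mathrm{nonpol}$ is then exact by
construction.

## Temperature, pressure and summary thermodynamics

Temperature enters the sampling Hamiltonian, so every leg is resampled at
each temperature; difference profiles are formed per component in its own
$k_BT$ units, $\Delta_T X(R) = X(R,T_2)/k_BT_2 - X(R,T_1)/k_BT_1$, and the
component additivity carries over exactly. Pressure, by contrast, enters
only through the backend's $\Delta G_\mathrm{hyd}(T,P)$, so pressure scans
reuse the 1-bar ensembles and re-evaluate only the reweighting leg;
$\Delta_P F = \Delta_P \mu_\mathrm{ex}$ is then an identity (the vacuum leg
cannot depend on pressure) and is returned as such.

The unfolding free energy treats a configurable set of grid distances
(default 0.5 and 0.6 nm, a native-plus-near-native convention) as the
folded state and every other sampled grid point as unfolded:
$\Delta F_u = \ln(p_f/p_u)$ in $k_BT$ over plain grid-point Boltzmann sums
— no extra Jacobian, since $F(R)$ is already defined from the
$R$-distribution — so positive values mean the folded state is more
stable. Its error resamples the profile within its per-bin standard
errors. The partial molar volume change is the least-squares slope of
$\Delta F_u \cdot k_BT$ against pressure over all computed pressures
(1 J mol⁻¹ bar⁻¹ = 10 cm³ mol⁻¹), more stable than a single finite
difference when three or more pressures are available.

## Toy systems and what the tests do (and do not) show

Two built-in systems have closed-form answers. The harmonic dumbbell's
radial potential of mean force is $\beta U(R) - 2\ln R$ up to a constant
(the $-2\ln R$ term is the three-dimensional Jacobian), with $U$ including
the pairwise GB/SA closed form for charged variants — this validates the
whole chain from sampling through WHAM, the ladder, reweighting and
assembly against analytic values. The freely jointed chain has the
classical piecewise-polynomial end-to-end density (checked against direct
simulation of the ideal chain), exercising multi-bead statistics. The toy
reference backend's pressure term is exactly linear in $P$ with an
analytic volume, so pressure responses can be checked to machine precision
on rigid systems.

These fixtures emulate umbrella-window trajectories and per-frame energy
tables with known Boltzmann statistics. They do not emulate rugged
all-atom energy landscapes, slow orthogonal degrees of freedom, or the
force-field and hydration-model errors of real peptides; passing tests
demonstrate the correctness of the estimators and the assembly algebra,
not the accuracy of any particular molecular model. For real systems the
table backend is the intended route: per-frame hydration energies computed
by an external molecular-level theory are ingested and the same machinery
applies unchanged.

## Numerical choices and limitations

- Convergence: WHAM tolerance $10^{-8}\,k_BT$ on window constants;
  overflow-safe log-space iteration; bootstrap replicates warm-started.
- Degenerate inputs are errors, not silent results: empty windows,
  non-overlapping window sets (named gap), charged topologies passed to
  the nonpolar route, missing ladder states or energy columns, folded
  states outside the grid, profiles with numerically zero folded or
  unfolded probability, backends evaluated outside their declared (T, P)
  domain, missing table keys.
- Grids never align implicitly: `profile_resample()` is the explicit step,
  and cycle assembly refuses mismatched grids.
- The effective-radius and surface-area formulas are smooth pairwise
  approximations; at severe bead overlap the descreening is capped at its
  contact value, which slightly underestimates burial for deeply
  interpenetrating beads. Toy topologies keep bonded beads near contact,
  where the approximation is well behaved.
- The unfolded-state definition (all non-folded sampled grid points) is a
  convention; the folded set and the reference distance are configurable.
- Umbrella windows can only hold the chain where the effective Hamiltonian
  permits: for strongly charged dumbbells the GB self-energy is steeply
  repulsive at short $R$, and windows centred below the accessible range
  simply sample their attainable tail. Window schedules should be placed
  inside the physically accessible region (the coverage check reports
  gaps).
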