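---
title: "Membrane transversal and lateral analysis: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane transversal and lateral analysis: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprofiler)
```

# Scope

`memprofiler` computes the membrane observables used to compare how a small
dipolar solute (chloroform-like) and its apolar counterpart (carbon
tetrachloride-like) partition in lipid bilayers and perturb membrane
mechanics. It works on annotated particle snapshots — positions, masses,
partial charges, molecule ids, species tags, and per-atom roles — read from
GRO/PDB files with a sidecar topology table, or produced by the package's own
synthetic emulator. It does not run molecular dynamics: force fields,
electrostatics solvers, thermostats and sampling are out of scope, and the
pair force field bundled here exists only to exercise the stress machinery on
synthetic systems.

# The bilayer frame

All transversal analyses assume a flat bilayer normal to z. Because the
bilayer center of mass drifts along a trajectory, every frame is centered
independently on the mass-weighted z of the membrane species before any
accumulation (`center_on_bilayer_com()`). Leaflets are assigned by the sign
of each lipid's phosphate z (key atom for cholesterol); a reference atom
exactly at z = 0 goes to the upper leaflet, deterministically, with a
warning.

Profiles are accumulated in 0.1 nm slices by default. Two grid flavours
exist for a reason:

* `profile_grid()` places one slice centered on the midplane (odd slice
  count). Midplane-referenced quantities — the potential gauge and the PMF
  reference density — then have an exact node at z = 0 instead of an
  interpolated one.
* `grid_from_box(box)` tiles the box height exactly (edges at ±Lz/2). The
  Irving-Kirkwood contour wraps segments periodically, and only an exactly
  tiling grid makes the per-pair slice fractions sum to one.

The scaled coordinate z_esc divides z by the phosphate density peak position
of its half-space, so the peaks sit at ±1. Peaks are located on the 0.1 nm
binned phosphate density with parabolic refinement over the three bins around
the maximum, which decouples the peak estimate from bin placement. The peak
positions are taken from the frame-averaged density, not per frame: per-frame
peaks on a 0.1 nm grid are noisy for small systems, while the averaged peak
is stable; this is an interpretation the input data do not fix.

# Transversal profiles

**Density.** Per-slice sums of mass, charge, or count divided by the slice
volume, averaged over frames. Slices never visited are `NA`, never zero, and
stay `NA` through downstream analyses.

**Electrostatic potential.** V(z) solves the one-dimensional Poisson
equation, integrating the charge density twice. The density is piecewise
constant per slice, so the field is piecewise linear and the potential
piecewise quadratic; `potential_profile()` integrates slab-by-slab in that
closed form rather than by generic quadrature, which makes sheet-charge test
cases exact to machine precision. Two boundary conventions are exposed:

* `"midplane"` (default): V(0) = 0 and E(0) = 0 at the bilayer center — the
  natural gauge for a symmetric bilayer, where the average charge density is
  even in z and the field vanishes at the midplane by symmetry.
* `"bulk"`: V = E = 0 at the lower grid edge, i.e. in bulk solvent.

The two differ by a linear gauge term whenever the two half-spaces carry
opposite net charge. An isolated parallel-plate capacitor (+σ at −d, −σ at
+d) is such a case: only the bulk convention reproduces the textbook plateau
difference σ·2d/ε₀, while under the midplane convention the interior field is
zero by construction. For physical bilayer charge distributions — even in z
on average — the conventions coincide, which the tests verify on a
mirror-symmetric double layer.

**Potential of mean force.** PMF(z) = −k_BT ln(ρ(z)/ρ₀) with ρ₀ the density
in the slice whose center is nearest the midplane. This Boltzmann inversion
is reliable only for solutes that genuinely sample the whole membrane
interior; empty slices are reported as `NA` rather than +∞ so plots and
splines skip them instead of interpolating through −ln 0. Values are stored
in k_BT units, making the profile temperature-free until conversion.

**Solute dipole orientation.** α(z) is the mean angle between the solute
C→H axis and +z, binned by the carbon position (the molecular center of a
chloroform-like solute). 0° means H pointing up; an isotropic orientation
averages to 90°. The profile is direction-resolved: H aligning toward the
nearest polar region gives α < 90° above the midplane and α > 90° below it.

# Lateral pressure and elastic moments

The stress profile separates into a kinetic and a configurational part.
The kinetic part is ρ_N(z)·k_BT at the stated temperature — coordinate files
carry no velocities, and for an isothermal system equipartition fixes this
term exactly. The configurational part applies the Irving-Kirkwood contour:
each pair's virial r⊗F is distributed along the straight minimum-image
segment joining the two particles, each slice receiving the fraction of the
segment it contains, divided by the slice volume. Segments crossing the
periodic z boundary wrap their contributions. Because the fractions of every
pair sum to one on a box-tiling grid, the volume-weighted slice sum equals
the direct global virial identically — the suite asserts agreement with an
independent double-loop oracle at 1e-8 relative.

P_L = (P_xx + P_yy)/2 and P_N = P_zz are reported per slice in k_BT/nm³
(1 kJ/mol/nm³ = 16.6054 bar for the `bar` option). Pairs within the same
molecule are excluded: bonded interactions are not modelled, and the
synthetic systems treat molecules as internally rigid.

**Moments.** Per monolayer, P1 = ∫ z·P_L dz and P2 = ∫ z²·P_L dz, integrated
from the midplane to the phosphate plane (|z_esc| = 1 by default — the
integration limit used when relating the moments to monolayer elastic
constants; other limits can be passed). The signed bilayer-frame z is the
integration variable, so a z-symmetric profile yields equal-magnitude,
opposite-sign monolayer P1: both monolayers frustrate the same spontaneous
curvature with opposite sign. The profile is piecewise linear between slice
centers, so z^k·P_L is at most cubic per segment and two-point Gauss-Legendre
integrates it exactly — closed-form cases (constant and triangular profiles)
hold to 1e-10. The single bilayer-level value is the mean of the two
monolayer magnitudes carrying the upper monolayer's sign; the per-monolayer
values are always reported alongside, since the bilayer-level combination is
a convention, not a measurement. First moments map onto the bending term
k_c·c₀ and second moments onto the Gaussian curvature modulus k_g;
`convert_moment_units()` moves values between J/nm, J/m, J and thermal units
exactly at a stated temperature.

**Conformational work.** W = a₁P1 + a₂P2 approximates the mechanical work
the pressure field exerts on a protein's cross-sectional area change, from a
Taylor expansion of the area-difference profile; the direct form
∫ΔA(z)·P_L(z) dz is available when ΔA(z) is supplied on the pressure grid.

**Smoothing.** `smooth_profile()` uses a cubic smoothing spline
(`stats::smooth.spline`). The default strength comes from generalized
cross-validation, then is reduced until the integral of the smoothed profile
agrees with the raw integral within 1% of the integral of |raw| — the
absolute-value denominator matters because near-antisymmetric pressure
profiles integrate to nearly zero. Moments are computed from the raw profile
by default; smoothing is presentation-layer.

# Lateral structure

**Order parameters.** For united-atom chains the two C–H directions at
carbon i are reconstructed perpendicular to the C(i−1)→C(i+1) axis, split by
the tetrahedral H–C–H angle about the backbone-bisector plane, and
S_CD = ⟨(3cos²θ − 1)/2⟩ against the bilayer normal. The global ⟨−S_CD⟩
averages only carbons flagged `bond_class = "single"`; double-bond carbons
are reported individually but excluded, since their C–H geometry does not
follow the tetrahedral reconstruction.

**Voronoi tessellation.** Key atoms (PC: the glycerol–phosphate linking
carbon; cholesterol: the hydroxyl) are projected per leaflet and tessellated
with periodic closure: seeds are replicated over the 8 neighbouring images
and each cell is clipped by perpendicular-bisector half-planes, visiting
neighbours in distance order and stopping once the next bisector cannot cut
the cell. The construction is exact — areas partition the box cross-section
to 1e-9 — and needs no external geometry library. Duplicate seeds receive a
deterministic 1e-6 nm jitter with a warning.

**Thickness.** Each PC's transbilayer neighbour is the opposite-leaflet PC
with the laterally nearest phosphorus (minimum image; ties broken by
molecule id); thickness is the 3-D phosphorus–phosphorus distance.

**Radial profiles.** The domain center is the per-axis circular mean of the
domain species' key atoms — the circular mean respects periodicity, where an
arithmetic mean would fail for a patch near the box edge. Molecules are
binned by lateral minimum-image distance r_CM and per-bin means accumulate
over frames.

**Proximity statistics.** "Close" is not a uniquely defined notion, so the
rule is explicit and configurable: by default a solute counts toward a lipid
when its center lies within a lateral cutoff r_prox = 0.7 nm (about one
lipid diameter) of the lipid's key atom on the same leaflet side; a
`"nearest"` rule (each solute assigned to exactly one lipid) is selectable.
The random baseline is the per-molecule binomial, P(k) = Binom(k; N_solute,
1/N_lipid) — molecules, not area, carry the weight, matching how per-species
occupancy distributions are usually presented; an area-weighted baseline
would differ when species' areas differ. `solute_lipid_ratio()` uses the
nearest-assignment rule so each solute is counted once, and reports the
uniform-random expectation alongside.

# Solute kinetics

Crossings are sign changes of z(t) across the midplane; a sample exactly at
zero inherits its previous side, so a grazing touch is not double-counted.
Confinement episodes are maximal runs where the solute is closer to the
phosphate plane of its current side than to the midplane (|z − sign(z)·z_P| <
|z|); episodes therefore persist through fast interleaflet jumps that never
linger near the midplane, which matches the dwell-and-jump picture the
trajectory statistics describe.

Lateral diffusivity is slope/4 of a linear fit to the (x, y) mean-squared
displacement, computed with all-pairs lag averaging via the FFT
autocorrelation identity (validated against a naive double loop) after
periodic unwrapping. The default fit window spans lags of 10–50% of the
series; for precise recovery the tests use ensembles of trajectories and
short lag windows (≲ 2% of the series), because single-trajectory MSD values
at long lags carry O(1) relative noise. A log–log MSD exponent far from 1
over the fit window flags non-diffusive (e.g. ballistic) input instead of
silently reporting a meaningless slope. 1 nm²/ns = 1000 µm²/s exactly.

# The synthetic emulator

`synthetic_spec()` + `generate_bilayer()` build coarse bead-rod bilayers
whose *statistics* — not chemistry — carry the structure the analyses
assume, with every imposed quantity recorded as ground truth. Defaults are
fixed at the study conditions of fluid PC bilayers at 310 K: area per
molecule 0.701 / 0.452 / 0.363 nm² (disordered PC / ordered PC /
cholesterol), phosphate planes at ±1.895 nm (disordered) and ±2.51 nm
(ordered), target ⟨−S_CD⟩ of 0.108 and 0.341, compositions of 128 PC (+32
Chol) per bilayer and the 256/256/64 and 64/448/112 patch compositions, 128
solutes against 512 PC in patch systems, a telegraph interleaflet switching
rate of 5 /ns, and 1 nm²/ns lateral solute diffusion.

Chains are all-trans zigzag rods tilted from the inward normal; the tilt β
satisfies sin²β = (1 − 2t)/1.5 for a target ⟨−S_CD⟩ = t, because a chain
axis at tilt β with uniformly random azimuth gives an azimuth-averaged
S_CD = (3sin²β/2 − 1)/2. Both the chain azimuth and the zigzag-plane
azimuth are randomized per molecule and frame — without the latter the C–H
frame would stay correlated with the tilt plane and bias S_CD. The recorded
ground truth is the realized mean over the sampled tilts, so the closure
test (recovery within 0.01 at ≥10⁴ samples) checks the analysis chain, not
the sampling noise of the generator.

Water is emulated as two-site dipoles at a reduced number density of
8 molecules/nm³ with a mild orientational bias toward the membrane — enough
charge structure to shape V(z) qualitatively while keeping desk-scale
systems a few thousand particles. Dipolar solutes carry ±0.2 e at 0.11 nm
(≈1 D); apolar solutes carry a chargeless C–H-like axis by default so their
orientation profile is computable and flat at 90°, and can be generated
without the axis to exercise the "no dipole atoms" error path. The
interfacial placement law mixes two Gaussians at ±0.75·z_P over a uniform
background (weight 0.7), keeping the midplane density finite so the PMF
reference exists, with minima on the interface flanks.

Solute z-trajectories are telegraph processes: exponential dwells at
±z_dwell with instantaneous side switches and sub-threshold Gaussian noise,
so every switch is exactly one midplane crossing and the imposed rate is
recoverable; (x, y) is a wrapped random walk at the specified D. Identical
spec + seed reproduces output bit for bit.

**What passing closures does and does not show.** The generator reproduces
geometry, composition, order, placement and kinetics, but none of the
thermodynamics: no force-field realism, no equilibrium partitioning, no
phase behaviour, no pressure-field realism (lipids are internally rigid, so
bonded stress contributions are absent). Tests passing on generator output
demonstrate that the analysis pipeline recovers imposed structure; they say
nothing about the accuracy of any particular simulation model. The uniform
lattice also gives every molecule in a leaflet the same expected Voronoi
area, so per-species area contrast (PC vs cholesterol) is not imposed, and
area-per-lipid closures are asserted on single-species systems.

# Problem sizes and defaults used in the shipped checks

The test-suite and the reproduction script run on desk-scale systems chosen
as the smallest sizes at which each statistical tolerance is comfortably
met: bilayers of 64–160 lipids per leaflet, 10–25 frames for order/PMF/
orientation statistics (≥10⁴ order-parameter samples), LJ slabs of ≤500
particles for stress checks, telegraph trajectories of 1000 ns at 0.01 ns
steps for the crossing rate, and ensembles of 8–12 × 200 ns walks for
diffusivity. Quantities with exact closed forms (capacitor potential,
ideal-gas pressure, virial consistency, Boltzmann inversion, Voronoi
partition, constant-profile moments) are checked at numerical-precision
tolerances, not statistical ones.

# Known limitations

* Orthorhombic boxes and flat reference surfaces only; no curvature or
  undulation correction.
* Pairwise LJ/truncated-Coulomb stress only: no Ewald-consistent
  decomposition, no bonded or many-body terms.
* The Boltzmann-inversion PMF is biased wherever the solute does not sample;
  it is not an enhanced-sampling free-energy method.
* The midplane/bulk potential gauge choice matters for charge distributions
  with oppositely charged half-spaces; both are exposed, and the default
  follows the bilayer-midplane convention.
* The binomial proximity baseline is per-molecule; an area-weighted variant
  would shift baselines when species' areas differ strongly.
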