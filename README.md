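# memprofiler

Transversal and lateral analysis of lipid bilayer systems in R.

## The problem

Small volatile organohalogens partition into lipid membranes and perturb
properties that are invisible to most experiments but central to
lipid-mediated hypotheses of anesthesia: the transversal electrostatic
potential V(z), the lateral pressure profile P_L(z) and its elastic moments,
the free-energy landscape a solute sees along the membrane normal, and the
lateral distribution of solutes between ordered and disordered lipid phases.
A dipolar solute (chloroform-like) and an apolar one (carbon
tetrachloride-like) behave very differently on exactly these observables.

`memprofiler` implements the full analysis chain for such studies, for
people who have bilayer particle configurations (from simulation or
construction) and want the membrane observables computed with explicit,
tested conventions:

* **Transversal profiles** — mass/charge density; V(z) by double integration
  of the Poisson equation, V(z) = −(1/ε₀)∬ρ_q, with midplane (V(0)=0,
  E(0)=0) or bulk boundary conventions; the potential of mean force
  PMF(z) = −k_BT ln(ρ(z)/ρ₀); solute dipole orientation α(z); all in 0.1 nm
  slices, optionally on the scaled axis z_esc that pins the phosphate
  density peaks to ±1.
* **Lateral pressure** — Irving–Kirkwood contour assignment of pairwise
  virials, kinetic part ρk_BT, P_L = (P_xx+P_yy)/2; cubic-spline smoothing;
  per-monolayer moments P1 = ∫z·P_L dz (→ k_c·c₀) and P2 = ∫z²·P_L dz
  (→ k_g) to |z_esc| = 1; conformational work W = a₁P1 + a₂P2; exact unit
  conversion between J/nm, J/m and k_BT units.
* **Lateral structure** — deuterium order parameters S_CD for united-atom
  chains; periodic Voronoi tessellation per leaflet with per-molecule areas;
  transbilayer thickness maps; radial composition/thickness/order profiles
  around a lipid nanodomain; solute proximity distributions P(k) with a
  binomial random baseline; solute:lipid ratios.
* **Solute kinetics** — interleaflet crossing rates, interfacial confinement
  episodes, lateral diffusivity from FFT-based MSD fits.
* **A synthetic bilayer emulator** — deterministic, fully parameterized
  generator of bilayer configurations, patch (nanodomain) membranes, and
  stochastic solute trajectories, with every imposed quantity recorded as
  ground truth, so the entire pipeline is testable without MD input.

Input is a GRO or PDB coordinate file plus a tab-separated topology table
(molecule id, species, role, mass, charge per atom), or a generated system.
Outputs are plain-text XVG-compatible profiles and TSV tables.

## Worked example

Generate a disordered-PC bilayer emulation with 32 dipolar solutes, then
compute the headline observables:

```r
library(memprofiler)

spec <- synthetic_spec(
  lipids_per_leaflet = c(PC_disordered = 64),
  n_solute = 32, solute_dipolar = TRUE, water_density = 4, seed = 7)
gen    <- generate_bilayer(spec, n_frames = 10)
frames <- gen$frames
grid   <- grid_from_box(frames[[1]]$box, exact = FALSE)

phos  <- density_profile(frames, selection = list(role = "phosphate"), grid = grid)
peaks <- locate_phosphate_peaks(phos)
#> z_P_minus  z_P_plus
#> -1.899865  1.899225

sol <- density_profile(frames, selection = list(species = "solute_dipolar"),
                       grid = grid)
pmf <- scale_to_phosphate_coordinates(pmf_profile(sol), peaks)
#> PMF minimum: -2.18 kBT at z_esc = 0.74

voronoi_leaflet(frames[[1]], "upper")
#> <voronoi_leaflet> upper leaflet, 64 molecules, area sum 44.8640 / box 44.8640 nm^2

mean(per_molecule_thickness(frames[[1]])$thickness)
#> 3.79 nm

order_parameters(frames)
#> <order_parameter_set> <-S_CD> = 0.1048 over 10240 samples

crossing_stats(generate_solute_trajectory(spec)$traj)
#> <crossing_stats> 516 crossings over 100 ns (5.16 /ns); mean confinement 9.99 ns (10 episodes)
```

Reading: the phosphate peaks sit at ±1.90 nm (the imposed 3.79 nm bilayer
thickness, which the per-molecule thickness map recovers); the dipolar
solute's free-energy minimum lies on the inner flank of the lipid/water
interface (z_esc ≈ 0.74), not at the bilayer center; Voronoi areas partition
the box cross-section exactly, giving 0.701 nm² per lipid; the chain order
parameter recovers the imposed ⟨−S_CD⟩ ≈ 0.108 of a disordered PC phase; and
the solute crosses the interleaflet plane about 5 times per nanosecond, the
imposed telegraph rate.

A YAML-driven end-to-end run (`run_pipeline()`, or
`Rscript inst/cli/memprofiler.R run -c run.yaml`) writes the profiles, the
per-molecule tables and a structural summary (area per PC, area per Chol,
thickness, ⟨−S_CD⟩, and P1/P2 when the pressure stage runs).

See the vignette `vignettes/membrane-analysis-methods.Rmd` for the models,
conventions, numerical choices and the generator's scope.

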