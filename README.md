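# memscape

Post-simulation analysis of membrane-protein molecular-dynamics trajectories,
built around the ABCA1 lipid exporter in a heterogeneous bilayer. The package
is aimed at structural bioinformaticians who have (or want to emulate)
atomistic trajectories of a transmembrane protein in a mixed membrane and
need the standard battery of protein- and lipid-side analyses in one tested,
scriptable place.

## What it computes

**Protein side.**

- Kabsch superposition (SVD), RMSD and mass-weighted radius-of-gyration
  series (reported in nm), and per-residue RMSF about the time-mean after
  per-frame superposition.
- Essential dynamics: PCA of the superposed coordinate covariance
  `C = <(x - <x>)(x - <x>)'>`; eigenvector 1 is the dominant collective
  motion, and `interpolate_mode()` writes a multi-model PDB sweeping 100
  conformers along it.
- Free-energy landscape over order parameters (RMSD, Rg): a Gaussian-mixture
  density `rho(x) = sum_k w_k N(x; mu_k, S_k)` fitted by EM (mclust, K chosen
  by BIC), the surface `F(x) = -kT ln(rho/rho_max)` (so `min F = 0`), and
  clustering of points into the basins of the density maxima by deterministic
  8-neighbour hill climbing on an evaluation grid.
- Secondary structure: per-residue propensity over {H, E, T, C}, a 70%
  consensus rule (a residue below 70% occupancy of its best class is
  *dynamic*), domain-wise composition over the six ABCA1 domains
  (ECD1 46–630, ECD2 1366–1640, TMD1 1–45 + 631–902, TMD2 1327–1365 +
  1641–1906, NBD1 903–1147, NBD2 1907–2143), and Bendix-style helix
  bend-angle profiles with the >15° / (0°, 15°] / ~0° flexibility classes.

**Membrane side.**

- Leaflet assignment by residue-centroid z against the bilayer mean
  (phosphate-free cholesterol included).
- Bilayer thickness as the distance between the phosphate density peaks of
  the two leaflets (1 Å histogram, parabolic peak refinement).
- Time-averaged leaflet deformation maps on a periodic XY grid, signed so
  positive always means outward expansion.
- Voxel partial densities (~2 Å columns, amu/Å³, lipids only), area per
  lipid `Lx * Ly / N_leaflet`, and Fourier-filtered Monge-patch mean
  curvature
  `H = [(1 + z_x^2) z_yy - 2 z_x z_y z_xy + (1 + z_y^2) z_xx] / [2 (1 + z_x^2 + z_y^2)^(3/2)]`
  on a 100 x 100 grid with spectral derivatives and a Gaussian low-pass
  (positive = the leaflet bends away from the bilayer centre).
- A 6 Å square lipid census grid per monolayer with per-type counts and a
  protein-occupancy overlay.

**Contacts.** Residue-level protein–lipid contacts at a 5 Å (0.5 nm) shell
with exact cell-list acceleration under the periodic minimum-image
convention; persistence as *total* (not necessarily consecutive) time in
contact; stable residues by a strict `> 500 ns` rule; per-lipid-type
frequencies; protein–protein contacts with an i±2 sequence exclusion; and
intersection with a residue annotation table (the eleven ABCA1
disease-variant positions ship in `inst/extdata/abca1_variants.csv`).

**Synthetic generator.** Because published trajectories of this system are
not deposited, the package includes a bilayer-plus-protein generator with
exact ground truth: the seven-lipid composition (POPC 482, PSM 108, CHL 48,
POPI 36, POPE 30, POPS 24, LLPC 18), three-atom lipid stubs with headgroups
on the ±T/2 planes, analytic surface deformations (flat, Gaussian bump,
spherical cap), scripted protein–lipid contact schedules, and scripted
secondary-structure label plans. Every analysis stage is tested against this
machinery.

## Worked example

```r
library(memscape)

sys <- embed_protein(build_bilayer(bilayer_spec(), seed = 1),
                     n_residues = 60, radius = 12)
st  <- simulate_frames(sys, 50, motion_model(jitter = 0.4), seed = 1, dt = 200)

census_totals(sys)            # POPC 473 of 482 remain (12 lipids removed)
average_thickness(st, sys)$mean
area_per_lipid(st, sys, "top")$mean
```

Running the numbered drivers in `analysis/` end to end prints, among others:

```
Built bilayer: 746 lipids; 12 removed for the protein footprint
Bilayer thickness 41.28 +/- 0.05 A (phosphate density peaks)
Area per lipid: 65.3 A^2 with the protein vs 64.4 A^2 control
Global consensus make-up: H 41.0%, C 21.0%, T 14.33%, E 5.40%, dynamic 18.27%
Landscape: BIC selected K = 7; 7 density-maxima clusters (truth 7)
Straight helix: max bend 0.27 deg (rigid); kinked helix: max 27.2 deg (flexible)
11 of the ... stable residues are disease-variant positions: C23Y, L694del, ...
```

The thickness sits in the generator's ground-truth band (headgroup planes at
±20.8 Å), the consensus make-up returns the scripted global fractions, the
landscape clustering recovers the seven scripted modes, and the variant
intersection recovers exactly the eleven annotated positions.

## Layout

- `R/` — the package (all computation lives here)
- `analysis/01_build_system.R … 06_contacts.R` — numbered narrative drivers
  writing tables and grids under `results/`
- `tests/testthat/` — unit, property and end-to-end oracle suites
- `vignettes/membrane-trajectory-analysis.Rmd` — the methods vignette
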