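---
title: "Methods: membrane-protein trajectory analysis with memscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-protein trajectory analysis with memscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscape)
```

memscape analyses molecular-dynamics trajectories of a membrane protein in a
mixed bilayer: protein conformational metrics and a free-energy landscape,
secondary-structure consensus and helix flexibility, bilayer scalar fields
(thickness, deformation, density, curvature, area per lipid), a square-cell
lipid census, and protein–lipid contact persistence. This vignette explains
the models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic test machinery does and does not establish.

## Data model and units

Coordinates are stored in Ångström throughout (the PDB convention); GRO
input is converted from nm on read. Parameters quoted in nm in the membrane
literature — the 0.5 nm contact shell, ~0.2 nm density voxels — are
converted once at the user-facing argument boundary (5 Å, 2 Å), never inside
kernels. Fluctuation metrics (RMSD, Rg, RMSF) are *reported* in nm, the
scale on which protein-level deviations of a large transporter are usually
discussed. Residue ids are 1-based; insertion codes are rejected rather than
silently renumbered. Binary trajectory formats are deliberately out of
scope: any reader that produces an `atoms × 3 × frames` array can construct
a `frame_stream`, which is the single contract all analyses consume. The
frame stride defaults to `dt = 200` ps, so frame *k* (0-based) sits at
`200 k` ps.

The ABCA1 domain table (ECD1 46–630, ECD2 1366–1640, TMD1 1–45 and 631–902,
TMD2 1327–1365 and 1641–1906, NBD1 903–1147, NBD2 1907–2143) leaves the
stretches 1148–1326 and 2144–2261 uncovered; these map to `"unassigned"`
rather than being attributed to a named domain, since no published range
covers them.

## Conformational metrics and the free-energy landscape

Superposition uses the SVD form of the Kabsch solution with an explicit
properness correction (`det R = +1`); sets with fewer than three atoms or a
collinear geometry are rejected because the rotation is under-determined.
The independent check in the test suite is Horn's closed-form quaternion
method, an algebraically unrelated route that must agree to 1e-9.

RMSF is computed about the time-mean position after superposing every frame
on the first, then aggregated per residue as the mass-weighted mean of the
per-atom mean-square fluctuations (square root taken last). Under isotropic
Gaussian jitter of width σ per coordinate the expected RMSF is σ√3; the test
uses a 100-residue chain so that the six rigid-body degrees of freedom
absorbed by superposition bias the result by well under the 5% tolerance.

Essential dynamics diagonalises the covariance of the superposed coordinate
vectors; eigenvalues are clamped at zero against numerical noise, and
projections onto the eigenvectors must reproduce the eigenvalues as their
variances (checked to 1e-8 relative). The conformer sweep along a mode spans
± twice the mode's standard deviation by default, with exactly
`n_conformers` equally spaced structures.

The landscape over (RMSD, Rg) is a full-covariance Gaussian mixture fitted
by EM via mclust. Two choices here were genuinely open:

- **Number of components.** No selection rule is prescribed by the
  methodology this follows, so K is chosen by BIC over a user range
  (default 1–8) — standard, and deterministic given the seed. For n > 2000
  the model-based hierarchical initialisation runs on a seeded 1000-point
  subset to keep the fit fast; the EM itself always uses all points.
- **Energy scale.** `F = -kT ln(rho/rho_max)` needs a kT convention; the
  default is 2.494 kJ/mol (300 K, the simulation temperature of the target
  system), exposed as an argument. Grid cells where the density underflows
  are capped at 50 kJ/mol and flagged rather than returning infinities.

Clustering assigns each point to the basin of the density maximum reached by
steepest 8-neighbour ascent on a 100×100 evaluation grid over the data range
(5% padding). Ties move to the lower linear grid index, which makes the
labelling deterministic and cycle-free (each hop strictly improves the pair
(density, −index)). Mixture components and basins are distinct notions: BIC
may legitimately split a heavy-tailed mode into two overlapping Gaussians,
while the density-maxima clustering still reports one basin — the basin
count is the scientifically meaningful "number of states".

## Secondary structure and helix flexibility

The assignment algorithm behind the published per-residue propensities is
not named, so the package provides two routes. The built-in classifier works
on backbone dihedrals: φ/ψ in the α region (φ ∈ [−100°, −30°],
ψ ∈ [−80°, −5°]) in runs of ≥ 4 residues → H; β region (φ ∈ [−180°, −90°],
ψ ∈ [90°, 180°] ∪ [−180°, −170°]) in runs of ≥ 3 → E; shorter (≥ 2) α/β
stretches → T; everything else, including residues with missing backbone
atoms (warned), → C. Alternatively, `read_label_matrix()` accepts external
per-frame labels as CSV or as DSSP letters (G,H,I→H; E,B→E; T→T;
S,blank,-,C→C), so a hydrogen-bond-based assigner can be substituted without
touching the rest of the pipeline.

The consensus rule assigns a residue its most frequent class iff that class
holds for **at least** 70% of frames; "70% of the time" is read as boundary-
inclusive, so exactly 3500 of 5000 frames is assigned and 3499 is dynamic.
The dynamic fraction is monotone non-decreasing in the threshold, and the
consensus is invariant to frame order (both tested). Composition reports are
emitted per domain, globally over all residues, and globally over
domain-assigned residues only — published percentages can be computed either
way, so both denominators are shown.

Helix axes are sliding-window centroids of Cα positions (window 4, about one
turn), followed by a second moving-average pass: a single pass leaves a
residual helical wobble of ~0.26 Å (the 3.6-residue period does not divide
the integer window), which the second pass suppresses to ~0.03 Å so that an
ideal straight helix profiles below the 1° rigidity tolerance. The bend
angle at an axis point is the angle between the chords `span` points behind
and ahead (default 4; about one turn of accumulated curvature). Classes
follow the red/white/blue semantics: flexible > 15°, intermediate
(rigid_tol, 15°] — the 15° boundary is inclusive to intermediate, since the
published classes are "(>15°)" and "(0–15°)" — and rigid ≤ 1°. Helix ends
are unresolved by construction (an axis point needs a full window both
sides). For bend profiling, helices are contiguous consensus-H runs of at
least six residues.

## Membrane fields

**Leaflets.** A lipid belongs to the leaflet on its side of the mean lipid-
centroid z of that frame, computed from unweighted coordinate means so the
rule works for phosphate-free cholesterol. The assignment is purely
per-frame geometry; a lipid that flips across the midplane changes label in
that frame. A frame in which all centroids coincide in z is degenerate and
rejected.

**Thickness** is the distance between the two phosphate density peaks: a 1 Å
z-histogram split at the mean selected z, the modal bin on each side refined
by three-point parabolic interpolation. This matches the "distance between
density peaks" definition while staying deterministic; the trade-off is a
resolution of one histogram bin for near-delta distributions (a plane pair
at ±20.8 Å reads 41.6 ± 1 Å). Whether thickness tooling elsewhere uses all P
atoms or leaflet-assigned ones is ambiguous; this implementation uses the
per-side split of the selection.

**Deformation maps** accumulate, per periodic XY grid cell (default 2 Å),
the headgroup height minus the leaflet's per-frame mean height, time-
averaged, then multiplied by +1 (top) / −1 (bottom) so that positive always
means outward expansion, irrespective of leaflet. Computing the reference
per frame removes box drift. Cells never visited are filled by iterative
periodic neighbour averaging and masked.

**Partial densities** are column voxels (default 2 Å in-plane, the full box
along the remaining axis); the value is time-averaged subset mass over voxel
volume, in amu/Å³, lipids only by default. Mass is conserved exactly by
construction (tested to 1e-9 relative).

**Mean curvature** grids headgroup z to a height field (default 100×100
bins), fills empty cells periodically, low-pass filters in Fourier space,
differentiates spectrally, and applies the Monge-patch formula. Two points
were open and are worth recording:

- **Filter shape.** A brick-wall mode cutoff produces Gibbs ringing that is
  catastrophic for curvature (second derivatives) of large smooth features —
  on a spherical-cap fixture a sharp cutoff mis-estimates the apex curvature
  several-fold with an erratic sign. The default filter is therefore a
  Gaussian attenuation `exp(-(|k|/q_modes)^2)` (q_modes = 4), which is
  ring-free and leaves the second derivative of any locally quadratic
  surface unchanged. The sharp cutoff remains available as `filter =
  "sharp"`, and `q_modes = NULL` disables filtering.
- **Cutoff scale.** `q_modes = 4` (smoothing length ≈ L/18) suppresses
  single-lipid gridding noise on realistic lipid densities. The analytic
  curvature oracles use `q_modes = 12` on densely sampled fixtures: the
  smoothing length must sit well below the surface's feature scale (σ = 20 Å
  bump; 60 Å cap core), while unfiltered spectra amplify the sub-Ångström
  cell-sampling jitter by q² up to the Nyquist frequency and drown the
  signal. Both choices follow from the bandwidth argument, not from tuning.

Signs: the raw Monge H of a dome-shaped height field is negative (−A/σ² at a
Gaussian apex). With `leaflet = "top"`/`"bottom"` the sign is flipped so
positive curvature means bending away from the bilayer centre; `"none"`
reports the raw convention.

**Area per lipid** is box XY area over leaflet lipid count; the protein
footprint is deliberately *not* subtracted (flagged in the output), which is
why a protein-carrying membrane reads a higher APL than a control of equal
box — the comparison direction, not the absolute value, is the meaningful
statement at this level of approximation.

## Lipid census grid

Residue positions are plain arithmetic means of atom coordinates — not
mass-weighted, following the stated "mean of the x, y, z coordinates". The
chosen monolayer (same mean-z rule as leaflets) is tiled with square cells
of edge 6 Å anchored at the box corner (the anchoring was unstated;
the origin is recorded in the output sidecar), centroids wrapped
periodically before binning. A cell is protein-flagged when at least one
protein residue centroid assigned to the monolayer falls in it; protein
residues are assigned by centroid z — above the bilayer mean → top — and
only if they lie within the z range actually occupied by that monolayer's
lipid atoms, since residues beyond it are extracellular or cytosolic. The
default analysed frame is the last one, with any frame selectable.

## Contacts

A protein residue and a partner residue are in contact when the minimum
distance over their atom pairs is ≤ 5 Å, computed with the periodic
minimum-image convention (needed for box-spanning lipids; the choice was
unstated but is the only box-consistent one). The cell-list acceleration
bins atoms into cells no smaller than the cutoff and scans 27 neighbour
cells; it is exactly equivalent to the all-pairs search, verified on 100
random periodic fixtures per run. Persistence accumulates *total* frames in
contact — "for more than 500 ns throughout the simulation" is read as a
total-time, not longest-run, criterion — and converts with dt exactly
(2600 frames × 200 ps = 520 ns). The stable-residue rule is strict:
exactly 500.0 ns does not qualify. Protein–protein contacts reuse the same
machinery with partners restricted to protein and sequence neighbours within
±2 excluded. Because contacts are counted per residue, a lipid parked
against one residue of a tightly packed fold also accrues time on that
residue's spatial neighbours; that is physical, and the drivers say so
rather than pretending designed anchors are the only qualifiers. Variant
annotation is a plain residue-id intersection; deletions and frameshifts
match by position.

## The synthetic generator: what it does and does not establish

Lipids are three-atom stubs — a headgroup atom (P, or O3 for cholesterol,
which genuinely lacks phosphate, forcing every analysis to cope with
P-free lipids) and two tail pseudo-atoms whose masses bring the residue
total to realistic values (e.g. POPC 760.1 amu). Headgroups sit exactly on
the ±T/2 planes (T = 41.6 Å by default, inside the experimentally reported
band for this composition) before deformation; placement is a seeded
jittered lattice, so generation is a pure function of (spec, seed). The
default composition is the seven-lipid mixture (POPC 482, PSM 108, CHL 48,
POPI 36, POPE 30, POPS 24, LLPC 18) in a 155 × 155 Å box, giving ~64 Å² per
lipid — the physiological order of magnitude.

Analytic deformations give the curvature and deformation stages closed-form
ground truth: a Gaussian bump has apex curvature −A/σ²; a spherical cap
places headgroups within `r_cap` exactly on a sphere of radius R (apex
H = 1/R) and blends to zero over a cosine taper so the field stays
continuous across the periodic box. The curvature oracles use densely
sampled leaflets (one headgroup per grid cell) because they test the
curvature *operator*; the default sparse composition tests the full
pipeline at realistic lipid densities, where the default filter recovers
the bump apex to ~4%.

Contact schedules move the *lipid* (never the protein, keeping RMSD/RMSF
interpretable): inside a scheduled interval the lipid head sits 3 Å from
the anchor residue along the outward horizontal direction from the protein
axis; outside, 12 Å. With jitter clamped to ±0.3 Å per coordinate on the
scheduled participants, the ≤ 4 Å / ≥ 8 Å guarantees hold exactly, frame by
frame. Label plans realise class fractions either exactly (largest-remainder
apportionment) or stochastically (i.i.d. draws), giving the consensus rule
both boundary-exact and statistical fixtures.

What passing these tests shows: the estimators are correct on inputs whose
ground truth is known exactly. What it does not show: anything about force
fields, sampling convergence, or lipid internal structure — the stubs have
no acyl-chain order, no undulation spectrum beyond the imposed deformation,
and jitter is white in time, so time-correlation-sensitive conclusions
cannot be drawn from them.

## Problem sizes and determinism

The test and acceptance runs use: 5000-frame schedules for persistence
(against exact 520 / 499.8 ns truth), 5000-point mixtures over
K ∈ {1, 3, 5, 7} × 20 seeds for landscape recovery, 5000 frames for the RMSF
limit, 100×100 grids for curvature, and 10000-residue label plans (the
smallest count for which 41 / 21 / 14.34 / 5.41% are exactly representable).
These sizes make every statistical tolerance comfortable while the full
suite runs in a few minutes on one CPU. All stochastic stages take explicit
integer seeds; `scripts/acceptance.R` derives every seed from its `--seed`
argument.

## Known limitations

- The φ/ψ classifier approximates, but is not, a hydrogen-bond method; π/3₁₀
  helices are not distinguished and map into H via the DSSP loader.
- Leaflet assignment by mean z assumes a roughly planar bilayer; strongly
  vesiculated or porated membranes would need a director-based rule.
- Curvature assumes the leaflet is a single-valued height field z(x, y);
  overhangs are outside the model.
- The area-per-lipid does not correct for the protein footprint (flagged in
  the output).
- `embed_protein()` builds a coarse Cα cylinder, adequate for footprint,
  occupancy and contact geometry, not for packing-level protein realism.
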