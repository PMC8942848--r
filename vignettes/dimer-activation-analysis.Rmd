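---
title: "Quantifying GPCR homodimer activation: states, interfaces, pockets and allosteric networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GPCR homodimer activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrdimer)
```

## The scientific problem

The yeast pheromone receptor Ste2 is a class D1 G-protein-coupled receptor
that functions as a homodimer. Its activation pathway runs through a series
of resolvable conformational states — ligand-free, antagonist-bound
(inactive), inactive-like and active-like agonist-bound intermediates, and
the G-protein-coupled active state. Comparing coordinate models of these
states quantitatively requires a small set of reproducible measurements:

* **aligned RMSD** between states over the C-alpha atoms of one protomer
  ("protomer A aligned"), with the pairing size reported;
* **named-residue C-alpha displacements** after that global alignment
  (e.g. the extracellular end of H6 measured at Ser267^6x59^);
* **helix kink angles** (axis-to-axis angle of a segment in two states)
  and **axial rotations** (the twist component of the segment's optimal
  rigid transform about its own axis);
* **dimer-interface area** — half the solvent-accessible surface area
  buried on dimerisation — plus typed residue contacts and their
  persistence over molecular-dynamics frames;
* **orthosteric pocket volume** by grid flood fill;
* **torsion mutual-information (MI) networks** with highest-MI shortest
  "pipelines" between the ligand-binding and G-protein-coupling sites and
  per-residue hubscores.

This package implements those measurements as composable functions with a
command-line front end, and ships a seeded synthetic-data generator so the
entire pipeline is testable offline against known ground truth.

## Coordinate handling and numbering

Structures are read from PDB or mmCIF into a plain atom table
(`StructureModel`). Author residue numbering is the internal key
throughout; class D1 generic numbers ("6x59") are attached only for
reporting via a segment table (`segment_table()`, `ste2_default_segments()`).
The printed helix boundary table of the underlying work is not public; the
defaults here are anchored so that every residue/generic-number pair that
*is* printed holds (Ser267 → 6x59, Ser243 → 6x35, Asn301 → 7x61, Pro290 →
7x50, Gly273 → ECL3, Arg234 → 5x58, Gln149 → 3x50, Ile80 → 2x42), with
boundaries interpolated between anchors. Users with their own boundary
definitions can supply a JSON table; JSON is used rather than TOML/YAML
because it needs no additional parser dependency.

Alternate locations are resolved by highest occupancy, then alphabetically.
HETATM records (waters, peptide ligands on their own chains, sterols) are
kept and flagged, and excluded from receptor-only computations.

## Geometry

Superposition is the closed-form Kabsch/SVD solution with determinant
correction (`det(R) = +1` always). "Global alignment" means Kabsch over all
common C-alpha atoms of a chosen protomer — the one alignment convention
the source work names — and the common set is the intersection of modelled
residues, ordered by residue number.

Helix axes use Kahn's estimator: second differences of consecutive C-alpha
positions are exactly perpendicular to an ideal helix axis, so cross
products of consecutive second differences recover the axis exactly for a
noiseless helix. A plain principal-component fit was rejected because the
residual helical phase biases short segments by one or two degrees, which
is material when the acceptance tolerance for planted motions is 1e-3
degrees. Kink angles are reported in [0°, 180°] between N→C oriented axes;
axial rotation is the swing–twist decomposition of the segment-to-segment
Kabsch rotation about the mean of the two axes.

Default reporting tolerances when comparing against printed values are
±0.2 Å for RMSD, ±0.5 Å for displacements and ±5° for angles, reflecting
that published selections (exact residue ranges, modelled-residue sets)
are not fully specified.

## Interface analysis

SASA is Shrake–Rupley with a deterministic spiral point set (default 960
points, probe 1.4 Å, Bondi radii). Buried interface area uses the
PISA-style convention `(SASA_A + SASA_B − SASA_AB) / 2` over the two
receptor chains only; the source work does not name its method, so this
area is treated as method-sensitive (±15%).

Contact typing follows the getcontacts-style defaults: van der Waals at
`r_i + r_j + 0.5 Å` on heavy atoms; hydrogen bonds at donor–acceptor
≤ 3.5 Å (with a D–H…A ≥ 110° check only when hydrogens are modelled, which
cryo-EM models rarely include); salt bridges at ≤ 4.0 Å between charged
side-chain N/O groups; cation–π at ≤ 6.0 Å from an aromatic ring centroid
within 60° of the ring normal. A residue pair is a *persistent* contact if
any contact type links it in **strictly more than** 60% of trajectory
frames; a pair at exactly 60% is excluded, and the boundary case is
tested explicitly.

The inter-protomer interaction energy is a deliberately *reduced*
forcefield: pairwise 12-6 Lennard-Jones plus Coulomb
(k = 332.0636 kcal·Å·mol⁻¹·e⁻², 12 Å cutoff) with one generic charge/LJ
class per atom type (formal charges on charged side-chain groups, small
polar backbone charges). Outputs are labelled `forcefield = "reduced"`.
Absolute parity with production CHARMM36m energies is explicitly out of
scope; the quantity is meant for state-to-state ordering, and its closed
forms (Coulomb at fixed separation, LJ minimum at `2^{1/6}σ`) are the test
surface.

## Pocket volume

`pocket_volume()` is a HOLLOW-style grid method: voxels (default 0.5 Å)
inside a bounding sphere (default 15 Å) are blocked within
`r_vdW + probe` of any heavy atom; the pocket is the 6-connected empty
component flood-filled from a seed, and volume is voxel count × spacing³.
The seed is the ligand heavy-atom centroid when a ligand is present; for a
ligand-free state the liganded seed is transferred through the protomer-A
superposition, keeping cross-state comparisons consistent. Convergence is
verified on analytic cavities (< 2% change when halving spacing from 1.0
to 0.5 Å; < 5% error against a spherical cavity). Absolute agreement with
any particular published HOLLOW run is not promised — those run parameters
are unpublished — only trend reproduction, which is what the contraction
statistic `(V_a − V_b)/V_a` reports.

## Torsions and the MI network

Trajectories load from multi-model PDB and DCD natively; XTC frames are
decoded through the system Python MDAnalysis installation (the only
xdrfile decoder available offline in the target environment) and converted
to Å. Torsions are the standard φ/ψ/χ1 dihedrals (IUPAC sign), wrapped to
(−180°, 180°], with missing angles masked rather than fatal. Only χ1 is
used beyond the backbone because the source of the MI method does not
enumerate its torsion set; χ1 captures the side-chain state at uniform
cost across residue types.

Residue-pair MI is computed on 24 equal circular bins (15°) for each of
the ≤ 9 torsion pairs, and the pair value is the **maximum** over torsion
pairs — preserving the strongest coupling channel rather than diluting it
by averaging. Finite-sample bias (which for 24×24 bins at n = 2000 frames
is ≈ 0.19 bits, far from negligible) is estimated by the mean MI over 20
seeded permutation shuffles and subtracted, floored at zero. The null
calibration test verifies that ≥ 95% of independent residue pairs land at
≤ 0.05 corrected bits.

The residue graph admits edges only between pairs whose (mean) C-alpha
distance is ≤ 10 Å, so "pipelines" are chains of physically adjacent
residues and may cross the dimer interface whenever inter-protomer pairs
satisfy that rule. Edge weight is `−log(MI/MI_max + 1e-6)`, converting the
highest-MI-path objective into an additive shortest-path problem solved by
an in-package Dijkstra with deterministic tie-breaks (fewer hops, then
residue order). Pipeline *strength* is the summed MI along the path —
"strength" is not precisely defined in the source, and summed MI makes
rank agree with the path objective; pipelines are ranked by strength and
the per-residue count of retained pipelines (endpoints included) is the
hubscore, reported as a top-10 table.

Site definitions reuse the contact machinery: residues in contact with the
ligand (or G-protein) chain in strictly more than 60% of frames.

## What the synthetic generator does and does not emulate

`make_toy_dimer_states()` builds two parallel ideal helices (rise 1.5 Å,
twist 100°/residue, C-alpha spacing 3.8 Å — the textbook α-helix) and
plants exact rigid sub-segment motions on protomer B: translations,
hinge rotations about the segment start, axial rotations about the segment
axis, covering the ranges seen across the receptor's activation transition
(shifts of a few to ~20 Å, kinks of tens of degrees, axial rotations up to
180°). Ground truth (per-C-alpha displacement, planted angles) is recorded
exactly, so recovery tests assert at 1e-6 Å / 1e-3°.

`simulate_coupled_torsion_trajectory()` draws φ/ψ/χ1 from von Mises
distributions (default κ = 8, circular SD ≈ 23°, a realistic torsional
fluctuation for a folded protein on the hundreds-of-nanoseconds scale) and
rebuilds serine-like coordinates each frame with a NeRF chain extension,
so `compute_torsions()` inverts the generator *exactly* — MI ground truth
flows through the real pipeline, not a shortcut path. Coupled residues
share an i.i.d. hidden two-state mode (p = 0.5) that offsets their torsion
means by 120°. Because the coupling is routed through a binary mode, the
true MI between any two coupled residues is bounded by the mode entropy,
H = 1 bit; with κ = 8 and a 120° offset the mode is essentially
recoverable from each angle, so pairwise MI sits just below 1 bit after
bias correction (and above 1 bit in the raw biased estimate). Tests assert
both sides of that bound rather than pretending the corrected value can
exceed it.

What the generator does **not** emulate: real backbone connectivity across
the dimer interface, forcefield physics, solvent/lipid, correlated motions
beyond the planted mode, or Ste2-specific dynamics. A green planted-chain
recovery therefore establishes that the estimator-plus-graph machinery
recovers known coupling structure at realistic noise — not that any
specific biological pipeline is correct.

`plant_contact_series()` places residue pairs in contact in an exact
seeded subset of frames, making the strict 60% persistence boundary
testable to machine precision (frequencies must be rational in the frame
count, otherwise the generator refuses).

## Numerical choices and degenerate inputs

* Collinear point sets and too-short segments raise typed
  `degenerate_geometry` errors rather than returning garbage.
* Angles at the ±180° wrap are handled circularly everywhere
  (`circular_mean()`, bin edges); a value of exactly 180° belongs to the
  last bin.
* The flood fill refuses buried seeds (`seed_buried`) instead of
  reporting a zero-volume pocket.
* Dijkstra never relaxes a finalized node (re-relaxation under tie-breaks
  can create predecessor cycles) and path reconstruction is bounded by the
  node count as a defensive check.
* All seeded procedures (permutation bias correction, generators) are
  bit-reproducible given the seed, and reports embed the full parameter
  set.

## Known limitations

* Printed-value reproduction on the five deposited coordinate sets
  requires those files, which cannot ship with the package and cannot be
  downloaded in an offline environment; the corresponding acceptance test
  fails honestly until the files are supplied under
  `inst/extdata/deposited/`.
* The reduced forcefield is not CHARMM36m; only orderings and closed-form
  limits are meaningful.
* The MI bias correction assumes exchangeable frames; strongly
  autocorrelated trajectories will under-correct (subsample frames first —
  trajectory stride metadata is carried for this purpose).
* Interface areas depend on the SASA method and point density at the
  percent level; comparisons across packages should use the same
  convention.
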