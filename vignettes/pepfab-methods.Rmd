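---
title: "Rigid-fragment peptide models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-fragment peptide models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pepfab)
```

## The model

`pepfab` treats a peptide as a kinematic chain: atoms are vertices of the
covalent bond graph, and rotation is permitted only about designated single
bonds, parameterized by torsion angles. Each residue contributes the
backbone dihedrals φ, ψ and ω plus up to four side-chain dihedrals χ₁..χ₄
(atom quads per residue type are a bundled table). ω is always emitted
locked: the peptide bond is planar and sits near 0°/180°, so it carries no
useful mobility for a hand-held model. Torsions whose axis lies in a ring
(proline φ and χ) are locked as well, since cutting a ring bond cannot
disconnect the graph — `fine_fragment()` refuses such cuts explicitly.

Deleting the axis bond of every free torsion partitions the graph into
**rigid fragments**, the package's printable unit. On an acyclic bond graph
the fragment count is exactly the cut count plus one; this invariant, and
equality with an independent flood-fill, are asserted across randomized
fixtures in the test suite. Fragment ids are deterministic (ordered by the
smallest contained atom serial). Each cut bond becomes a revolute joint
with a **male port on the fragment containing the N-proximal axis atom**
(for χ joints, the CA side). Nothing about the physics forces a particular
gender assignment — only that it be consistent — so this convention is the
package's own, applied uniformly and deterministically. Ports are keyed by
joint kind (φ, ψ, χ, other → 4 polygon classes), enough to make the
physically wrong connection impossible to assemble while keeping the
number of distinct printed shapes small.

## Coordinate reconstruction

`apply_conformation()` reproduces how the physical model is manipulated:
hold one fragment (the anchor, by default the N-terminal fragment), then
walk the joint tree breadth-first away from it (ties broken by joint id),
rotating each downstream subtree rigidly about its joint axis until the
measured dihedral equals the requested value. Because every operation is a
rigid rotation, bond lengths and intra-fragment distances are preserved to
machine precision; the suite checks round trips
(`extract_conformation(apply_conformation(s)) == s`) to 1e-6 degrees over
100 seeded random conformers and per-fragment internal distances to
1e-9 Å. Angles are measured with the atan2 dihedral form (IUPAC sign, cis
= 0) and normalized to (−180, 180]; a second, independently coded
cross/dot-product implementation serves as the test oracle.

## The ideal-geometry builder

`build_ideal_peptide()` makes every other module testable without
downloads. The backbone is grown atom-by-atom by natural-extension
(NeRF) placement from fixed Engh–Huber-style bond lengths and angles
(N–Cα 1.458 Å, Cα–C′ 1.525 Å, C′–N 1.329 Å, C′=O 1.231 Å); side chains
come from a bundled internal-coordinate table derived once from ideal
residue coordinates, then are rotated onto requested χ values, so measured
torsions equal the request exactly.

Defaults are chosen once and define the conditions of all generated
fixtures:

* backbone φ = −120°, ψ = 140° (β-strand-like extension). A fully
  extended 180°/180° chain with all-trans side chains genuinely clashes at
  the 0.7 radius scale for some residue types (valine's γ-carbons against
  the preceding carbonyl oxygen; tryptophan's ring against the next
  backbone) — that is a fact about peptide sterics, not an artifact, so
  the default is the realistic extended conformation instead;
* side-chain χ at each residue's template rotamer, which is clash-free for
  all 20 types;
* ω = 180° (trans).

Partial charges are a bundled united-atom style table (hydrogen charges
folded into the parent heavy atom), Amber-flavoured, at pH 7 protonation:
aspartate/glutamate −1, lysine/arginine +1, histidine neutral. No source
names an exact charge set for this kind of model, so the table is a
documented stand-in; residue totals are exact formal charges, which is
what the charge-glyph population and the electrostatic heat maps actually
consume. vdW radii are Bondi-style per element; Lennard-Jones parameters
are Amber-style per element (ε, r_min/2). Hydrogens are excluded by
default everywhere, matching the heavy-atom physical models.

## Energetics and feasibility

Only nonbonded terms are computed — fragments are rigid, so stretch/bend
terms are constants of the model; the reported "energy" of a scan is this
nonbonded potential energy, not a free energy. Exclusions follow the
conventional Amber treatment: pairs 1 and 2 bonds apart are skipped, 1-4
pairs are scaled by divisors 2.0 (LJ) and 1.2 (Coulomb). The dielectric D
is constant (default 1). Pair r_min is the sum of the two r_min/2 values
and ε the geometric mean. Coincident atoms report +Inf with a clash flag.

Hard-sphere feasibility at `radius_scale` 0.7 is exactly the predicate
"the printed parts collide". Because 0.7·(Rᵢ+Rⱼ) is below the LJ minimum
2^(−1/6)·r_min for every element pair in the bundled tables, any
overlapping pair contributes a strictly repulsive LJ term — asserted
numerically in the suite rather than assumed.

`grid_scan()` sweeps two free torsions over the full circle; the axes are
deviations Δ from the native angles (native cell at (0, 0), always on the
grid), 18 values per axis at the default 20° increment. The electrostatic
heat map of a charged system is the `coulomb` component of the same scan.

## Template and contact scoring

`make_template()` builds the mold: a box minus the ligand's printed
spheres minus their upward sweep cylinders. The statement that the box is
"half the size" of the ligand's bounding box is ambiguous (half per axis?
half volume? which half?); the reading implemented — full footprint in the
two axes perpendicular to the pull direction, padded by the largest sphere
radius, and the **lower half of the height** along the pull axis — is the
one that makes the construction physically coherent: the mold is poured up
to the ligand's mid-height so the native chain rests in it and can be
lifted straight out. The choice is isolated in one documented function, so
an alternative reading is a local change.

Surface marks are a deterministic Fibonacci spiral per atom, with count
round(density · 4πR²), generated **on the printed spheres**
(radius_scale × vdW) and pruned against neighbours at the same scale. One
consistent scale is essential: marks at unscaled radii would sit inside
the material carved at 0.7 and the native conformation would register as
colliding, destroying the defining property of the mold.

A mark scores as a contact iff it is outside the material and within
`tolerance` (default 0.5 Å, the notional paint-film thickness) of the
**carved pocket surface** — the sphere and cylinder walls, not the box's
outer faces, because the physical procedure paints the binding pocket
only. Distances are computed analytically: candidate nearest points are
generated on every primitive surface (sphere surfaces, cylinder walls
clamped to their span, the circles where spheres meet the box floor/top,
and for the general-purpose distance also the box faces), each candidate
is validated against the CSG membership function by a probe nudged 1e-7 Å
onto its material side, and the minimum valid distance is taken. Boundary
semantics are deliberate: membership uses strict inequalities with a
1e-9 Å shell, so a point exactly on a carved surface is a touching,
non-colliding contact at distance zero. The test suite checks the whole
construction against a dense-sampling oracle (0.05 Å resolution) and
asserts exact invariance of counts under a common rigid motion of marks
and solid (`transform_template()`).

`match_profile()` applies each reported conformation holding a designated
anchor fragment at its native pose (the rigid placement rule of the
physical comparison), regenerates marks, and reports count plus a
collision flag; colliding poses are reported, flagged, never silently
dropped. Over seeded random 3-piece fixtures — one joint at each residue
boundary, pieces of comparable size like the demonstration ligands this
models — the native conformation achieves the strict maximum count
against ≥40° perturbations in ≥95% of draws; with degenerate 3-atom middle
pieces (two adjacent torsions cut) ties occur and no such property should
be expected.

## CAD emission

Scripts use a restricted primitive set (sphere, cylinder, cube, union,
difference, intersection, translate, rotate) with fixed 6-decimal
formatting, making output byte-deterministic and renderer-agnostic;
STL/G-code generation is delegated to OpenSCAD and a slicer. Default
print scale is 3.5 mm/Å, which renders a carbon sphere at the 0.7 radius
scale just over 8 mm across — comfortably hand-manipulable. Joint pins
default to 5 mm diameter and depth with 0.2 mm radial clearance on the
female hole; measurement ticks ring each female port every 20° with a
deeper index notch every third tick; charge glyphs (cross = +, bar = −)
number round(|q| / 0.1 e) per atom, spread by the same Fibonacci lattice.
`split_for_print()` intersects any solid with equal slabs so large parts
fit a small print bed; the slab union reproduces the original membership
exactly, which the suite checks on random probes.

## Problem sizes and determinism

The suite and the acceptance script run on deliberately small systems:
2–6-residue ideal peptides (≈10–40 heavy atoms), 18 × 18 scans on
tripeptides, 50 seeded fixture draws for the contact-maximality rate, and
mark densities of 0.8–2 per Å². These sizes keep every property check
exhaustive (O(n²) oracles, dense CSG sampling) while completing in
minutes. All randomness flows through explicit seeds; reruns are
bit-reproducible.

## What the synthetic fixtures do and do not show

The generator produces ideal-geometry, single-chain peptides: uniform bond
lengths/angles, no hydrogens, no solvent, no counterions, one rotamer per
side chain, and (for the worked examples) short chains. Real PDB
structures add deviations from ideal geometry, missing atoms, alternate
locations and longer-range packing, of which only the parsing aspects
(altloc selection, chain breaks, CONECT records) are exercised here by
construction. Passing tests therefore demonstrate correctness of the
kinematics, combinatorics, energetics and scoring machinery — not
biological realism of any particular fixture. Likewise the nonbonded
potential is a screening surrogate: no solvation, entropy or bonded
relaxation, so scan heat maps rank conformations rather than predict
binding free energies.

## Known limitations

* One ligand chain plus one receptor; no mmCIF, no nucleic acids.
* Side-chain hydrogens are never built; amide hydrogens only on request.
* The mold's half-height reading is one of several defensible
  interpretations (see above).
* Contact distance is exact on primitive surfaces and their box-plane
  intersection circles; distances realized only on other primitive-pair
  intersection curves can be slightly overestimated. The sampling-oracle
  tests bound the effect below the scoring tolerance on the fixtures used.
* The analysis path assumes torsion angles are reported manually (tick
  resolution); camera-based angle capture is out of scope.
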