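---
title: "Topology and energetics of a heptapeptide-bound Fe4S4 cluster: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology and energetics of a heptapeptide-bound Fe4S4 cluster: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrotopo)
```

## The scientific question

Bacterial ferredoxins bind their Fe4S4 clusters through a conserved
Cys-X-X-Cys-X-X-Cys heptapeptide.  Although the cubane cluster itself is
achiral, every experimentally determined CXXCXXC motif wraps around it with
the same, right-handed topology.  `ferrotopo` implements a model-based
analysis of why: it enumerates the conformations a minimal CGGCGGC peptide
fused to an idealized cluster can adopt, classifies each survivor's fold
handedness with a topology angle, censuses backbone-amide hydrogen bonds
to the cluster sulfurs, and estimates the electrostatic stabilization the
peptide's amide dipoles give the charged cluster.  The central result the
pipeline reproduces qualitatively is an asymmetry not of sterics but of
electrostatics: both handedness classes exist and have comparable van der
Waals feasibility, but only the right-handed fold can aim a full network of
amides at the cluster.

## The model

### Covalent geometry

All structures are built from ideal internal coordinates (bond lengths and
angles of the Engh-Huber type) stored in one editable plain-text template
file:

```{r}
tpl <- residue_templates()
tpl$lengths
```

A chain is grown residue by residue by natural-extension placement: each
atom is positioned from a bond length, a bond angle and a torsion.  Peptide
bonds are fixed trans (omega = 180 degrees); omega is not part of the
searched torsion space.  The L configuration at each alpha carbon is set by
the C-N-CA-CB torsion of -122.5 degrees and is checkable by a signed-volume
test (`is_l_configured()`).  Amide hydrogens are built explicitly at 1.01 A
in the peptide plane, anti to the carbonyl oxygen, for residues 2-7; they
exist for the hydrogen-bond census, not for the steric screen (see below).

### The cluster and the Clu residue

The idealized cubane is deliberately not a perfect cube.  Crystallographic
Fe4S4 clusters are compressed: the four Fe form a small regular tetrahedron
(Fe-Fe about 2.73 A) interpenetrating a larger sulfide tetrahedron, with
all twelve Fe-S contacts near 2.28 A.  `build_cubane()` constructs exactly
this geometry (both distances are parameters), which keeps an exact
three-fold symmetry about every centroid-Fe axis.  The model complex fuses
the cluster to the central cysteine's Sgamma (bond 2.30 A), turning residue
4 into the hybrid "Clu" residue with two extra torsions: chi2
(CA-CB-SG-Fe) and chi3 (CB-SG-Fe-S).

Because of the three-fold symmetry noted above, rotating chi3 by 120
degrees maps the idealized cluster onto itself up to atom relabeling, so
chi3 takes a single frozen value in all production grids; nothing is lost.
chi2, in contrast, genuinely reorients the cluster relative to the peptide,
and the pipeline's default grid leaves it free.  The printed-arithmetic
grid (12 backbone torsions at 60 degrees, three chi1 rotamers at
{-180, -60, 60}; chi2 and chi3 frozen) remains the `grid_spec()` default so
that the canonical state count, 3^3 x 6^12 (about 5.8e10), is reproduced
exactly; the pipeline default multiplies it by the three chi2 rotamers.
The fourth Fe coordination site is left vacant in the model: the
heptapeptide supplies only three thiolates, and adding a phantom ligand
would prejudge chemistry the model does not contain.

## The screen

A conformation survives when, for **both** terminal cysteines,

* the minimum Sgamma...Fe distance over the four irons is below 3.0 A
  (strict), and
* the CB-SG...Fe angle at that nearest iron lies in [120, 180] degrees
  (closed), and

the total 12-6 Lennard-Jones energy of the complex is strictly below
0 kcal/mol.  Comparisons are strict on the open side exactly as the cutoffs
are printed.

Two modeling choices around the LJ screen deserve emphasis:

* **Heavy atoms only.**  The enumerated models carry amide hydrogens only
  so that H...S criteria can be evaluated; the steric feasibility screen is
  a heavy-atom criterion (`lj_heavy_only = TRUE` in `filter_criteria()`).
* **Scaled radii.**  Screening discretely sampled conformations against
  full-size van der Waals radii rejects nearly everything, because a 60
  degree grid cannot relieve tenth-Angstrom strains.  Protein-design energy
  functions handle exactly this situation by scaling atomic radii, with 0.9
  the canonical factor; the shipped parameter table applies that factor via
  its `scale` directive.  With unscaled radii the same enumeration retains
  only a handful of survivors; the scaled screen retains a few thousand
  out of 1.8e11, and every downstream conclusion is about orderings within
  that ensemble, not about the absolute count.

## The staged exact search

The full grid (about 5.8e10 states, or 1.8e11 with chi2 free) is far too
large to build state by state, but the screen factorizes:

* Sgamma(1) and CB(1) depend only on chi1 of residue 1 in the fixed seed
  frame;
* the cluster pose depends only on the "prefix" torsions psi1 ... phi4,
  chi1(4), chi2, chi3;
* Sgamma(7) and CB(7) depend only on the "suffix" torsions psi4 ... phi7,
  chi1(7), expressed in the local frame of residue 4.

`run_enumeration(mode = "pruned")` therefore scans all cluster poses once,
keeps those where residue 1 can ligate (an exact test), intersects each
with a precomputed suffix table (radius prefilter, then exact distance and
angle tests), rejects pairs whose atoms overlap so severely that no
arrangement of the remaining pairs could pull the LJ total below the
cutoff (an admissible bound derived from the parameter table), and only
then assembles full states for the few million remaining candidates.  Every
elimination is either exact or provably admissible, so the survivor set is
identical to exhaustive screening; the test suite proves the equivalence on
every grid small enough to brute-force.  Survivors are reported in
lexicographic grid order with their grid index, so pruned, exhaustive and
restarted runs produce byte-identical tables.

Desk-scale alternatives: `mode = "exhaustive"` visits every state (small
grids), `mode = "subsampled"` draws a seeded uniform sample (unbiased for
ensemble statistics, but it will not find the rare screen survivors: their
density is about 1e-7).

## Topology angle

For the three motif Calpha atoms in N-to-C order, the plane normal is
`cross(ca2 - ca1, ca3 - ca1)` and theta is the angle between that normal
and the vector from the middle Calpha to the cluster centroid: 0-90 degrees
is right-handed, 90-180 left-handed, with boundaries undefined within a
configurable tolerance (default 1e-6 degrees).  Two conventions had to be
fixed: the cross-product order (chosen so that natural, right-handed
ferredoxin motifs score below 90 degrees; mirroring a structure maps theta
to 180 - theta exactly) and the cluster point (the centroid of the eight
cubane atoms; no single atom is distinguished).

## Hydrogen-bond census

Donors are the six backbone amides of residues 2-7 (the N-terminus carries
an amine, not an amide).  Acceptors are the four inorganic sulfides plus,
by default, any ligating cysteine Sgamma.  Two discrete rules are
implemented: H...S < 3.5 A with N-H...S in [120, 180] degrees, and
N...S < 3.8 A with the angle window [110, 180] degrees; the N-S rule is the
natural choice for crystallographic models without hydrogens (the reader
reconstructs amide H geometrically), the H-S rule for the package's own
models.  Counting is pair-level - one donor reaching two sulfurs counts
twice - with a `per_donor` switch, because the quantity of interest is the
number of stabilizing interactions, not of busy donors.

## Energetics

The electrostatic model is a pairwise Coulomb sum (332.06 kcal A / mol e^2)
with the cluster charges qFe = 0.6518 e, qS = -0.5552 e, qSG = -0.6042 e
and a standard amide-dipole backbone set, balanced so the cluster plus its
three cysteines carries a net charge of -1 e.  Solvent screening uses a
distance-dependent dielectric eps(r) = 4r (a constant-dielectric mode
exists).  The stabilization of the charged cluster is the difference of two
single-point energies - full charges versus cluster-sulfide charges zeroed -
so every term not touching a sulfide cancels; a rigid intra-cluster offset
remains in the difference, identical for every conformation.  Absolute
values from this screened model are deliberately not comparable to
molecular-mechanics energies with an implicit-solvent model; all assertions
in the package are about signs, orderings and gaps.

Relaxation (`relax_complex()`) is a distance-restrained Cartesian
minimization: LJ plus screened Coulomb plus harmonic restraints holding
every bonded (1-2) and angle-defining (1-3) distance at its template value,
minimized by L-BFGS with the printed stopping rule (gradient RMS below
1e-4 kcal/mol-A or 1e5 cycles).  It plays the role of removing the strain
of discrete sampling before hydrogen bonds are counted.  Ensemble
annotation (`annotate_survivors()`) measures the whole ensemble unrelaxed
in one vectorized pass, then relaxes the 50 most promising survivors per
handedness class (ranked by unrelaxed hydrogen-bond count, ties by
stabilization energy) with desk-scale settings (400 cycles, tolerance
1e-2); the per-class hydrogen-bond maxima are read from that relaxed
subset.  The ranking is a protocol choice made for tractable runtimes and
is stated in the summary outputs via the `relaxed` column.

## Ensemble post-processing

Deduplication is greedy leader clustering on best-fit heavy-atom RMSD
(superposition by least squares), radius 0.5 A, input in enumeration order
- deterministic, idempotent on its representatives, and a faithful
stand-in for the k-clustering used historically for the same purpose.
Within the pipeline it clusters the relaxed subset: duplicates arise when
distinct grid states minimize onto the same structure, so unrelaxed
survivors - distinct grid states by construction - remain singleton
clusters.  The
alpha-sheet call labels each residue alphaR (phi in (-120, 0), psi in
(-90, 30)) or alphaL (phi in (0, 120), psi in (-30, 90)) - generous
symmetric windows, because the alternation pattern, not the exact
boundaries, carries the conclusion - and requires strict alphaL/alphaR
alternation over the five interior residues.

## The synthetic fixtures

The generator builds everything the tests need without any experimental
coordinates: the idealized cubane; a right-handed cluster-binding complex
(a stored survivor of the package's own enumeration, verified at build time
to score theta in (20, 70) and to ligate all three cysteines) and its
mirror as the left-handed fixture; noisy copies; toy hydrogen-bond sets
engineered by explicit trigonometry to census exactly 0, 1, 3 and 6
contacts (each member is re-verified by an independent brute-force pass
before it is returned); and survey files - PDB renderings of handed
complexes with author renumbering and a fabricated outlier cysteine capping
the vacant iron (C-terminal for Type A, N-terminal for Type B).  What the
fixtures do not emulate: crystallographic artifacts (B-factors, symmetry
mates, more than one toy altloc case), real side chains beyond Cys/Ala/Gly,
and real cluster distortions; survey results on fixtures therefore validate
the machinery, not any claim about the Protein Data Bank.

## Problem sizes and determinism

The shipped analyses use: the full staged enumeration of the default
pipeline grid (1.8e11 states conceptually; a few million full candidates
actually built; minutes of CPU), relaxation of up to 50 survivors per
class at 400 cycles, and dedup on the relaxed representatives.  The same
protocol at larger settings (relax the full ensemble, 1e5-cycle
relaxations) changes no ordering the tests assert, only the sharpness of
the hydrogen-bond maxima.  All randomness (subsampling, fixture jitter) is
seed-derived; enumeration and annotation are deterministic, so repeated
runs are byte-identical.

## Known limitations

* The energy model is a screened Coulomb plus 12-6 with scaled radii - fit
  for orderings within the ensemble, not for absolute binding energies.
* Survivor counts are sensitive to the ideal internal coordinates and to
  the radius scale; the package documents both in editable files rather
  than claiming a canonical count.
* The survey consumes whatever file list it is given; non-redundancy
  filtering of a structure database is the caller's responsibility.
* Motifs split across chains or involving modified cysteines are skipped
  with a logged warning.
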