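---
title: "Reconstructing and measuring helical DIX-domain polymers from crystal symmetry"
author: "dixpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and measuring helical DIX-domain polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dixpol)
```

## The model

DIX domains polymerize head-to-tail: strand β4 of one ubiquitin-like
subunit forms a parallel intermolecular β-bridge with strand β2 of the
next, so a polymer is a chain of rigid subunits related by one screw
transform — a rotation by the twist ω about a common axis combined with a
translation (the rise d) along it. In a crystal the polymer is implicit:
the deposited model contains only the asymmetric unit, and the filament
appears when space-group operators and lattice translations are applied.
`dixpol` makes that reconstruction explicit and measures it.

The pipeline is a composition of five steps:

1. **Read** a structure with its crystallographic context. Unit cell and
   space group are mandatory; the supported groups (P 1, P 2₁ 2₁ 2₁,
   P 6₁) carry hard-coded fractional operators that are unit-tested for
   closure under composition modulo lattice translations.
2. **Expand** the neighborhood: every symmetry/lattice copy of every
   chain whose bounding sphere comes within a radius (default 60 Å) of an
   asymmetric-unit chain, deduplicated by generator
   (chain, operator, shift). The graph built on these copies — not the
   radius — defines the filament; the radius only bounds the search.
3. **Detect** head-to-tail edges: an edge runs from the copy engaging its
   β4 (head face) to the copy engaging its β2 (tail face) when at least
   two main-chain N···O pairs between those strands fall within 3.5 Å
   with parallel strand directionality. A path `A → B → C` therefore
   leaves A's β2 exposed (the filament's tail end) and C's β4 exposed
   (the head end). No lower distance bound is applied here: a compressed
   N···O contact still evidences the bridge, and imposing a clash floor
   was observed to fragment otherwise unambiguous filaments.
4. **Build** protofilaments as maximal simple paths (a copy with two head
   or two tail partners is non-filamentous packing and an error), then
   find inter-filament contacts — copy pairs from distinct protofilaments
   with any heavy-atom distance ≤ 4.5 Å — typed as type I (loop β1-β2
   against loop β3-β4) or type II (loop β1-β2 against the β1-β5-β3-β4
   sheet) by the dominant region pair, with ties resolved toward type I.
5. **Measure**: superpose each consecutive subunit pair (CA atoms, common
   author residue numbers), decompose each transform into screw
   parameters, average the twist with circular statistics (angles near
   the wrap-around would bias an arithmetic mean) and the rise
   arithmetically, and derive pitch = d · 360 / |ω| and subunits per turn
   = 360 / |ω|. A twist spread above 15° across pairs means the path is
   not a regular helix and is an error rather than a number.

**Handedness.** A helix is left-handed when successive subunits advance
clockwise viewed down the advance direction, i.e. when the signed twist
(right-hand rule about the rise-positive axis) is negative. At exactly
180° the sense is undefined and reported as right by convention.

**Architecture.** Classification works on the connected component (under
inter-filament contact edges) that contains the longest protofilament,
because a crystal lattice usually holds several translation-equivalent
images of the same filament that never touch each other. The component is
*double* when it holds exactly two protofilaments whose helix axes lie
within 10° of parallel and which share at least two inter-filament edges
per helical turn; *single* when it is one protofilament with no partner;
anything else is *irregular*.

**Broken-path healing.** A single sub-threshold β-bridge (one bond
stretched past the cutoff by disorder or noise) would otherwise split a
protofilament in two and misclassify a double filament as irregular. Path
fragments are therefore rejoined when the head end of one sits in atomic
contact (≤ 5 Å) with the tail end of another *and* the junction transform
matches the filament's own median screw step within 10° of twist and
1.5 Å of rise. Parallel lattice images fail both tests (their junction
transform is a pure translation and they are not in contact), so the
healing cannot fuse distinct filaments.

## Interfaces

Solvent-accessible surface area uses the Shrake–Rupley construction: each
atom's solvent-extended sphere (van der Waals radius + 1.4 Å probe) is
sampled with a deterministic golden-spiral lattice (default 960 points)
and a point is buried when it falls inside a neighbor's extended sphere.
Radii are C 1.70, N 1.55, O 1.52, S 1.80, Se 1.90, P 1.80 Å with a 1.70 Å
fallback (with warning). Two numerical choices matter:

* **Rotational invariance.** A fixed point lattice is not rotation
  invariant, so coordinates are first taken to a canonical frame: the
  principal axes of the coordinate cloud, signs fixed by the third moment
  along each axis (an orientation-independent quantity), third axis by
  right-handedness. Rotating or translating the input then changes the
  result by strictly floating-point noise. Degenerate clouds (fewer than
  three atoms, or vanishing covariance) fall back to the identity frame —
  correct because a sphere is orientation-free.
* **Tangency tie-break.** A sample point lying exactly on a neighbor's
  surface (coincident or tangent spheres, which synthetic data produce
  exactly) is assigned to the earlier atom, so duplicated atoms are not
  double-counted and two coincident atoms expose one sphere in total.

Buried surface area is reported primarily as the two-side sum
ΔASA_A + ΔASA_B, the convention that matches the ~590 Å² scale published
for compact head-to-tail DIX interfaces; the per-side mean is reported
alongside, since published values do not always state their convention.
All three SASA evaluations inside one BSA computation share a single
canonical frame (derived from the complex), which makes the buried area
of fully separated parts exactly zero rather than merely small.

Contact detectors are heavy-atom and distance-only: the crystal models in
scope (3.0 and 1.96 Å resolution) carry no hydrogens, so donor/acceptor
roles follow atom identity, and angular criteria are deliberately
omitted. Defaults: hydrogen bonds N/O···N/O ≤ 3.5 Å (with a 2.2 Å clash
floor for *inventories*; main-chain N + main-chain O pairs are flagged
`mainchain_hbond`), salt bridges Asp/Glu side-chain O to Lys/Arg/His
side-chain N ≤ 4.0 Å, hydrophobic side-chain C···C ≤ 4.5 Å aggregated per
residue pair, water bridges both legs ≤ 3.5 Å with optional two-water
chaining (depth 2) for relay cases. Site assignment depends on the
interface kind: head-to-tail interfaces split contacts into Site 1 (the
β3/loop/β4 head face against the β2-β1-β5 sheet) and Site 2 (loop β1-β2
against β3/β4); inter-filament interfaces into type I and type II as
above. The kind is auto-detected from the presence of the main-chain
β4:β2 bridge.

## Sequences

Cross-species comparisons (superposing homologous domains, the residue
pairing behind "n Cα atoms" statements) require an alignment-derived
residue map. The alignment engine is Needleman–Wunsch with affine gaps
via `Biostrings::pairwiseAlignment` (BLOSUM62, gap open 10, gap extend
0.5 — standard protein defaults; the tie-breaking among co-optimal
alignments is the library's deterministic traceback). The package owns
the identity bookkeeping: because published identity percentages rarely
state their denominator, `percentIdentity()` reports any of gap-free
columns, shorter sequence length, or alignment length. The test suite
pins the engine to an exhaustive enumeration oracle on short strings and
checks that re-scoring the emitted gapped strings reproduces the reported
score.

## What the synthetic generator emulates — and what it does not

`generateFilament()` builds the study conditions: a rigid subunit
repeated at screw positions k·(d, ω) about z, optionally a second
protofilament at a phase rotation (default 180°) and axial offset
(default d/2), isotropic Gaussian coordinate noise, and a P 1 cell. When
the twist closes a whole number of turns over the generated subunits the
c edge equals the filament repeat exactly, so lattice translation along
±c genuinely extends the filament and the crystallographic code path is
exercised end to end; incommensurate twists get padded, isolated cells.

The subunit template is engineered so that every pipeline stage has exact
ground truth:

* β2 runs tangentially at radius ~12.5 Å; the β4 amide nitrogens of three
  consecutive residues are placed so that, under the screw step, each
  sits exactly 2.9 Å from a β2 carbonyl oxygen of the *next* copy — three
  main-chain bridges whose geometry is invariant along the filament by
  construction (the placement solves `a = R_ω b + (v_xy, d)` with
  `|v_xy| = 2.9`). The fourth strand residue is pushed radially out of
  bonding range so the planted count is exactly three.
* For two-start assemblies, one type I pair (loop β1-β2 Arg NH1 against
  loop β3-β4 Asn OD1, same subunit index on the partner strand) and one
  type II pair (loop β1-β2 Asp OD1 against β5 Lys NZ, partner index k−1)
  are planted at exactly 3.0 Å by the same invariance. Their anchors sit
  at radii 6 and 13 Å and 45° apart in azimuth, with contact vectors
  aligned to the rotation chord (type I) or radial with a 2 Å axial
  component (type II): these choices keep every *reverse* relation — the
  unplanned image pairs that share the axial cancellation when the offset
  is d/2 — beyond the 4.5 Å contact cutoff for twists between 30° and 60°
  in magnitude and rises ≥ 5 Å, the supported grid.
* The remaining "body" residues are placed by seeded rejection sampling:
  a candidate backbone is accepted only if it stays ≥ 6 Å from every
  cross-strand image and ≥ 4.8 Å from every same-strand image of the
  atoms already placed (relative subunit offsets −4…4). The designed
  contacts are therefore the *only* classification-active contacts, and
  the planted inventory is exactly recoverable.
* Optional bridging waters are placed equidistant (3.0 Å) from one
  donor/acceptor atom on each side of every consecutive interface.

Determinism: the template, body placement and noise all derive from the
spec's single integer seed; fixtures are byte-stable across runs.

What passing these tests shows: the symmetry expansion, graph assembly,
screw estimation, SASA machinery and contact detectors are correct on
assemblies whose ground truth is known exactly, including under 0.2 Å
coordinate noise. What they do not show: robustness to real-protein
pathologies — alternate conformations at interfaces, missing loops,
non-ideal β-bridge geometry, waters that belong to symmetry mates, or
filaments whose axis wobbles systematically. The toy subunit is not a
protein (no Ramachandran validity, sparse atoms); only rigid-body and
contact geometry are meaningful.

## Noise bound used in the recovery tests

Each pairwise rise estimate superposes two noisy 24-atom CA sets, so its
standard error is about σ·√(2/24); the mean over m consecutive pairs is
tested against the 3-sigma bound 3σ·√(2/(24 m)). Pair estimates share
subunits and are therefore correlated, so this bound is approximate; the
observed worst-case errors across the grid sit well inside it. Twist
errors are compared through their arc displacement at the mean CA radius
(~12 Å) against three times the same bound.

## Problem sizes

The shipped tests and the acceptance script run: the full factorial
recovery grid (3 rises × 6 twists × single/double × σ ∈ {0, 0.2 Å}, 72
pipeline runs with one-turn asymmetric units of 6–12 subunits, expansion
radius 30 Å with ±1 lattice shifts), 100 random 10-point clouds for the
superposition oracle, 960-point SASA spheres, ten ≤ 20-atom toys per
contact detector, and ≤ 8-residue strings for the exhaustive alignment
oracle. These sizes keep a full run in a few minutes on one core while
covering every code path; all of them scale up by argument.

## Known limitations

* Only the three space groups above are supported; others raise a clear
  error listing the supported set. Non-crystallographic symmetry is not
  expanded.
* Contact criteria are distance-only (no angles, no hydrogens), matching
  how moderate-resolution interfaces are normally inventoried, but
  borderline contacts near the cutoffs are convention-dependent.
* Waters are taken from the asymmetric unit as deposited; water images
  under symmetry are not generated, so water-mediated inventories across
  a symmetry interface can be incomplete for real crystals.
* The β-strand residue ranges driving detection and site assignment are
  configuration, not computed secondary structure: `defaultStrandDefs()`
  ships ranges for the mouse and zebrafish Ccd1 DIX domains (author
  numbering) and for the toy subunit; other proteins need their own.
* `dimerRotationDifference()` anchors on the tail subunit by default; the
  head anchor is available and reported side by side by `runPipeline()`,
  since published rotation differences rarely state the anchor.
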