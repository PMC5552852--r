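# dixpol

Reconstruction and quantitative analysis of helical DIX-domain
homopolymers from crystal symmetry.

## The problem

DIX domains — the ~80-residue ubiquitin-like modules (five β-strands, one
α-helix) of Dishevelled, Axin and Ccd1 — polymerize head-to-tail: strand
β4 of one subunit forms a parallel intermolecular β-bridge with strand β2
of the next. In crystals these polymers appear as helical filaments
generated by the lattice symmetry, so the filament is never present as an
explicit model: it must be reconstructed by applying the space-group
operators and lattice translations to the asymmetric unit, chaining the
β-bridge interfaces into protofilaments, and measuring the resulting screw
geometry. Whether such a filament is a *single* helix or a *double* helix
of two intertwined protofilaments is biologically decisive — insertion of
the β1-β2 loop into the head-to-tail interface of a partner filament
(a zipper-like type I / type II contact system) auto-inhibits further
polymerization.

`dixpol` implements that entire analysis for structural biologists:

* **structure model** — mmCIF/PDB reading and writing with unit cell and
  space-group context (`P 1`, `P 2₁ 2₁ 2₁`, `P 6₁`), coordinate selection,
  symmetry transforms (`readStructure`, `selectCoords`, `applyOp`);
* **assembly** — crystallographic neighborhood expansion, β-bridge
  detection (≥ 2 main-chain N···O bonds ≤ 3.5 Å between the β4 and β2
  strands, parallel strand direction), protofilament building, and
  single/double/irregular architecture classification
  (`expandNeighborhood`, `detectHeadToTail`, `buildFilaments`,
  `classifyArchitecture`, `countInterfilamentNeighbors`);
* **geometry** — Kabsch least-squares superposition, pairwise RMSD
  matrices, screw-axis decomposition, per-subunit helix parameters, and
  head-to-tail dimer rotation comparison (`superpose`,
  `averagePairwiseRmsd`, `screwDecompose`, `helixParameters`,
  `dimerRotationDifference`);
* **interfaces** — Shrake–Rupley solvent-accessible surface area on a
  deterministic golden-spiral lattice, buried interface area, and typed
  contact inventories: hydrogen bonds, salt bridges, hydrophobic and
  water-mediated contacts, assigned to Site 1 / Site 2 or type I / type II
  by β-strand residue ranges (`sasa`, `buriedSurfaceArea`, `findHBonds`,
  `findSaltBridges`, `findHydrophobic`, `findWaterMediated`,
  `interfaceFingerprint`);
* **sequences** — global pairwise alignment (BLOSUM62, affine gaps) with
  percent identity under three denominators and author-numbered residue
  pairing for cross-species superposition (`globalAlign`,
  `percentIdentity`, `residuePairing`);
* **synthetic data** — a generator of crystal-structure fixtures with
  exact ground truth: a rigid toy subunit repeated along an ideal screw
  axis, optionally two intertwined protofilaments, planted interface
  chemistry, Gaussian noise, packed into a P 1 cell whose c edge equals
  the filament repeat so that symmetry expansion genuinely extends the
  filament (`filamentSpec`, `generateFilament`, `writeFixture`);
* **pipeline** — `analysisConfig` + `runPipeline` orchestrate everything
  and emit JSON/TSV reports.

## The quantities

For a filament whose consecutive subunits are related by the screw
transform (R, t), the package reports per-subunit

* **rise** `d = t · û` (Å), with û the rotation axis of R,
* **twist** `ω` (degrees, from `cos ω = (tr R − 1)/2`, signed by the
  rotation sense about the advance direction; ω < 0 = left-handed),
* **pitch** `P = d · 360 / |ω|` and **subunits per turn** `360 / |ω|`,

averaging the twist with circular statistics over all consecutive pairs.
Buried surface area is reported as the two-side sum
`ΔASA_A + ΔASA_B = SASA(A) + SASA(B) − SASA(AB)` (the per-side convention
is reported alongside).

## Worked example

Generate a left-handed seven-per-turn filament (rise 11.43 Å, twist
−360/7°), write it as a crystal, and run the full
read → expand → detect → build → measure pipeline:

```r
library(dixpol)

spec  <- filamentSpec(rise = 11.43, twist = -360/7, nSubunits = 7, seed = 42)
g     <- generateFilament(spec)
paths <- writeFixture(g$structure, g$truth, tempdir(), "demo")

s      <- readStructure(paths["pdb"])
copies <- expandNeighborhood(s, radius = 30, maxShift = 1)
edges  <- detectHeadToTail(copies, defaultStrandDefs("toy"))
fil    <- buildFilaments(copies, edges, defaultStrandDefs("toy"))
fil
#> FilamentModel: single architecture; 9 protofilament(s); 37 copies
#>   protofilament sizes: 3, 3, 2, 17, 4, 2, 2, 2, 2
#>   28 head-to-tail edge(s), 0 inter-filament edge(s)

helixParameters(fil)
#> HelixParameters: rise 11.430 A, twist -51.428 deg (left-handed),
#>   pitch 80.01 A, 7.000 subunits/turn (16 pairs averaged)
```

The 17-subunit protofilament is the filament itself, extended across the
±c cell boundaries by lattice translation; the short parallel fragments
are its translation images in neighboring lattice columns, truncated by
the expansion radius. The recovered geometry — 11.43 Å rise, −51.43°
twist, 80 Å pitch, 7 subunits per turn, left-handed — is the generator's
exact ground truth. The head-to-tail interface carries the planted
β4:β2 main-chain bridge:

```r
rep <- interfaceFingerprint(filamentCopies(fil)[["A:1:+0,+0,+0"]],
                            filamentCopies(fil)[["B:1:+0,+0,+0"]],
                            defaultStrandDefs("toy"))
rep
#> InterfaceReport: BSA 196.8 A^2 total (99.8 + 96.9); 3 contact(s)
#>    mainchain_hbond: 3
```

Adding `secondStrand = TRUE` to the spec produces a two-start
(double-helical) assembly whose interior subunits each contact two
subunits of the partner protofilament through one type I and one type II
interface.

Deposited crystal structures are analyzed the same way: point
`analysisConfig()` at mmCIF/PDB files (cell and space-group records are
required) and supply the protein's β-strand ranges —
`defaultStrandDefs("mCcd1")` and `defaultStrandDefs("zCcd1")` ship with
the package.

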