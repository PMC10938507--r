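---
title: "Enumerating and embedding stereoisomers of coordination complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating and embedding stereoisomers of coordination complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordenum)
```

## The model

A mononuclear complex is described by a central metal with a formal charge,
a coordination geometry — octahedral (`OH`, 6 donors) or square-planar
(`SP`, 4 donors) — and a list of ligands given as SMILES in which donor
atoms carry nonzero atom-map numbers. Coordination is represented by dative
donor→metal bonds, so ligand-internal valences, charges and stereocenters
are untouched by complexation; the total complex charge is simply the metal
charge plus the ligand formal charges.

A *stereoisomer* of such a complex is an assignment of the donor atoms to
the vertices of the coordination polyhedron, together with a configuration
for every donor atom that becomes a tetrahedral stereocenter on
coordination (a coordinated secondary amine is the canonical example: its
four substituents N–H, two chain arms, and the metal can be arranged in two
non-superimposable ways). Two assignments describe the same stereoisomer
when a rotation of the polyhedron, combined with a symmetry of the ligand
set itself (swapping two identical ligands, or the two identical arms of a
symmetric chelate), maps one onto the other.

### Vertex convention

All cis/trans logic in the package derives from one fixed numbering:
octahedron vertices 1..6 with trans pairs (1,6), (2,4), (3,5) — vertex 1 =
+z, 2 = +x, 3 = +y; square plane 1..4 with trans pairs (1,3), (2,4). The
choice is arbitrary but must be fixed once; every arrangement, XYZ metadata
record and classification label refers to it.

### Symmetry groups

`rotation_group()` builds the 24 octahedral rotations from two 90°
generator rotations and the 8 square-planar operations from the in-plane
90° rotation and a C2 flip, closing under composition and verifying order,
closure and inverses at construction. With `include_reflections = TRUE`
improper operations are added for enantiomer merging; improper elements are
flagged because they invert every tetrahedral parity. For the square plane
the improper operations induce no new vertex permutations (the out-of-plane
mirror fixes all four vertices), so the group doubles to 16 flagged
elements over the same 8 permutations — we count only permutation-distinct
operations when reporting the group order, and keep the parity-flipping
copies because they matter for stereocenters.

### Canonical signature sets

Deduplication uses the set-of-canonical-strings construction: for a given
stereoisomer, apply each group element to its donor-vertex labels (improper
elements also flip parities) and canonicalize the resulting vertex-colored
molecular graph; collect the strings as a set. Relabeling by any group
element permutes which string is generated by which element but leaves the
set unchanged, so two stereoisomers are equivalent **iff** their sets
intersect — and the sets of equivalent stereoisomers are in fact equal,
which lets deduplication key on the lexicographically smallest element (the
same rule provides the deterministic class representative).

Canonicalization is BLISS canonical labeling (igraph) of a graph in which
every bond is subdivided by a dummy vertex colored by bond order and
dativeness, atoms are colored by (element, charge, isotope, aromaticity,
donor-vertex label), and tetrahedral parities are appended in the canonical
frame, each re-expressed relative to the ascending canonical order of its
four neighbor indices. This makes the string invariant under arbitrary atom
renumbering, which is exactly the property the orbit argument needs. A
canonical SMILES writer would serve the same purpose; a graph-canonical
string is used because it extends naturally to the dative-bonded,
vertex-colored complex graph.

Stereocenter expansion happens **before** deduplication, so
amine-configuration isomers that coincide under a symmetry are still
merged. A donor is treated as a potential stereocenter when it is
four-coordinate counting the metal and does not carry two identical
single-atom substituents; whether it is *genuinely* stereogenic is decided
by the signature machinery itself (the two parities are emitted and merge
if equivalent), which is the only test that respects context such as the
arrangement-dependent stereogenicity of a symmetric pincer's central amine.

### Donor pinning

An isotope label from a reserved pair on a donor atom pins its
configuration instead of expanding it: isotope 11 selects parity +1,
isotope 22 parity −1, where parity +1 corresponds to `@` with the four
neighbors (metal included) taken in ascending atom order. The reserved
isotope is consumed during parsing so it never leaks into graph
comparisons. Genuine isotopes (e.g. ¹³C) elsewhere are preserved and do
distinguish stereoisomers.

## Feasibility filters

Two substructure rules remove arrangements that are chemically strained or
typically nonlocalizable:

1. **Trans-spanning short chelates.** A chelating donor pair on trans
   vertices with a through-ligand linker of at most
   `max_chelate_path_for_trans_ban` atoms (default 4, i.e. chelate rings up
   to 6-membered counting the metal) is removed. The rule is applied to
   every donor pair of every multidentate ligand, which also removes the
   bent placements of tridentates whose *adjacent* donors land trans. The
   threshold quantifies a qualitative "constrained small ring" criterion;
   4 linker atoms is the largest chain that still forces a near-linear
   donor–metal–donor fragment into a small ring.
2. **Facial rigid tridentates.** A tridentate ligand whose donor–donor
   linker paths consist entirely of aromatic or sp²-in-ring atoms
   (terpyridine-like) cannot fold facially; its fac placements are removed.
   Rigidity is a structural predicate, deliberately conservative — no
   energetics are estimated.

Both rules are heuristics and can discard isomers within roughly 10 kJ/mol
of feasible ones, so each has an off switch, the defaults are prominent in
the CLI, and removed stereoisomers are always returned with a reason rather
than silently dropped. When screening a new system it is advisable to run
once with the filters off.

## 3D embedding

Each stereoisomer is turned into coordinates by bounds-matrix distance
geometry:

* metal–donor target distance d = sum of tabulated single-bond covalent
  radii, with a ±10 % tolerance (`metal_donor_tol`) — the radii sums
  reproduce typical M–L bond lengths to within the tolerance;
* donor–donor targets follow from the vertex geometry: cis pairs at
  √(d₁²+d₂²), trans pairs at d₁+d₂ (±8 %);
* bonded pairs at covalent-radius sums (±4 %), 1–3 pairs by the law of
  cosines over idealized angles (109.47°/120°/180° by hybridization, 90°
  and 180° at the metal), all other pairs at generic repulsive lower
  bounds;
* the matrices are triangle-smoothed (Floyd upper bounds, inverse-triangle
  lower bounds); a contradictory pair after smoothing marks the
  stereoisomer *nonlocalizable* — reported, not raised, because absence of
  a geometric solution is itself the result (such configurations are
  interpreted as exceptionally high energy);
* random distances are drawn uniformly within the bounds, embedded via the
  metric-matrix eigendecomposition, and refined by L-BFGS against the
  bounds-violation error with signed-volume restraints holding every
  tetrahedral parity (parity +1 ⇔ negative volume over the
  ascending-ordered substituents, the `@` sense).

The realized arrangement is then **verified**: every donor–metal–donor
angle is classified cis below 135° and trans at or above it (the midpoint
of the ideal 90°/180°), and the classification must match the intended
vertex assignment pair-by-pair. Verification runs both before and after
relaxation — embedding errors and relaxation drift are different failure
modes and both discard the conformer.

Relaxation uses a harmonic force field assembled in the package: bond
stretches at covalent-radius equilibria (dative bonds get their own
generic force constant), angles at idealized equilibria with 90°/180° at
the metal, purely repulsive nonbonded terms beyond three bonds, planarity
restraints on sp² centers, the same parity restraints, and **no torsional
terms across dative bonds** (zero barrier — the conventional supplement
where dative parameters are undefined). Energies are in arbitrary units
and comparative only; the minimizer never returns a higher energy than its
input, and these structures are starting points for quantum-chemical
optimization, not final geometries.

Each requested conformer retries embedding up to 10 times with derived
sub-seeds; all randomness flows from the user seed, so a (stereomer, seed)
pair reproduces bitwise-identical coordinates. The default of 5 conformers
per stereoisomer matches a typical screening protocol for pincer
complexes.

### Fixed-stereochemistry mode

With `fixed = TRUE` the atom-map numbers are read as explicit vertex
indices and the single requested arrangement is embedded without any
search. Two donors on vertices 1 and 6 give a linear fragment, five donors
a square pyramid — both as partial octahedra whose unoccupied vertices
simply carry no constraints.

## What the fixtures emulate — and what they do not

The test suite runs entirely on generated ligands: six distinct
monodentates (CO, hydride, MeCN, chloride, ammine, aqua), flexible and
rigid bi-/tridentates, a model XNX pincer whose central secondary amine is
a coordination-induced stereocenter, and a 14-member combinatorial pincer
family (NNN/PNP/SNS arms with R = Me, iPr on N and S and Me, iPr, Ph on P,
on pyridine and aliphatic-amine backbones). These cover the discrete
structure of the problem — denticity, symmetry, rigidity, stereocenters —
which is what the enumeration logic sees. They do not cover
crystallographic bond-length diversity, polyhaptic or π-bound ligands,
Jahn-Teller distortions, or counterions; a green suite therefore certifies
the combinatorics and the geometric contracts, not force-field accuracy on
real complexes.

Randomized property tests compare the deduplicated count against an
independent brute-force oracle that never canonicalizes: it BFS-computes
orbits of the explicit group action on raw placements, using graph
automorphism generators for the ligand-symmetry part, and cross-checks with
Burnside's lemma where no stereocenters are present. The acceptance suite
runs 200 such randomized multisets; the embedding contract is exercised on
all 30 monodentate stereoisomers, the XNX pincer complex and the six
methyl-substituted members of the combinatorial pincer family (spanning all
three arm types, both backbones and all three metals) at 5 conformers each
— the methyl subset keeps the suite proportionate while retaining every
structural class of the family.

## Numerical choices and degenerate inputs

* Ties in deduplication are broken by the lexicographically smallest
  canonical string; class representatives are therefore deterministic
  across runs and platforms.
* Eigendecomposition of the metric matrix takes the top three eigenvalues
  clamped below at 10⁻⁴ to survive near-degenerate distance samples.
* `verify_arrangement` with fewer than two donors is vacuously true
  (nothing to classify in a linear fixed build beyond its single pair).
* Unknown elements fail fast with a "no covalent radius" error at bounds
  construction, before any optimization.
* SMILES directional bonds (`/`, `\`) are accepted but double-bond
  geometry is not modeled; disconnected SMILES and wildcard atoms are
  rejected.

## Known limitations

π-bonding and polyhaptic ligands are unsupported (a donor is a single
atom), as are polynuclear complexes — a ligand containing a metal atom is
rejected as not mononuclear-compatible, which also settles what to do with
would-be bridging donors. Trigonal-bipyramidal and tetrahedral geometries
are out of scope; 2- and 5-coordinate structures exist only as partial
octahedra in fixed mode. The force field is a generic harmonic surrogate:
adequate for producing verifiable starting structures, not for ranking
conformer energies beyond gross comparisons. Highly symmetric cage
multidentates can exhaust the embedding retries and come back
nonlocalizable even when a structure exists.
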