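---
title: "Interaction-pattern screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-pattern screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipscreen)
```

## The screening model

Brivudine (BVDU), a thymidine analogue, binds its kinase targets through
a characteristic arrangement of noncovalent contacts: its nucleobase
ring stacks against protein aromatic rings, a pair of roughly
antiparallel hydrogen bonds anchors the base edge, and the deoxyribose
and bromovinyl moieties make contacts at characteristic distances from
the base ring. ipscreen encodes this arrangement as ten boolean
interaction patterns evaluated per protein--ligand complex:

| Pattern | Definition | Extra geometric constraint |
|---|---|---|
| A | stacked aromatic ring in the ligand (base ring) | — |
| B | double π-stacking to the base ring | — |
| C | double π-stacking on opposite faces | — |
| D | double π-stacking, both parallel-type | — |
| E | double hydrogen bonds to the base-ring moiety | — |
| F | double hydrogen bonds to a shared residue | — |
| G | double hydrogen bonds in parallel | angle 180° ± 18° |
| H | distal hydrophobic contact | 4.0 Å < x < 6.5 Å |
| I | distal hydrogen bond | 5.4 Å < x < 6.1 Å |
| J | distal halogen bond | 7.8 Å < x < 9.2 Å |

Here *x* is the distance from the ligand-side interaction anchor (the
hydrophobic carbon, the hydrogen-bond anchor, the halogen atom) to the
base-ring centroid, and the bands are strict inequalities. Pattern A is
prerequisite to everything else: every pattern is defined relative to a
ligand aromatic ring that participates in at least one π-stacking
interaction. The implications B,E,H,I,J ⇒ A, C,D ⇒ B and F,G ⇒ E hold
by construction, and a complex's score is the pattern count of its best
single base ring (patterns are never pooled across rings, since every
definition is anchored to one ring).

A collection of structures is screened complex by complex; when a
ligand occurs in several complexes the complex with the most patterns
represents it. Compounds with six or more patterns are reported as
hits, following the rationale that ranking by pattern count — rather
than filtering on a fixed consensus — retains compounds that realize
strong but partial matches.

## Interaction detection

Four detectors produce the interactions the patterns consume. The
thresholds default to the documented standard settings of the PLIP
family of interaction profilers and are all configurable
(`interaction_config()`):

* **Hydrogen bonds** — donor–acceptor heavy-atom distance ≤ 4.1 Å.
  When explicit hydrogens are present the donor angle is measured at
  the hydrogen (≥ 100°). PDB entries rarely include hydrogens, so
  without them a heavy-atom surrogate is used: the largest
  neighbor–donor–acceptor angle must be ≥ 90°, which discards only
  geometries where the acceptor sits behind the donor's covalent
  frame. A donor with no bonded neighbor (e.g. a free hydroxyl probe)
  imposes no angular restriction. Both donation directions across the
  interface are searched and the two directions of one atom pair are
  collapsed to the better-angle one.
* **Hydrophobic contacts** — carbon atoms bonded only to carbon or
  hydrogen, ligand × protein, distance ≤ 4.0 Å; per ligand atom only
  the nearest protein partner is kept, which keeps packed apolar
  pockets from inflating contact counts (hydrogen bonds and stacks are
  naturally sparse, so no collapsing is applied there).
* **π-stacking** — ring centroid distance ≤ 5.5 Å and lateral offset
  ≤ 2.0 Å (the smaller of the two centroid-projection offsets). The
  planar angle between ring normals, folded into [0°, 90°], classifies
  the stack: ≤ 30° parallel, ≥ 60° T-shaped; intermediate tilts are
  discarded. The face sign records which side of the base-ring plane
  holds the partner centroid; a centroid exactly in-plane gets sign 0
  and never counts toward face opposition (pattern C).
* **Halogen bonds** — ligand Cl, Br or I (F excluded by default, as
  its σ-hole is marginal) against protein O/N/S acceptors, distance
  ≤ 4.0 Å, C–X···A angle within 165° ± 30°, Y–A···X angle within
  120° ± 30° for some covalent neighbor Y of the acceptor.

Detection thresholds are inclusive, while the pattern bands of Table
form are strict — the two conventions are kept deliberately distinct
because the pattern definitions print strict inequalities.

### Heavy-atom capability typing

Without hydrogens, donor/acceptor capability is inferred from element,
connectivity and bond length: an oxygen with a single heavy neighbor
closer than 1.32 Å is carbonyl-like (acceptor only), at 1.32 Å or more
hydroxyl-like (donor and acceptor); an aromatic ring nitrogen without
hydrogen is pyridine-like (acceptor only), with three ring/substituent
connections it is neither; an sp³ nitrogen with at most two heavy
neighbors is treated as amine-like (donor and acceptor). These
surrogates can differ from a protonation engine on borderline cases —
notably, a pyrrole-type NH with the hydrogen stripped is
misclassified as an acceptor — which is a known limitation of
heavy-atom operation. Covalent bonds are inferred by the
covalent-radius rule (distance ≤ r₁ + r₂ + 0.45 Å) and supplemented by
CONECT records when present.

### Pattern G direction convention

Pattern G uses directed donor→acceptor vectors. BVDU's paired bonds
run antiparallel — the ligand donates one bond and accepts the other —
so two bonds qualify when their direction vectors subtend an angle
within 180° ± 18° (i.e. ≥ 162°). Using undirected lines would also
admit genuinely parallel same-sense pairs, which the reference
geometry does not show.

## Structure handling

PDB (and mmCIF) files are read through bio3d. Only the first model of
multi-model entries is used; alternate locations are resolved to the
highest-occupancy conformer with ties going to altloc A; residue
numbering is taken verbatim. Ligands are hetero residues excluding
water, one selection per residue instance, optionally intersected with
a BioLiP-style allowlist — the biological-relevance decision is
consumed as data, never recomputed. The binding site is carved at an
atom-level 7.5 Å cutoff (the reference profiler's default), and
aromatic rings are perceived as the smallest 5- or 6-cycles of C/N/O/S
atoms planar within 0.15 Å — wide enough for nucleobases, phenyl and
imidazole, tight enough to reject puckered cyclohexane. Ring normals
are sign-canonicalized (positive z, then x, then y component) so they
are independent of atom input order; quantities derived from them that
are frame-dependent (the face sign) are only ever used through
frame-invariant relations (opposition).

## The synthetic fixture generator

Real reference complexes cannot ship with the package, so the ground
truth for every pipeline stage is generated: `build_fixture(S)` emits a
PDB-format binding site whose best evaluation is exactly the requested
implication-closed pattern subset S. The ligand is a geometric test
article, not a synthesizable molecule: a planar pyrimidine-like
six-ring (so ring perception, pyridine-type nitrogen typing and
stacking all operate on nucleobase-like input), an exocyclic carbonyl
oxygen and amine nitrogen forming the paired hydrogen-bond edge, an
aliphatic arm ending at the distal-hydrophobic band midpoint (5.25 Å),
a bromine arm ending at the distal-halogen midpoint (8.5 Å) and a
hydroxyl arm at the distal-hydrogen-bond midpoint (5.75 Å). Protein
partners are plausible residues (imidazole rings, Gln/Ser
donor–acceptor pairs, Leu carbons, backbone-like carbonyls) placed
only for requested patterns:

* the base stack is a parallel imidazole 3.5 Å above the ring plane;
* pattern C places the second ring below the plane (T-shaped, or
  parallel when D is also requested);
* B without C or D uses an edge-to-face ring lying exactly in the
  ligand plane: its face sign is exactly 0, so neither C nor D can
  fire. A second ring on the occupied face cannot be placed within the
  5.5 Å centroid budget without colliding with the base ring at
  covalent distances (which would fuse the rings during bond inference
  and destroy perception) — the in-plane placement sidesteps this, and
  the same constraint is why the same-face double-parallel variant
  (B,D without C) stacks its second ring directly above the first with
  a 1.9 Å gap and a 36° twist so the atoms interleave;
* pattern G is toggled purely by the direction of the amine's
  acceptor partner: antiparallel to the carbonyl's donor bond (170°)
  when requested, at 120° otherwise; F is toggled by placing both
  partners in one glutamine residue versus splitting them over
  Gln/Ser.

When a distal pattern is not requested its protein probe is simply
omitted rather than moved outside the band: an out-of-band hydrophobic
probe near the arm would inevitably contact in-band arm atoms and turn
the pattern back on. Band strictness is instead exercised by direct
unit tests at the boundary values (4.0, 6.5, 5.4, 6.1, 7.8, 9.2
exactly) and, naturally, by the base-ring hydrogen bonds whose anchors
(x ≈ 2.6 Å) fall outside the distal bands in every fixture containing
E.

`fixture_library(n, seed)` cycles deterministically through all 201
closed subsets, jittering the stack distance (± 0.1 Å), hydrogen-bond
length (± 0.05 Å) and distal radii (± 0.2 Å for H and J; ± 0.05 Å for
I, whose hydroxyl arm has a geometric reach of 5.82 Å) while keeping
at least 0.1 Å of margin inside every strict band.

What the fixtures do *not* emulate: conformational strain, crystal
packing, solvent, protonation ambiguity, partial occupancy or atoms
with marginal geometry. A perfect score on the fixture suite therefore
demonstrates that the geometric definitions are implemented exactly,
not that the thresholds reproduce any particular published screen on
borderline real-world geometries — the original work never printed its
effective thresholds, so agreement on marginal cases cannot be
guaranteed from the publication alone.

## Prioritization

Chemical similarity is Tanimoto similarity on ChemmineR atom-pair
descriptors computed from user-supplied SMILES; this replaces the
retired PubChem score-matrix web service, so absolute values differ
from the original heatmap while the grouping behavior (nucleobase
scaffolds cluster together, unrelated scaffolds stand apart) is
preserved. Compounds are grouped by scaffold label (assigned by the
user, as in the original manual assignment) and ordered within each
group by average-linkage hierarchical clustering on distance
1 − similarity; scaffold groups are ordered alphabetically and members
pre-sorted by id, making the leaf order deterministic under input
permutation.

The repositioning matrix aggregates user-supplied compound–target
evidence pairs onto a drug-class × target-superfamily grid; a cell is
*structural* if any mapped pair has structural evidence, else *other*
if any pair has other evidence (structural dominates, making cells
single-kind and the coverage percentages additive). Coverage is
reported to one decimal and as the nearest integer: on a 19 × 23 grid
with 41 structural and 81 other cells this yields 437 cells, 9.4 %
(prints as 9 %), 18.5 %, and 27.9 % combined (prints as 28 %).

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
input: the exhaustive round-trip covers all 201 closed subsets, the
property fuzz uses 1000 random evaluation contexts, and the end-to-end
screen uses a 100-structure library — sizes chosen so the whole suite
exercises every code path in about a minute on one CPU. All randomness
(jitter, fuzz, rigid motions) flows from fixed seeds; identical input
and configuration give byte-identical fixtures and reports.

## Known limitations

* Heavy-atom surrogates for donors/acceptors differ from a protonation
  engine on tautomer-ambiguous and stripped-hydrogen cases.
* The distal distance *x* is measured to the base-ring centroid; the
  choice of reference point (centroid versus nearest ring atom) is not
  fixed by the pattern table and shifts borderline hits.
* Pattern E accepts hydrogen bonds anchored on ring atoms or atoms
  covalently bonded to a ring member; a proximity-based moiety
  definition would admit slightly different bond sets.
* No water bridges, salt bridges, π-cation or metal coordination are
  detected — no pattern consumes them.
* Only the first model of NMR-style multi-model files is evaluated,
  and no assembly/symmetry expansion is performed.
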