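# ipscreen

Interaction-pattern screening of protein–ligand complexes for
structure-based drug repositioning.

## The problem

A drug can be repositioned to a new indication by finding other
compounds that *interact* with their targets the way the drug does —
even when those compounds share neither scaffold with the drug nor
sequence with its targets. The antiviral brivudine (BVDU), a thymidine
analogue with anticancer activity, binds its kinase targets through a
distinctive arrangement of noncovalent contacts: its nucleobase ring
π-stacks with protein aromatic rings, a pair of antiparallel hydrogen
bonds pins the base edge, and hydrophobic, hydrogen-bond and halogen
contacts occur at characteristic distances from the ring. ipscreen
encodes this arrangement as ten boolean patterns A–J, detects the
underlying interactions geometrically in any PDB/mmCIF structure, and
ranks the ligands of a structure collection by how many patterns they
realize.

The patterns, all defined relative to one stacked ligand aromatic ring
(the *base ring*, pattern A):

| | Pattern | Constraint |
|---|---|---|
| A | base ring: stacked aromatic ring in the ligand | – |
| B | double π-stacking to the base ring | – |
| C | … on opposite faces | – |
| D | … both parallel-type | – |
| E | double hydrogen bonds to the base-ring moiety | – |
| F | … to a shared residue | – |
| G | … in parallel | angle 180° ± 18° |
| H | distal hydrophobic contact | 4.0 Å < x < 6.5 Å |
| I | distal hydrogen bond | 5.4 Å < x < 6.1 Å |
| J | distal halogen bond | 7.8 Å < x < 9.2 Å |

with *x* the distance from the ligand-side anchor to the base-ring
centroid (strict bounds). A complex scores the pattern count of its
best base ring; a ligand scores its best complex; compounds with ≥ 6
patterns are hits. Detection thresholds (hydrogen bond ≤ 4.1 Å,
hydrophobic ≤ 4.0 Å, stacking ≤ 5.5 Å / offset ≤ 2.0 Å, halogen
≤ 4.0 Å with angular windows) follow the documented defaults of the
PLIP family of interaction profilers and are configurable.

The package also covers the downstream prioritization steps: Tanimoto
chemical-similarity clustering within user-assigned scaffolds, and a
drug-class × target-superfamily "repositioning matrix" that grades
each cell by structural versus other binding evidence, with coverage
statistics.

## Worked example

Everything below runs without downloads: the package generates
synthetic binding sites realizing any implication-closed pattern
subset, which are its ground truth.

```r
library(ipscreen)

# a complex realizing the stacking sandwich + distal contacts,
# but no paired hydrogen bonds (an amodiaquine-like signature)
fx <- build_fixture(c("A", "B", "C", "D", "H", "J"))
ev <- evaluate_fixture(fx)
ev$flags
#>     A     B     C     D     E     F     G     H     I     J
#>  TRUE  TRUE  TRUE  TRUE FALSE FALSE FALSE  TRUE FALSE  TRUE
ev$count
#> [1] 6

# screen a small synthetic collection and rank ligands
dir <- file.path(tempdir(), "lib")
write_fixtures(fixture_library(24, seed = 1), dir)
scores <- screen_collection(list.files(dir, full.names = TRUE))
report <- rank_and_annotate(aggregate_by_ligand(scores), min_count = 6)
report
#> Interaction-pattern screen: 24 ligands, 0 hits with >= 6 patterns
#> Count histogram (0-10): 1 1 4 7 7 4 0 0 0 0 0
#>    rank component_id best_count A B C D E F G H I J best_structure ...
#> 1     1          L0G          5 1 0 0 0 1 0 0 1 1 1         FX0017
#> 2     2          L0K          5 1 0 0 0 1 1 0 0 1 1         FX0021
#> ...
```

The flags line reads: the complex realizes the base ring (A), a double
π-stack on opposite faces in parallel orientation (B–D), a hydrophobic
contact 4.0–6.5 Å from the ring centroid (H) and a halogen bond
7.8–9.2 Å from it (J) — six patterns, no base-edge hydrogen bonds
(E–G false). In the screen report, each row is one ligand with its
best complex's flags; the histogram counts ligands per pattern count.

Real structures go through the same calls —
`parse_structure("1abc.pdb")`, `select_ligands()` (optionally with a
BioLiP-style allowlist), `build_binding_site()`, `profile_complex()`,
`best_evaluation()` — or in one step through the command line:

```sh
exec/ipscreen patterns my_complex.pdb
exec/ipscreen screen --input pdb_dir --allowlist biolip.tsv \
    --drugs ttd.tsv --min-count 6 --out report.tsv
exec/ipscreen fixtures --set ABCDHJ --out fx.pdb
```

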