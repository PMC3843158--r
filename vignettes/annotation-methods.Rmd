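---
title: "Methods: perception, matching and decomposition in ccannotate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perception, matching and decomposition in ccannotate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccannotate)
```

## The problem

A deposited macromolecular structure carries, besides its polymer chains,
an arbitrary collection of small molecules: ions, solvents, sugars,
inhibitors, modified residues. Before such an entry can be archived, each
of those *instances* must be identified against a reference catalogue of
chemical component definitions (1–3 character codes, named atoms, bonds
with orders, stereo assignments, idealized coordinates), or flagged as a
new chemical entity. The experimental coordinates carry no bonds, no bond
orders and no stereo labels — all of that must be perceived from geometry —
and ligands are frequently covalently attached to the polymer, so part of
their free-form chemistry (a leaving group) is missing from the model.

`ccannotate` implements this workflow as a library plus a thin command-line
script: dictionary and entry I/O, geometric perception, isomorphism-based
candidate search with a five-category composite score, leaving-group
capping, peptide-like decomposition ("chopping"), definition editing, and a
batch report. A deterministic fixture generator stands in for the real
reference dictionary so the whole pipeline is testable offline.

## Perception from 3D coordinates

**Bonds.** Two non-metal heavy atoms are bonded iff their distance is at
most the sum of their single-bond covalent radii (Cordero's values) plus a
tolerance of 0.40 Å. Contacts from a metal to N, O or S within 3.0 Å are
recorded as *coordination* contacts, never covalent edges: a zinc site must
not fuse its ligands into one instance. Hydrogens, when present in the
input, are excluded from the chemical graph ("heavy atoms" throughout means
non-hydrogen).

**Bond order.** An edge's order is classified from its length against
midpoints between the sums of single-, double- and triple-bond radii
(Pyykkö's multiple-bond radii). For C–C the single/double midpoint sits at
1.435 Å, so aromatic rings (~1.39 Å) read as alternating or all-double
bonds; the subsequent aromaticity pass replaces them with a dedicated
`aromatic` order so kekulization never has to be compared. Triple bonds are
only classified for C/N/O pairs — for S and P the double and triple radii
sums are nearly coincident and a misread would be likely.

**Hybridization.** A centre with three neighbours is sp2 iff the sum of its
three bond angles reaches 355° (an ideal tetrahedron gives 328.5°, a planar
centre 360°; 355° tolerates experimental noise while still catching a
flattened anomeric carbon). Four neighbours give sp3; two neighbours
classify by the single angle (≥160° sp, ≥115° sp2, otherwise sp3) so that
ring CH carbons in benzene (120°) and cyclohexane (109.5°) separate
cleanly; fewer than two give "other".

**Canonical ranks and handedness.** Atom ranks are computed by Morgan-style
iterative refinement seeded with (element, heavy degree) and refined by
sorted neighbour-rank multisets to a fixed point; they are invariant under
relabeling. For every sp3 atom with ≥3 heavy neighbours of pairwise
distinct ranks, the handedness *parity* is the sign of the determinant of
the vectors to the three highest-ranked neighbours taken in rank order.
Parity is deliberately not an R/S label: it is compared between instance
and definition computed identically on both sides (the definition's parity
comes from its idealized coordinates), which makes the comparison
convention-independent. Centres with duplicated neighbour ranks are treated
as non-stereogenic rather than guessing a tie-break.

**Aromaticity.** Smallest rings are found per edge (shortest cycle through
each bond); each ring of five or more atoms is Hückel-tested with a small
π-contribution table: an atom in a ring double bond contributes 1; ring
N/O/S without a ring double bond contribute a lone pair (2); ring carbon
with an exocyclic double bond contributes 0; a ring sp3 atom fails the
ring. Rings with 4n+2 π electrons mark their atoms aromatic and their bonds
order `aromatic`.

## Matching and the composite score

Candidate generation requires full heavy-atom, element-labeled graph
isomorphism, prescreened by element-count vectors through the dictionary
index. Isomorphisms are enumerated with igraph's VF2; a brute-force
all-assignments matcher exists in the test suite as an independent oracle
and is never the implementation path. Two reference graphs exist per
definition: the full form and, when leaving-flag atoms are present (the
anomeric hydroxyl of a sugar, the OXT of an amino acid), the linked/polymer
form with those atoms removed — this is what lets a glycosylated sugar or a
polymerized residue still match exactly. Only if the strict pass finds
nothing is a fallback induced subgraph-isomorphism pass tried
(instance ⊆ definition), which handles unobserved atoms; unmapped
definition atoms then count as mismatches.

The composite score compares an instance with one candidate in five
categories, each `100 × matched / eligible` with the eligible set taken
from the definition side (the only reading consistent with a 4-of-5
stereocentre comparison printing 80%): heavy atoms (element identity under
the mapping), chiral-centre count (independent of handedness), handedness
(among centres chiral on both sides), aromatic atoms, and bond order
(per-atom incident order multisets, aromatic as its own order). An empty
eligible set reports "n/a", never 0 or 100.

When a molecule admits several isomorphisms (benzene has twelve), the
mapping that maximizes handedness then bond-order matches is kept, with
remaining ties broken by the lexicographically smallest definition-index
sequence — determinism matters more than which symmetric copy is chosen,
because the score is the same for all tied mappings.

Candidates are ranked by (1) deposited-code equality *with* exact
chemistry, then (2) mean of the defined categories, (3) handedness, (4)
code. The match status is `passed` only when the top hit is chemically
exact *and* carries the deposited code — an instance deposited under the
wrong code is a `close match` even when every category reads 100, because
the annotator's action (fix the code) differs from the no-action of
`passed`. `no match` means the candidate list is empty and a new definition
is needed.

## Covalent environment and leaving groups

Inter-residue contacts are classified with the same covalent/coordination
rules and reported as linkage records; instances remain per-residue (the
linkage records, not residue fusion, carry multi-residue connectivity).
For each covalent linkage the instance is augmented with a cap along the
direction to the former partner: a hydroxyl oxygen at 1.43 Å when the
attachment atom is carbon, an implicit hydrogen when it is nitrogen or
oxygen. Capping appends — it never moves an existing atom — and the capped
instance is re-perceived, so an anomeric carbon that lost its substituent
to a glycosidic bond becomes a defined stereocentre again. If the centre is
geometrically flattened, sp2 classification takes precedence and it stays
non-stereogenic, which is exactly the behaviour wanted for a distorted
deposition.

## Chopping peptide-like ligands

Default cleavage bonds are acyclic C–N bonds where either (a) the carbon
bears a double-bonded oxygen (a true amide), or (b) the carbon is attached
to a free-carboxyl carbon and the nitrogen is a secondary, non-amide amine.
Rule (b) is deliberately narrower than "any N next to a carbonyl": stated
that loosely it would also cut the internal Cα–N bond of a lysine inside a
lisinopril-type backbone and the terminal Cα–N of a tripeptide. As
implemented, a lisinopril-like parent selects exactly its two pseudo-peptide
bonds, a triglycine its two amides, and a free amino acid nothing; the
selection is only a default the caller may edit. Ring membership is tested
on the bond, not the nitrogen, so amides to proline-type ring nitrogens are
cleavable.

Cutting removes the bonds, caps the carbon side with –OH and the nitrogen
side with –H (implicit), producing each fragment in its free neutral state;
fragments are matched like any instance and ordered by following the
cleaved C→N bonds from the unique fragment that is never a nitrogen-side
endpoint (the free N-terminus — or, for a fragment with no backbone
nitrogen at all, the head of the chain). Cyclic backbones start at the
lexicographically smallest top hit; `reverse` and `rotate:k` permute the
*current* order, so reversing twice is the identity. Applying a
decomposition in polymer mode replaces the parent residue with sequential
residues named through each fragment's top-hit mapping, caps excluded; in
subcomponent mode the parent stays and the ordered code list is recorded.

## Editing and implicit hydrogens

Definitions use kekulized integer orders with aromatic flags, CCD-style.
Implicit hydrogens are the smallest allowed valence state (C 4; N 3; O 2;
S 2/4/6; P 3/5; halogens 1; metals 0; formal charges shift the state — N⁺
4, O⁻ 1) minus the explicit bond-order sum; any edit that exceeds every
allowed state is rejected. Changing a bond order therefore moves implicit
hydrogens at both ends automatically, and adding an explicit hydrogen
decrements its partner's implicit count. Atoms added by editing receive
placeholder idealized positions from local tetrahedral/trigonal templates
around their anchor; full molecular re-embedding is intentionally out of
scope, so edited definitions are flagged `ideal_approximate`. Committing a
definition runs a redundancy check (isomorphism with all categories at 100)
against the dictionary first.

## The fixture generator, and what it does not emulate

`make_toy_dictionary()` builds seventeen definitions from ideal geometry —
tetrahedral 109.47°, trigonal 120°, canonical bond lengths, chair and
planar-ring templates — including a five-stereocentre pyranose with its C1
anomer, a lisinopril-like parent assembled by rigidly attaching the free
residue templates (so fragment parities equal template parities by
construction), and a triglycine. Two deliberate geometry choices keep
length-based order classification unambiguous: amide C–N bonds are built at
1.45 Å so they classify single (their kekulized order), and the pyranose
ring/anomeric bonds are built slightly long (1.55/1.46 Å) because
flattening the anomeric carbon shortens its bonds by up to 0.08 Å and must
not push any of them across a classification midpoint.

`make_entry()` places seeded, rigidly rotated copies at 25 Å spacings with
a uniform coordinate jitter of ±0.005 Å (configurable up to ±0.05 Å) and
applies perturbations to coordinates and labels only: flattening moves a
stereocentre toward its neighbour plane until the angle sum reaches 358°;
parity inversion reflects a terminal substituent through the plane of the
centre and its other neighbours (epimerization — axial↔equatorial — which
leaves every other centre untouched); bond-order changes re-scale one bond
to the other order's canonical length; plus atom renaming, code
relabeling, atom deletion, and glycosylation-style attachment of an
asparagine-like polymer residue.

What passing tests on these fixtures shows is that the *rules* are
implemented correctly and consistently with each other. What they do not
show: robustness to real crystallographic noise (B-factors, genuinely
distorted geometry near the classification midpoints), alternate
conformers beyond the single-conformer rule (highest occupancy, ties
alphabetical), charged/tautomeric chemistry perceived from geometry (formal
charges are taken as stated, never perceived), and macrocyclic peptides
with exotic residue chemistry. Real dictionary files remain readable
because unrecognized mmCIF categories are ignored, but only the
`chem_comp`, `chem_comp_atom` and `chem_comp_bond` categories are
interpreted.

## Numerical choices and degenerate inputs

All thresholds live in one place: bond tolerance 0.40 Å, metal coordination
cutoff 3.0 Å, sp2 planarity 355°, sp/sp2/sp3 two-neighbour angle cuts
160°/115°, cap lengths 1.43 Å (C–O) and 1.01 Å (N–H, implicit). Parity
determinants below 10⁻⁶ (numerically planar centres) are treated as
non-stereogenic. Ring perception caps ring size at 8 for aromaticity and
12 for cleavage-bond screening. Problem sizes are deliberately small —
definitions of 1–29 heavy atoms, entries of up to a few hundred atoms — and
the exhaustive test oracle is run only on pairs of at most 12 heavy atoms;
the full suite and the acceptance script each complete in well under a
minute on one CPU.

Degenerate inputs are errors, not silent defaults: unknown elements, bonds
naming missing atoms, duplicate codes or atom names, stereo flags on
under-coordinated atoms, valence-overflowing edits, cleaving a ring bond
that does not open a macrocycle, ordering a branched decomposition, and
capping an attachment atom already at full valence.
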