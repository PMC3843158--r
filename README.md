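# ccannotate

Chemical component annotation for macromolecular structure entries.

When a structure is deposited to an archive, every small molecule in it —
ions, solvents, sugars, inhibitors, modified residues — must be identified
against a reference dictionary of chemical component definitions, or
flagged as a new chemical entity that needs a definition of its own. The
experimental coordinates carry no bonds, no bond orders and no stereo
labels, and ligands are often covalently attached to the polymer, so part
of their free-form chemistry is missing. `ccannotate` implements this
annotation workflow for R:

* **I/O** — a minimal PDBx/mmCIF `chem_comp` dictionary reader/writer and a
  PDB/mmCIF coordinate reader/writer (`read_dictionary()`,
  `read_entry()`, ...).
* **Perception** — bonds and bond orders from covalent radii, hybridization
  from bond-angle sums, canonical atom ranks (Morgan refinement),
  chirality *parity* as the sign of a signed volume, and ring + Hückel
  aromaticity (`perceive()`).
* **Matching** — element-labeled graph-isomorphism candidate search with an
  element-count prescreen and a missing-atom subgraph fallback, scored by
  the five-category **composite score**

  ```
  score_c = 100 × (matched atoms in category c) / (eligible atoms in c)
  ```

  over heavy atoms, chiral-center count, handedness, aromatic atoms and
  bond order, with the eligible sets taken from the definition side; a
  **match status** of `passed` / `close match` / `no match` triages each
  instance (`match_instance()`, `batch_report()`).
* **Environment** — covalent/coordination linkage detection and
  leaving-group capping (–OH on carbon, –H on nitrogen/oxygen) so the
  absolute stereochemistry of attachment points such as glycosylated
  anomeric carbons becomes determinable (`detect_linkages()`,
  `add_leaving_group()`).
* **Chopper** — decomposition of peptide-like ligands along automatically
  selected amide / pseudo-peptide C–N bonds into capped free-neutral
  fragments, matched and ordered N→C (`chop()`,
  `apply_chop_to_entry()`).
* **Editing** — add atoms, change bond orders, recompute implicit
  hydrogens/formulas, redundancy-check and commit new definitions
  (`add_atom()`, `commit_definition()`).
* **Fixtures** — a deterministic toy dictionary (17 hand-built definitions
  with idealized geometry) and a seeded synthetic-entry generator with
  targeted perturbations (`make_toy_dictionary()`, `make_entry()`).

## Worked example

A synthetic deposited entry with 14 components: two mannose-like sugars
deposited under the wrong code, eight N-acetyl-glucosamine-like sugars one
of which has its anomeric carbon C1 flattened to sp2, two
morpholine-sulfonate buffer molecules and two zinc ions.

```r
library(ccannotate)
dict  <- make_toy_dictionary()
entry <- make_entry(list(
  list(comp_id = "MAN", count = 2, perturb = list(type = "relabel_id", new = "GLA")),
  list(comp_id = "NAG", count = 8, perturb = list(type = "flatten_chiral", atom = "C1")),
  list(comp_id = "MES", count = 2),
  list(comp_id = "ZN",  count = 2)), seed = 42, dict = dict)
writeLines(format_report(batch_report(entry, dict), "tsv"))
```

```
instance        top_hit status      heavy_atoms chiral_count handedness aromatic bond_order
1_C_GLA_1001    MAN     close match 100         100          100        -        100
2_C_MAN_1002    MAN     passed      100         100          100        -        100
3_C_NAG_1003    NAG     close match 100         80           100        -        100
4_C_NAG_1004    NAG     passed      100         100          100        -        100
...
14_C_ZN_1014    ZN      passed      100         -            -          -        100
```

Row 1 is chemically identical to its top hit in every category, yet only a
`close match`: the deposited code (`GLA`) differs from the dictionary code,
and the fix is to update the code. Row 3 scores **80%** in the
chiral-center category — one of the five stereocenters (the flattened C1)
is sp2 in the coordinates and no longer a stereocenter — while the other
four parities still agree (handedness 100). `-` marks categories with no
eligible atoms (a zinc ion has no stereocenters). `run_pipeline()` performs
the follow-up standardization: codes and atom names are rewritten through
the top-hit mapping and logged.

A lisinopril-like ligand decomposes along its two automatically selected
backbone bonds (the N-alkyl amine bond to the lysine nitrogen and the
amide to the proline ring nitrogen):

```r
e2  <- make_entry(list(list(comp_id = "LPR", count = 1)), seed = 1, dict = dict)
dec <- chop(extract_instances(e2, dict)[[1]], d = dict)
dec
#> <decomposition> 3 fragment(s), 2 cleaved bond(s), order mode auto
#>   sequence: CLT - LYS - PRO
```

Each fragment is capped to its free neutral form (–OH on the carbon side
of each cut, –H on the nitrogen side) and matches its dictionary
definition at 100 in every category.

A shell front end over the same functions lives in `exec/ccannotate`
(subcommands `report`, `search`, `chop`, `newid`, `edit`, `fixtures`).

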