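# ivscreen

Inverse virtual screening (target fishing) for small molecules, with
decoy-normalised docking affinities.

Conventional virtual screening ranks many ligands against one protein.
Inverse virtual screening (IVS) does the opposite: one (or a few) query
compounds are docked against a large panel of protein structures to
rank *candidate targets* — useful for natural products, which are
typically isolated in amounts too small for broad experimental target
deconvolution. `ivscreen` implements the full analysis for panels of
PDB structures and the three hemp-leaf phytocannabinoids bundled as its
worked example (a hydroxylated cannabitriol, cannabidiol and
cannabidiolic acid), and is equally usable with any compound set and
panel.

Raw docking affinities favour promiscuous pockets that bind anything
drug-like. The screen therefore normalises each best affinity V₀
(kcal/mol) of a query on a structure by the mean best affinity V_R of
ten decoys — molecules matched to the query in molecular weight,
hydrogen-bond donor and acceptor counts, but structurally dissimilar —
on the same structure:

    V = V₀ / V_R        (dimensionless)

Structures are retained only when the binding energy is below
−7.5 kcal/mol **and** V is above 0.75 (both strict). Retained hits are
ranked two ways: the top-scored target per compound (by affinity or by
V), and the consensus targets — UniProt accessions with at least one
retained structure for *every* query compound, ordered by how often
they were retrieved.

The package covers the surrounding pipeline end to end:

* **Compound registry** — SMILES/SDF input, Hill formulas, average and
  nominal masses, nominal [M+H]⁺ for unit-resolution ESI-MS identity
  checks, Lipinski-style donor/acceptor counts, rotatable bonds
  (`compound_properties()`, `validate_identity()`).
* **Decoy selection** — property windows (MW ± 25 Da, HBD/HBA ± 1) and
  FP2-Tanimoto dissimilarity (< 0.4), deterministic and auditable
  (`select_decoys()`, `verify_decoy_set()`).
* **Panel preparation** — PDB cleaning (waters/ions/buffer removal,
  altlocs, multi-model files), binding sites from co-crystallised
  ligands or a grid buriedness scan, and docking boxes with a 10 Å
  buffer per direction at 1.0 Å grid spacing (`clean_structure()`,
  `binding_site()`, `build_box()`).
* **Docking adapter** — an AutoDock-Vina-compatible subprocess backend
  (PDBQT preparation through Open Babel, exhaustiveness 64, fixed
  seed) and a deterministic *replay* backend that serves recorded
  affinity tables, so the whole analysis runs and is testable with no
  engine installed (`vina_backend()`, `replay_backend()`,
  `dock_batch()`).
* **Pose audit** — geometric detection of hydrogen bonds, π-π stacking
  and salt bridges with chain:ResnameNumber labels, scored against
  known binding-site residue lists (`interaction_report()`).
* **Synthetic data** — seeded affinity matrices with planted true
  targets, toy receptor/ligand complexes with a cavity of known
  centre, and decoy candidate libraries (`generate_affinity_table()`,
  `generate_toy_complex()`, `generate_decoy_library()`).

## Worked example

Replay the recorded cannabinoid screen (the bundled affinity table
holds the retained best affinities of compounds **1**–**3**; the decoy
table accompanying it is synthetic, see `?hemp_screen_example`):

```r
library(ivscreen)
library(dplyr)

compound_properties(hemp_compounds()) |>
  select(id, formula, mz_protonated)
#>   id  formula  mz_protonated
#> 1 1   C21H30O3           331
#> 2 2   C21H30O2           315
#> 3 3   C22H30O4           359

ex  <- hemp_screen_example()
scr <- run_screen(ex$compounds, ex$panel, ex$decoy_map,
                  replay_backend(bind_rows(ex$affinities, ex$decoy_affinities)))
scr
#> <ivs_screen>
#>   hits: 9 normalised, 9 passed (V0 < -7.5 kcal/mol, V > 0.75 )
#>   consensus targets: 3
#>   top targets by affinity:
#>  compound_id criterion pdb_id value  tied uniprot_id         molecule_name
#>            1  affinity   6X83  -9.2 FALSE     P01375 Tumor necrosis factor
#>            2  affinity   7KPA  -9.7 FALSE     P01375 Tumor necrosis factor
#>            3  affinity   7KPA -10.1 FALSE     P01375 Tumor necrosis factor

consensus_table(scr$consensus)
#>   uniprot_id molecule_name            retrieval_count compound_1  compound_2  compound_3
#> 1 P01375     Tumor necrosis factor                  3 -9.2 (6X83) -9.7 (7KPA) -10.1 (7KPA)
#> 2 P37231     Peroxisome proliferator-…              3 -8.6 (2ZK6) -9.2 (4PRG) -9.4 (4PRG)
#> 3 P00734     Prothrombin/Thrombin                   3 -8.4 (6ZUX) -8.6 (6ZV8) -8.5 (1RD3)
```

The three protonated nominal masses reproduce the observed ESI-MS
values that confirm each compound's formula. In the replayed screen
all three cannabinoids score best against tumor necrosis factor alpha
(TNFα), and thrombin (P00734) plus PPARγ (P37231) are retrieved by all
three compounds — the consensus targets. `autoplot(scr)` draws the
V-versus-V₀ plane with both retention thresholds;
`tidy(scr)`/`glance(scr)` give the per-hit table and a one-row
summary; `write_screen_report(scr, dir)` emits the JSON + TSV report.

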