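---
title: "Decoy-normalised inverse virtual screening: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoy-normalised inverse virtual screening: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivscreen)
library(dplyr)
```

## The screen and its statistic

Inverse virtual screening docks a query compound against a panel of
protein structures and asks which targets it plausibly binds. The raw
ranking signal — the engine's best-pose affinity $V_0$ in kcal/mol,
more negative meaning stronger — is biased: large greasy pockets score
well against almost any ligand. The screen therefore measures each
structure's promiscuity with ten decoys, molecules that resemble the
query in coarse chemistry (molecular weight, hydrogen-bond donors and
acceptors) but have different structures, and normalises:

$$V = \frac{V_0}{V_R},$$

where $V_R$ is the arithmetic mean of the ten decoys' best affinities
on the same structure. $V > 1$ means the query beats its decoys there;
$V \le 0.75$ discards structures where the signal is indistinguishable
from (or worse than) generic binding. Retention requires **both**
$V_0 < -7.5$ kcal/mol and $V > 0.75$, read literally as strict
inequalities ("below", "above"). Because affinities are negative,
$V_0 < 0.75\,V_R$ is the equivalent form of the second condition; note
that $0.75 < V < 1$ admits compounds scoring slightly *worse* than
their decoys — the threshold is implemented as stated, and the
retention rule is deliberately permissive at that margin.

Two result shapes follow. *Top scores*: per compound, the retained
structure with minimum $V_0$ (or maximum $V$); ties break by lower
$V_0$, then lexicographic PDB id, and are flagged. *Consensus
targets*: retained hits are grouped by UniProt accession, and only
accessions with at least one retained structure for every query
compound survive. The retrieval count is defined as the total number
of retained (compound, structure) hits in the group — "how often this
protein came back" — and this definition is recorded in the JSON
report, since "most retrieved" admits other readings (e.g. distinct
structures only). Per-compound best affinities within each group are
minima over that compound's retained hits.

Assumptions worth keeping in mind: $V_R$ is an untrimmed mean (no
outlier rejection); $V$ is undefined and the hit is excluded (with a
log entry) when the decoy mean is zero or positive; a query affinity
$\ge 0$ is auto-failed rather than an error, since docking engines can
emit non-binding scores; normalisation is per structure, and filtering
happens *before* UniProt grouping, so different structures of one
protein are filtered independently.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| affinity threshold `e_max` | −7.5 | kcal/mol | the screen's published retention bound |
| V threshold `v_min` | 0.75 | — | idem; strict inequality |
| decoys per query | 10 | — | the design the normalisation assumes |
| decoy MW window | ±25 | Da | tight enough to "resemble", loose enough to find 10 decoys in a modest candidate library |
| decoy HBD/HBA window | ±1 | counts | coarse Lipinski-style matching |
| decoy dissimilarity | FP2 Tanimoto < 0.4 | — | standard decoy-dissimilarity practice; the query itself (similarity 1) is always excluded |
| docking-box buffer | 10 | Å per direction | published grid construction |
| grid spacing | 1.0 | Å | recorded as metadata; Vina-convention engines take centre/size only |
| exhaustiveness | 64 | — | published search effort |
| engine seed | 20220624 | — | no seed is published; a fixed default makes runs repeatable and is recorded in the engine metadata |

Hydrogen-bond donors are N/O atoms bearing at least one hydrogen and
acceptors are all N/O atoms — deliberately plain Lipinski-style counts,
matching the coarse matching the decoy design calls for (more refined
definitions, e.g. excluding carboxylic oxygens, would change CBDA's
acceptor count from 4 to 3). Nominal masses use integer
most-abundant-isotope masses (C = 12, H = 1, O = 16), so
[M+H]⁺ = nominal + 1 matches unit-resolution positive-mode ESI-MS.
Rotatable bonds are acyclic single bonds between non-terminal heavy
atoms (bridges of the molecular graph), consistent with "all
open-chain bonds active" ligand preparation.

The bundled query compounds are the three hemp-leaf cannabinoids. Two
have standard literature stereochemistry (CBD, CBDA). The
hydroxylated cannabitriol (compound "1") has no deposited structure
record; its SMILES is encoded from the assigned name — CBD skeleton
with the ring double bond exocyclic and an α-hydroxyl at the
2-position, three stereocentres — and is validated against its
C₂₁H₃₀O₃ formula and observed [M+H]⁺ of 331. Property computations
depend only on the constitution, not the stereo assignment.

## Panel preparation and pocket detection

Cleaning keeps the first model of multi-model files, resolves
alternate locations to the highest-occupancy conformer (ties to the
alphabetically first altloc), removes residues on a curated,
user-extensible exclusion list (waters, common ions, crystallisation
additives), and extracts the largest remaining hetero group as the
co-crystallised ligand (ties by lower chain id, then residue number —
cofactors are not distinguished from ligands; the rule is
deterministic). Cleaning is idempotent, and panel runs log failed
entries instead of aborting.

When a ligand is present, the binding site is its heavy-atom centroid
and axis-aligned bounds; a retained hetero group with fewer than three
heavy atoms (a stray ion) is a degenerate-ligand error. Otherwise a
grid buriedness scan proposes pockets: a 1.0 Å grid over the protein
bounding box; a point is buried when it is ≥ 2.0 Å from every atom
and at least **5 of 7** scan directions (±x, ±y, ±z and one diagonal)
are occluded within 8 Å (perpendicular capture radius 1.5 Å); buried
points cluster by 26-connectivity; clusters of ≥ 10 points are
pockets, scored by point count, top five returned. The scan is an
explicit, fully deterministic substitute for proprietary site-mapping
software, not a reproduction of it: its score is a cavity-volume
proxy with no energetic term. Two numerical choices matter. First,
the occlusion majority is 5 of 7 rather than 4 of 7: with only one
diagonal probe, a point just outside a convex surface near a
bounding-box corner can have four directions grazing the protein, so
a 4-of-7 rule hallucinates pockets on convex bodies, while a strict
majority cannot. Second, all distance comparisons carry a 10⁻⁶
tolerance so boundary-exact values (common when synthetic receptors
sit on a lattice commensurate with the grid) classify identically
after rigid translations; the grid is anchored to the protein
bounding box, making detection translation-covariant.

The docking box adds the 10 Å buffer per direction to the site's
bounding box; a degenerate point site therefore yields a
20 × 20 × 20 Å box.

## Docking backends and replay

The engine contract is pluggable. The Vina-convention backend
prepares inputs as PDBQT through Open Babel (hydrogens for pH 7.4,
Gasteiger charges, rigid receptors) and parses pose affinities from
`REMARK VINA RESULT` records; engine failures are caught per job and
summarised, never fatal to a batch. The replay backend serves a
recorded `(compound_id, pdb_id, affinity_kcal_mol)` table and is
bit-reproducible, which is what makes the entire downstream analysis
— normalisation, filtering, ranking, consensus — testable with no
docking software installed, and is also how published affinity tables
are re-analysed. Batches are order-invariant, and the bundled example
table records only the retained pairs of the cannabinoid screen, so
jobs for unrecorded pairs are logged failures by design. The decoy
affinities accompanying that example are synthetic (a flat
−6.5 kcal/mol), as the originals were never published; with every
recorded $V_0 < -7.5$ and $V = V_0/-6.5 > 1$, retention of the
recorded hits is unaffected by this choice.

## Pose auditing

Contact detection is purely geometric. Hydrogen bonds: donor-acceptor
heavy-atom pairs within 3.5 Å, in both directions; when the pose
carries explicit hydrogens on a donor the best D–H···A angle must
reach 120°, otherwise the criterion is distance-only with the angle
reported as `NA` (receptor structures rarely include hydrogens). The
same heavy-atom pair read in both donor directions is reported once,
preferring the reading with angle evidence. π-π stacking: ring pairs
(ligand aromatic rings against His/Phe/Tyr/Trp side-chain rings) with
centroid distance ≤ 5.5 Å, parallel when the interplanar angle is
≤ 30°, T-shaped at 60–90°, intermediate tilts excluded. Salt bridges:
ligand carboxylate oxygens or formally charged atoms against
Arg/Lys/His nitrogens and Asp/Glu oxygens within 4.0 Å. Labels render
as `chain:ResnameNumber` (e.g. `B:Ser195`) with residue numbering
preserved verbatim from the input, and contacts can be intersected
with a reference list of known binding-site residues (chain-less
references match any chain). These defaults are the widely used
geometric criteria made explicit and configurable; visualisation
software applies unstated and sometimes different rules, so contact
lists on real poses need not coincide with any viewer's rendering.

## The synthetic-data module

The generator emulates the *statistical* structure the screen assumes
— true targets bind the query better than decoys and background — not
docking energetics. Query affinities are
$N(\mu_{\text{base}}, \sigma)$ with a negative shift added on planted
(compound, target) pairs; decoy affinities are
$N(\mu_{\text{decoy}}, \sigma)$. Defaults $\mu_{\text{base}} = -6.0$,
$\mu_{\text{decoy}} = -6.5$, $\sigma = 0.8$, shift $= -3.0$ kcal/mol
straddle the −7.5 threshold so both filter branches are exercised;
everything is deterministic per seed. With no planted targets the
false-positive rate of the default filter has a closed form — the V
condition is implied by the affinity condition unless the decoy mean
drifts below −10, which is essentially impossible here, so the rate
is $\Phi((-7.5 - \mu_{\text{base}})/\sigma) \approx 0.030$ — and the
test suite checks the pipeline against that analytic tail over 100
seeds. Recovery runs (planted-rank and retention checks; 50 targets,
2 planted, 20 seeds) use $\sigma = 0.3$, the regime in which a
−3 kcal/mol planted advantage separates cleanly (at $\sigma = 0.8$
the planted/background affinity distributions overlap enough that
strict all-pairs ranking fails ~0.4% of the time per pair by
construction, which would measure the noise level, not the pipeline).

Toy complexes are geometry-only: carbon pseudo-atoms on a 2 Å lattice
filling a sphere, with a spherical cavity of known centre one
cavity-radius below the surface, opened by a narrow channel, plus a
rigid ring ligand sized to the cavity; a convex solid ball serves as
the no-pocket negative control. Decoy candidate libraries are acyclic
polyol/polyether chains whose oxygen counts and lengths span the
matching windows — structurally dissimilar from any ring-bearing
query by construction.

What passing synthetic tests shows: the statistic, filter, grouping
and ranking machinery is correct, deterministic and faithful to its
definitions. What it does not show: anything about real docking
accuracy, real pocket geometry, or the composition of any real target
panel.

## Scope decisions and limitations

* No statistical significance is attached to V; none is defined for
  the method.
* The published panel (structures annotated to an acute-inflammation
  GO term; thousands of entries at retrieval time) is
  database-version dependent and no accession list is deposited, so
  panels are supplied by the user as files plus a PDB→UniProt mapping
  table; the package performs no live PDB/GO/SIFTS queries.
* The ten decoys of the original screen are unnamed; no
  reconstruction is attempted. Decoy candidates are user- or
  generator-supplied.
* Live docking requires an external Vina-convention engine; its
  stochastic search and preparation differences mean published
  affinities are reproduced approximately at best. The test suite
  drives the adapter through a mock engine; the replay backend
  carries all exact-reproduction guarantees.
* Problem sizes in the suite (panels of 20–50 synthetic targets,
  100–200 random instances for oracle comparisons, 20-seed recovery
  replicates, toy receptors of ~600 atoms) were chosen as the
  smallest at which every property under test is sharply decided.

```{r example}
ex <- hemp_screen_example()
scr <- suppressWarnings(run_screen(
  ex$compounds, ex$panel, ex$decoy_map,
  replay_backend(bind_rows(ex$affinities, ex$decoy_affinities))))
glance(scr)
consensus_table(scr$consensus)
```
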