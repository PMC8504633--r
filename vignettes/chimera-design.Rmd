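---
title: "Designing single-crossover protein chimeras with chimeraforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing single-crossover protein chimeras with chimeraforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraforge)
```

## The problem

Natural protein space grew largely by duplication and recombination of
sub-domain sized fragments. Mimicking that process *in silico* — fusing the
N-terminal part of one domain to the C-terminal part of another at a single
crossover — has produced well-folded designer proteins, but building the
models by hand is slow and error-prone. chimeraforge automates the pipeline:

1. **Hits.** Load a table of fragment-homology hits: each row names a query
   and a subject domain, the bounds of the fragment they share, gapped
   alignment strings, a profile-HMM probability, an RMSD, a TM-score and
   SCOPe lineage codes. Filter hits, select SCOPe groups, drop domains.
2. **Networks.** Represent hits as a similarity network whose nodes are
   domain-fragment clusters and whose edges join domains sharing a fragment;
   connected components group domains around one fragment type.
3. **Building.** Map the alignment of a chosen hit onto the two parent
   structures, superpose the shared fragment, call every aligned position
   whose Cα pair lies within a cutoff a *fusion point*, and assemble the two
   chimeras per fusion point, discarding models with backbone clashes.
4. **Analysis.** Characterize any model: solvent accessible surface area,
   contact maps, relative contact order, salt bridges, hydrogen bonds and
   hydrophobic clusters.

## The data model

`ProteinStructure` holds an ordered residue list as a flat atom table;
author numbering (`chain`, `resid`, `icode`) is preserved for I/O, but every
algorithm addresses residues by the internal sequential index. Fragment
bounds in hit tables are **0-based half-open on that internal index** (the
hit schema does not define them on author numbering, which may contain gaps
and insertion codes); alignment columns are likewise 0-based, so chimera
names like `comb1_72` cite the 0-based crossover column.

PDB files are read through bio3d with a single-conformer dialect: first
model only, altloc blank/`A`, HETATM records, waters and hydrogens dropped.
All analyses are heavy-atom based, which suits X-ray models and built
chimeras alike (neither carries reliable hydrogens).

## Superposition and fusion points

Correspondence between the parents comes from the *sequence alignment* of
the hit, never from structural re-alignment: the alignment is the template
the chimera inherits. Given the mapped Cα pairs, a least-squares rigid fit
(Kabsch, SVD with reflection correction) superposes the subject fragment
onto the query in one of two modes:

* **global** — one transform over all aligned Cα pairs;
* **partial** — alignment gaps delimit segments (e.g. βα-motifs of a long
  fragment), and each segment with at least `minSegLen` aligned pairs
  (default 3) is fitted independently. Each column's Cα-Cα distance is
  measured under its own segment's transform; columns in shorter segments
  are excluded from fusion-point candidacy, because 1-2-point fits are
  ill-conditioned. Least squares per segment was chosen over re-running a
  heuristic structure aligner per segment: with correspondences fixed by
  the alignment, least squares *is* the optimal transform.

A **fusion point** is an aligned column whose post-superposition Cα-Cα
distance falls below the cutoff (default 1 Å, user-adjustable): fusing
there perturbs the merged backbone minimally.

TM-scores use the standard normalization `d0 = 1.24 (L-15)^(1/3) - 1.8`
with a 0.5 Å floor for chains of 15 residues or fewer.

## Assembly conventions

Each fusion point yields two chimeras: combination 1 takes the N-terminus
from the query, combination 2 from the subject. The crossover convention —
a genuinely open choice — is that the N-terminal side **includes the
residue at the fusion column** and the C-terminal side starts at the
partner residue after it. Subject coordinates are always carried into the
query frame by the governing superposition; the junction peptide bond is
implied by concatenation, and no junction geometry idealization is
performed (that is the job of a downstream minimizer, for which the written
PDB, with provenance in the B-factor column, is ready input).

The clash filter scans backbone heavy atoms (N, CA, C, O) *between* the two
parent-derived halves only — intra-parent geometry comes from experimental
models and is taken as valid — and rejects a chimera when any cross pair
lies within 2.5 Å, just below the shortest non-bonded backbone contacts in
folded proteins. The two residues joined by the new peptide bond are
excluded from the scan as a pair: their backbone atoms (O–N ≈ 2.25 Å,
C–CA ≈ 2.44 Å across any trans peptide bond) are covalent geometry, not
clashes. They are still tested against every other residue of the opposite
half.

## The synthetic generators

`buildIdealSS()` produces poly-Ala chains from ideal internal coordinates
(helix φ/ψ = −57°/−47°, strand −139°/+135°, loop −75°/+150°, trans peptide,
standard bond lengths and angles), backbone plus Cβ only. One caveat worth
knowing: joining a helix directly to a strand with no intervening loop
creates one backbone O–O contact of 2.49 Å right at the transition — real
proteins interpose loops. Fixtures that exercise the clash filter therefore
use single-kind or loop-buffered chains.

`makeToyPair(nShared, nFusable, seed)` is the package's controlled stand-in
for a natural parent pair. It cuts an extended ideal chain into a query
(N-terminal flank + fragment) and a subject (fragment + C-terminal flank),
displaces each subject fragment residue rigidly — ≈0.2 Å for the
`nFusable` designated positions, ≈1.8 Å for the rest — and then applies a
random rigid motion to the whole subject. The displacement magnitudes
leave a wide margin on both sides of the 1 Å cutoff, and the generator
verifies the engineered count against an actual superposition before
returning (resampling directions in the rare case a margin is violated), so
the advertised fusable count is exact by construction. The extended-chain
geometry guarantees that chimeras assembled at engineered points
reconstitute a clash-free chain. What these fixtures do **not** emulate:
real side chains, sequence diversity, compact tertiary packing, or the
β-strand order conflicts that make many real chimera pairs clash — so
passing tests demonstrate correctness of the machinery, not design success
rates on natural domains.

## Analysis battery: parameters and their defaults

| analysis | key parameters | default | why |
|---|---|---|---|
| SASA | probe radius; sphere points | 1.4 Å; 960 | water probe; 960 points give ≈1% quadrature error (tests verify 2% self-convergence against 10 000 points) |
| contact map | — | Cα-Cα | standard 2-D representation |
| contact order | contact distance; min separation | 6 Å; 1 | heavy-atom contact definition of the relative contact-order literature |
| salt bridges | O–N cutoff; His basic | 4 Å; yes | common geometric criterion; both exposed as arguments |
| H-bonds | donor-acceptor distance | 3.5 Å | heavy-atom criterion, since models carry no hydrogens; backbone pairs need sequence separation ≥ 2 (closer ones are covalent geometry) |
| hydrophobic clusters | contact pad; min size | 1.4 Å; 4 | two apolar atoms are in contact when closer than the sum of van der Waals radii plus twice the pad — no water fits between them |

Van der Waals radii: C 1.7, N 1.55, O 1.52, S 1.8 Å; unknown elements fall
back to 1.7 Å with a warning.

The hydrophobic-cluster detector approximates the CSU
(contacts-of-structural-units) contact classification with a
distance-threshold contact graph over the side-chain C/S atoms of
hydrophobic-class residues (ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO, CYS);
clusters are connected components of the residue contact graph, and a
cluster's area sums, per atomic contact, the spherical cap of the smaller
atom facing its partner (same quadrature as SASA). The full CSU
surface-partition legitimacy test (occlusion by intervening atoms) is not
reproduced; published cluster areas computed with CSU proper should be
treated as qualitative references. Published contact-order or SASA values
for minimized models will also differ slightly from values computed on
unminimized inputs, so comparisons there are tolerance-based.

## A worked example

```{r example}
toy <- makeToyPair(101, 32, seed = 7)
map <- mapAlignment(toy$hit, toy$query, toy$subject)
map
theoreticalMaxChimeras(map)     # two combinations per aligned position
fps <- findFusionPoints(map, cutoff = 1.0)
nrow(fps)                       # the engineered 32 points
res <- buildAllChimeras(map, cutoff = 1.0)
nrow(res$manifest)              # 64 candidates entered the clash filter
length(res$chimeras)            # all survive on this clash-free fixture
res$chimeras[[1]]
```

Hit-table work uses the packaged 12-row toy table:

```{r hits}
hits <- loadHits(system.file("extdata", "toy_hits.tsv",
                             package = "chimeraforge"))
length(filterHits(hits))              # strict >70% prob, <3 A, <0.3 TM;
                                      # inclusive 10..200 length
net <- buildNetwork(filterHits(hits))
summarizeNetwork(net)[c("nNodes", "nEdges", "nComponents")]
```

## Numerical choices and degenerate inputs

* Probability and TM-score filter bounds are strict inequalities, fragment
  length bounds inclusive, mirroring the usual phrasing of such thresholds;
  every criterion can be disabled independently. The hit schema carries a
  single `tm_score` column; when upstream pipelines report both a fragment
  and a full-domain TM-score, the caller decides which one to store and
  filter on.
* The fusion cutoff is a strict `<`; a cutoff of 0 therefore yields no
  fusion points.
* Kabsch on near-collinear point sets warns but still returns the
  least-squares solution; fewer than 3 pairs is an error.
* Degenerate chimeras (a fusion at a terminal column leaving one side
  empty) are dropped and recorded as such in the build manifest.
* Ties in component ordering break by smallest node id; hub ties break by
  node id, so all orderings are deterministic.
* Reciprocal duplicate hits (A→B and B→A) collapse into one edge with
  `multiplicity = 2`; a mode collapsing cluster tags to bare domains exists
  but is non-default, since distinct cluster tags mark distinct fragment
  occurrences and explain why such networks hold more nodes than domains.
* `loadHits(format = "sqlite")` reads the single-table SQLite dialect
  through the Python standard library's sqlite3 module (no R SQLite driver
  is required at runtime beyond a `python` on the PATH); the TSV path needs
  nothing external.

## Problem sizes used by the test battery

The packaged checks run on fixtures chosen to keep the full suite fast on a
single core while still exercising every code path at the sizes the
pipeline is designed for: toy pairs of 8-101 shared residues, fusion-point
recovery over engineered counts 0-10 across 20 seeds each, 50 random
fixtures per geometric detector against brute-force all-pairs oracles, and
SASA quadrature convergence at 960 versus 10 000 sphere points on a
20-residue helix.

## Known limitations

* Single crossover only; no multi-crossover chimeras, loop rebuilding or
  junction minimization.
* No forcefield scoring or energy ranking: the PDB output (provenance in
  the B-factor column) is intended as input to external minimizers.
* Sequence-dependent superposition only; no sequence-independent structure
  alignment is attempted.
* mmCIF, NMR multi-model files and hydrogen placement are out of scope.
* The CSU approximation above; hydrophobic-cluster areas are comparative,
  not absolute.
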