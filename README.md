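# chimeraforge

Automated design and structural analysis of single-crossover protein
chimeras, for protein engineers and evolutionary biologists who work with
fragment recombination.

Ancient sub-domain fragments recur across protein folds; a table of
fragment-homology *hits* (query domain, subject domain, shared-fragment
bounds, gapped alignment, HMM probability, RMSD, TM-score, SCOPe lineages)
records them. chimeraforge turns such a table into designed proteins:

* **hits** — load (TSV or single-table SQLite), validate, filter
  (probability > 70 %, RMSD < 3 Å, fragment length 10–200, TM-score < 0.3
  by default, all adjustable/disablable), select SCOPe groups, exclude
  domains;
* **network** — similarity networks (nodes = domain-fragment clusters,
  edges = shared fragments), components, hubs, GraphML/DOT export;
* **superpose** — least-squares (Kabsch) superposition of the shared
  fragment's Cα atoms, globally or per gap-delimited segment, plus
  TM-scores;
* **builder** — map the alignment onto both parent structures, call every
  aligned position with post-superposition Cα–Cα distance < 1 Å a *fusion
  point*, assemble both chimeras per point (combination 1 = query
  N-terminus, combination 2 = subject N-terminus), reject models with
  backbone–backbone clashes (< 2.5 Å between the parent-derived halves);
* **analysis** — Shrake–Rupley SASA, Cα contact maps, relative contact
  order, salt bridges, hydrogen bonds, CSU-style hydrophobic clusters;
* **structures** — PDB I/O and deterministic ideal-geometry generators,
  including `makeToyPair()`, which engineers parent pairs with an exact,
  known number of fusion points.

The core quantities: a fusion point is an aligned pair *(i, j)* with
`||Ca_i − R Ca_j − t|| < 1 Å` under the least-squares rigid fit *(R, t)*;
an alignment mapping *N* positions can yield at most *2N* chimeras (two
combinations per position); the TM-score is
`(1/L) Σ 1/(1 + (d_i/d0)²)` with `d0 = 1.24 (L−15)^{1/3} − 1.8`; the
relative contact order is `100/(L·N) Σ |i−j|` over the *N* heavy-atom
contact pairs within 6 Å.

## Worked example

A synthetic parent pair sharing a 101-residue fragment, 32 of whose aligned
Cα pairs are engineered below the 1 Å cutoff:

```r
library(chimeraforge)
toy <- makeToyPair(101, 32, seed = 7)
map <- mapAlignment(toy$hit, toy$query, toy$subject)
map
#> AlignmentMap: 101 aligned pairs (toyq vs toys), 1 segment(s)
theoreticalMaxChimeras(map)
#> [1] 202
fps <- findFusionPoints(map, cutoff = 1.0)
nrow(fps)
#> [1] 32
res <- buildAllChimeras(map, cutoff = 1.0)
nrow(res$manifest); length(res$chimeras)
#> [1] 64
#> [1] 64
res$chimeras[[1]]
#> Chimera 'comb1_1' (combination 1, fusion column 1, Ca dist 0.39 A)
#>   109 residues: 6 query + 103 subject
```

101 aligned positions cap the design space at 202 offspring; the 32 fusion
points send 64 candidates into the clash filter, and on this clash-free
synthetic pair all 64 survive. Each chimera records its crossover column,
the parent residues joined there, the Cα distance at the junction and
per-residue provenance (also written into the B-factor column of its PDB
output). Hit-table work looks like:

```r
hits <- loadHits(system.file("extdata", "toy_hits.tsv", package = "chimeraforge"))
length(filterHits(hits))
#> [1] 7
s <- summarizeNetwork(buildNetwork(filterHits(hits)))
unlist(s[c("nNodes", "nEdges", "nComponents")])
#>      nNodes      nEdges nComponents
#>           9           7           2
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/chimeraforge.R fetch --hits toy_hits.tsv --scop c.37 --min-prob 70
Rscript inst/scripts/chimeraforge.R build --hits hit.tsv --hit-id 1 \
    --qpdb q.pdb --spdb s.pdb --alignment-mode partial --cutoff 1.0 -o models/
Rscript inst/scripts/chimeraforge.R analyze models/comb1_1.pdb --json report.json
```

See `vignettes/chimera-design.Rmd` for the model, conventions (crossover
residue ownership, junction exclusion in the clash scan, 0-based fragment
bounds) and parameter rationale.

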