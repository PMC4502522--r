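# OrthoUnits

Cross-species ortholog interaction networks and molecular process
units for microbial communities.

## What this package is for

Mixed microbial cultures can show community-level phenotypes — such as
the strongly accelerated dissolution of chalcopyrite (CuFeS₂) by
consortia of iron- and sulfur-oxidizing acidophiles — that no member
species produces alone. A natural way to dissect such cooperation is
gene-centric: annotate the proteomes of the member species, identify
the orthologous (shared) gene complement, transfer interaction
knowledge from the well-characterised species to the poorly
characterised one, and segment the resulting cross-species interaction
network into densely connected **molecular process units** whose
mutual dependencies and species-specific attachments model the shared
physiology.

OrthoUnits provides that workflow for systems biologists working with
two-species (or larger) communities:

* **Annotation store** — a `Community` S4 container built from one
  long-format annotation TSV plus per-species FASTA, with multi-valued
  COG/pathway/EC annotation, coverage tables, and literature
  query-string construction.
* **Ortholog mapping** — all-vs-all Needleman–Wunsch global alignment
  with affine gaps (BLOSUM62, gap open 10, gap extend 0.5), top-hit
  (one-way) or reciprocal-best-hit assignment with deterministic
  tie-breaking.
* **Interaction networks** — simple undirected scored graphs from
  STRING-like edge lists and pathway co-membership (EC-restricted),
  interolog transfer across species through the ortholog map, induced
  subgraphs with zero-connectivity elimination, and the index of
  aggregation.
* **COG aggregation** — per-category ortholog statistics and
  cross-species category graphs with edge weights normalised to the
  species holding fewer genes in the category,
  `w = 100 · matched(min side) / min(n_A, n_B)`, plus within-species
  co-annotation networks.
* **MCODE segmentation** — a full re-implementation of the
  density-based MCODE clustering: vertex weight
  `w(v) = k_max · 2e/(n(n−1))` of the highest k-core of the closed
  neighbourhood, seeded expansion at a node score cutoff,
  2-core filtering, haircut and fluff post-processing, with
  deterministic lexicographic tie-breaks.
* **Process model** — inter-unit edges counting distinct cross-unit
  interactions, overlays linking species-specific genes into units,
  per-unit COG group tallies; serialised as JSON and GraphML.
* **Synthetic community generator** — a seeded, byte-deterministic
  generator of two-species fixtures with planted orthologs, planted
  dense modules and background noise, plus ground-truth tables and
  recovery metrics, so the whole pipeline is testable offline.

See `vignettes/orthounits-methods.Rmd` for the models, parameter
semantics and design decisions.

## Worked example

```r
library(OrthoUnits)

fx  <- generateCommunity(synthConfig(seed = 1, nGenesA = 80, nGenesB = 80,
                                     orthologFraction = 0.8,
                                     seqLengthRange = c(50, 80),
                                     nModules = 4))
map <- mapOrthologs(fx$community, "spA", "spB", minIdentity = 40)
map
#> OrthologMap spA -> spB (one-way): 64 pairs

evaluateRecovery(fx$truth, map = map)[c("orthologRecall", "orthologPrecision")]
#> $orthologRecall
#> [1] 1
#> $orthologPrecision
#> [1] 1

orthoNet <- inducedSubgraph(fx$network, unique(orthologPairs(map)$gene_a))
units    <- findComplexes(orthoNet)
units[[1]]
#> FunctionalUnit 1: 7 members, density 0.952, score 6.667 (seed spA_g0029)

model <- buildProcessModel(units, orthoNet, community = fx$community,
                           specificGenes = setdiff(
                             geneIds(fx$community, "spA"),
                             unique(orthologPairs(map)$gene_a)),
                           netSpecific = fx$network)
model
#> ProcessModel: 3 units, 0 unit edges, 6 overlay genes

modelTallies(model)
#>   unit_id     group n_genes
#> 1       1    energy       3
#> 2       1 transport       0
#> 3       2    energy       0
#> 4       2 transport       3
#> 5       3    energy       2
#> 6       3 transport       2
```

The 64 recovered pairs are exactly the planted orthologs (recall and
precision 1 at the 40% identity cutoff). The three functional units
are the planted modules that survive the restriction to ortholog
genes; the tallies report how many member genes fall into the energy
COG category (C) versus the transport categories (E, H, P, Q), and the
overlay lists species-A-specific genes together with how many of their
interactions reach into each unit.

The same chain runs from the shell:

```sh
Rscript inst/scripts/orthounits.R simulate --seed 1 --out-dir fixture
Rscript inst/scripts/orthounits.R model --in-dir fixture --out-dir out \
    --min-identity 40
```

which writes `orthologs.tsv`, `imputed_edges.tsv`, `units.tsv`,
`model.json` and `model.graphml`.

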