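---
title: "Cross-species molecular process units: models and methods"
author: "OrthoUnits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species molecular process units: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoUnits)
options(OrthoUnits.quiet = TRUE)
```

## The problem

Microbial consortia often show community-level phenotypes that no member
species produces alone. A prominent example is the accelerated leaching
of metal sulfide ores such as chalcopyrite by mixed cultures of
acidophilic bacteria: iron oxidizers and sulfur oxidizers together
regenerate the ferric iron and protons that drive ore dissolution far
more efficiently than either species in isolation. Understanding such
cooperation means asking which molecular processes the species *share*,
how those processes depend on one another, and where species-specific
genes plug into the shared machinery.

OrthoUnits implements a gene-centric workflow for this question, built
on a simple hierarchy: genes (with multi-valued annotation) form
species catalogs; species form a community; interactions among genes
form networks; densely connected network segments are interpreted as
molecular process units; and units plus their inter-unit dependencies
form a process model of the community phenotype. Every level is an
explicit S4 class (`Community`, `InteractionNetwork`, `OrthologMap`,
`FunctionalUnit`, `ProcessModel`) so intermediate results are
inspectable and serialisable.

## Annotation model and coverage

All annotation sources are ingested through a single long-format table
(`species_id`, `gene_id`, `item`, `value`); each source-specific field
(database identifiers, COG categories, COG entries, pathways, EC
numbers, protein names) is a value of the `item` column, and repeated
(gene, item) rows accumulate into value sets. This collapses the many
upstream schemas of annotation databases into one testable dialect.
Genes are protein-coding by inclusion: no gene-type filter is applied.

Coverage of an item for a species is the percentage of genes holding at
least one *valid* entry, where valid means non-empty and different from
the literal string `"NA"` — presence, not correctness, is counted.
Percentages are rounded half-up to two decimals, the convention of
published annotation-coverage tables (base R's round-half-to-even would
print 83.875 as it happens to fall, not deterministically upward).
Interaction coverage is analogous with "holds at least one interaction"
(degree ≥ 1) as the predicate.

The literature-screening helper only *constructs* query strings, one
per (gene, keyword) pair in the form `"<protein name>" AND <keyword>`,
with a default seven-keyword catalog covering cooperative aspects
(synergism, consortium, community, cooperation) and bioleaching
utilisation (bioleaching, biomining, chalcopyrite). Executing queries
against any service is out of scope.

## Ortholog mapping

Orthologs are operationalised as top-scoring global-alignment partners.
Alignment is Needleman–Wunsch with affine gaps, scored with BLOSUM62
and gap open 10 / gap extend 0.5 (the classical protein defaults of
global aligners; a gap of length $L$ costs $\mathrm{open} + L \cdot
\mathrm{extend}$). The implementation delegates the dynamic program to
`Biostrings::pairwiseAlignment`, whose gap convention matches this cost
model exactly; the test suite verifies the scores against an
independent exhaustive enumeration of all global alignments on short
sequences.

Mapping is all-vs-all with no candidate pre-filtering — correctness
over speed at the scale of two bacterial proteomes. Two modes are
provided:

* **one-way** (default): every species-B gene is paired with its
  top-scoring species-A gene. Several B genes may share one A partner
  ("multiple assignment"); this matches the direction in which
  interactions are later imputed (A's interactions are transferred to
  B).
* **rbh**: reciprocal best hit; a pair is kept only when each gene is
  the other's top hit, yielding a one-to-one pairing.

Score ties break by higher percent identity, then by lexicographically
smaller partner id, making the mapping deterministic and invariant to
input order. No identity threshold is applied by default; a
`minIdentity` cutoff (percent identical positions over the alignment
length, gaps included) is available and is used at 40% in the synthetic
validation, where it removes every spurious pairing of non-ortholog
genes while keeping all planted orthologs.

## Interaction networks and interolog transfer

Networks are simple undirected scored graphs: self-loops are dropped,
duplicate evidence for a pair merges into one edge keeping the maximum
score and the union of source tags. Three construction routes exist:
scored edge lists (STRING-like), pathway co-membership (an edge between
every pair of genes sharing a pathway, by default restricted to genes
holding an EC number, the enzymatic reading of pathway databases), and
**imputation**: an edge $(a_1, a_2)$ of species A becomes $(b_1, b_2)$
in species B whenever both endpoints have ortholog partners, tagged
`imported` and carrying the original score. A pair of A genes mapping
onto the same B gene would create a self-loop and is dropped with a log
line. On synthetic data the imputed network is exactly edge-isomorphic,
under the ortholog pairing, to the induced species-A subgraph on mapped
genes — this is asserted in the tests.

`inducedSubgraph` restricts a network to a gene set and eliminates
genes with zero connectivity inside the subgraph; it is idempotent.
The index of aggregation — the fraction of nodes in the largest
connected component — is 1.0 exactly when every node holds a path to
every other.

## COG-level aggregation

Per (species, category) statistics count genes, genes with at least
one ortholog partner annotated to the same category in the other
species, and the total number of such pairs (multiple assignments
counted). The cross-species edge weight is the ortholog percentage
normalised to the species holding the *fewer* genes in the category:

$$ w = 100 \cdot \frac{\text{ortholog-matched genes of the smaller
side}}{\min(n_A, n_B)} $$

Counting *genes of the smaller side* rather than ortholog pairs keeps
$w \le 100$ even with multiple assignments; a pair count could exceed
the denominator. When $n_A = n_B$ the numerator comes from the first
argument — by the tie itself the choice only matters when the two
matched-gene counts differ, which is reported as-is.

Aggregation can be restricted to a supplied gene subset (e.g. the gene
sets of specific pathways). Whether such percentages should be
computed within the subset or against whole-genome category membership
is genuinely ambiguous; the subset interpretation is the default
because it keeps numerator and denominator on the same universe, and
the unrestricted computation is available by simply not passing a
subset.

Within one species, reciprocal assignment of genes to two COG labels
is read as functional closeness: the co-annotation network weights a
label pair by the number of genes carrying both.

## MCODE segmentation

The segmentation re-implements the MCODE density-based clustering
algorithm. Vertex weighting: for each vertex $v$ with degree at least
the degree cutoff, take the closed neighbourhood $N[v]$, peel it to
its highest $k$-core (the non-empty core with maximal $k$), and set

$$ w(v) = k_{\max} \cdot \frac{2e}{n(n-1)} $$

with $n, e$ of that core. Complex prediction seeds from the
highest-weight unvisited vertex and expands breadth-first, admitting a
neighbour when its weight is at least $(1 - \text{node score cutoff})$
times the *seed* weight; visited vertices are never re-seeded or
re-added, so units are disjoint unless fluff is on. Post-processing
discards complexes lacking a 2-core, applies the haircut, optionally
fluffs, and drops complexes below two members. Units are scored
$\text{density} \times \text{size}$ and ranked.

Deliberate choices, all documented in the parameter object:

* **Defaults** are the documented defaults of the Cytoscape MCODE
  plugin (degree cutoff 2, node score cutoff 0.2, 2-core, max depth
  100, haircut on, fluff off).
* **Tie-breaking** everywhere is lexicographic by gene id (seed
  selection among equal weights, ranking among equal scores via larger
  size then smallest member). The original tool leaves tie behaviour
  unspecified; fixing it makes every run reproducible.
* **Haircut to a fixpoint**: a single degree-1 removal pass can expose
  new degree-1 vertices, so the haircut iterates until stable
  (equivalently, each complex is reduced to its 2-core). This is a
  deliberate strengthening of the usual one-pass description. In the
  rare case the haircut removes the seeding vertex itself, the unit's
  recorded seed becomes its highest-weight remaining member.
* **Density** is always $2e/(n(n-1))$, loops excluded.
* **Fluff and overlap**: with fluff off units are disjoint; fluff adds
  unvisited neighbours whose closed-neighbourhood density exceeds the
  fluff cutoff and is the only mechanism by which a gene can belong to
  several units. Reports of genes shared between process units
  therefore imply fluff (or an equivalent overlap mechanism) was
  active; both behaviours are available.

A structural property worth knowing: two equally dense cliques joined
by a *direct* bridge edge merge into one unit, because both bridge
endpoints retain the full clique weight and the expansion walks across.
Joined through a low-weight connector vertex, they segment into two
units. The test suite pins both behaviours.

## Process model

Inter-unit edges operationalise "dependency between processes" as the
number of distinct network edges between members of the two units,
with members shared by both units (possible under fluff) excluded via
the $U_i \setminus U_j$ convention so no edge is double-counted. No
statistical significance test is implied; the threshold below which an
edge is suppressed defaults to 1 and is configurable. The overlay
attaches species-specific (non-ortholog) genes to units by counting
that species' own edges into each unit; genes linking nowhere are
omitted. Per-unit tallies count member genes per COG group under a
configurable partition, defaulting to energy = {C} and transport =
{E, H, P, Q}; a gene in several groups counts once in each.

## The synthetic community generator

Real annotation and interaction snapshots for a two-species consortium
are tied to particular database versions and are not reproducible at
desk scale, so validation runs on a seeded generator that emulates the
relevant structure: two proteomes with a tunable planted-ortholog
fraction (B-side sequences are per-position substituted copies of
distinct A genes; the rest are fresh uniform-random proteins),
multi-label COG assignment with ortholog pairs usually inheriting
their source's labels, per-species pathway memberships, and a
species-A interaction network of disjoint planted dense modules over
background noise. Module wiring samples exactly
$\lceil d \cdot \binom{n}{2} \rceil$ distinct internal pairs, so the
realised internal density is never below the configured target.

**Background edges involve at least one gene of the unassigned
background proteome.** Pairs with both endpoints inside planted
modules are never background: the planted modules — including their
mutual separation — are the benchmark's ground truth, and module
recovery is only well-posed if noise does not silently rewire the
truth itself. With noise between modules permitted, a handful of
random cross-module edges (expected ≈ 18 at the default sizes) would
connect the module-level graph and the seeded expansion would merge
equal-weight modules — a property of the algorithm, not a recovery
failure of the implementation. The generator therefore models
inter-module independence as exact; detecting module merging under
cross-talk is a question about MCODE itself and is covered by the
direct-bridge structural test instead.

One integer seed drives a single private RNG stream (the caller's RNG
state is saved and restored), making every emitted file byte-identical
across runs with the same configuration.

What the generator does *not* emulate: realistic protein evolution (no
indels or domain structure — substitution only), realistic degree
distributions (no hubs or scale-free tails), annotation bias and
error, score calibration of interaction evidence, and shared genes
between pathway and interaction truth. Passing the validation suite
therefore demonstrates algorithmic correctness and determinism under
controlled conditions, not biological validity of conclusions drawn
from any particular real dataset.

## Validation problem sizes

The packaged validation uses: 200 random sequence pairs of length ≤ 8
against the exhaustive alignment oracle; 100 random graphs of ≤ 12
vertices against the brute-force core-peeling oracle; 50 random graphs
for the component-fraction oracle; two 150-gene proteomes (lengths
80–120, 60% orthologs at 5% substitution) for ortholog recovery; and a
300-gene network with 8 planted modules (6–10 genes, density 0.9,
background probability 0.01) for module recovery. These sizes give
exhaustive oracles room to run exactly while exercising every code
path; the pipeline itself has no size-dependent switches.

## Worked example

```{r example}
fx <- generateCommunity(synthConfig(seed = 1, nGenesA = 80, nGenesB = 80,
                                    orthologFraction = 0.8,
                                    seqLengthRange = c(50, 80),
                                    nModules = 4))
map <- mapOrthologs(fx$community, "spA", "spB", minIdentity = 40)
map
evaluateRecovery(fx$truth, map = map)[c("orthologRecall",
                                        "orthologPrecision")]
orthoNet <- inducedSubgraph(fx$network, unique(orthologPairs(map)$gene_a))
units <- findComplexes(orthoNet)
model <- buildProcessModel(units, orthoNet, community = fx$community,
                           specificGenes = setdiff(
                             geneIds(fx$community, "spA"),
                             unique(orthologPairs(map)$gene_a)),
                           netSpecific = fx$network)
model
head(modelTallies(model))
```

## Known limitations

* All-vs-all alignment is quadratic in proteome size; at full
  bacterial-proteome scale (~3000 × 3000 genes) a run takes hours, and
  no pre-filter (k-mer screen, length window) is implemented.
* Interaction evidence is taken at face value; no score recalibration
  or evidence weighting across sources is attempted.
* One-way mapping direction and the absence of a default identity
  cutoff reflect the imputation use case; for strict orthology use
  `mode = "rbh"` with a cutoff.
* Unit naming (biological interpretation of segments) is manual by
  design and out of scope.
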