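#' @import methods
NULL

# Canonical annotation item names used by the convenience accessors.
# Any other item name travels through the long-format annotation table
# untouched and is available via annotationValues().
ITEM_COG_CATEGORY <- "cog_category"
ITEM_COG_TERM     <- "cog_term"
ITEM_PATHWAY      <- "pathway"
ITEM_EC           <- "ec_number"
ITEM_PROTEIN_NAME <- "protein_name"

#' Community of annotated genes from two or more species
#'
#' Gene-centric container for a microbial community: one row per
#' protein-coding gene in \code{genes}, protein sequences as an
#' \linkS4class{AAStringSet} (named by gene id; genes without sequence are
#' simply absent from the set), and a long-format annotation table with
#' columns \code{species_id}, \code{gene_id}, \code{item}, \code{value}.
#' Repeated (gene, item) rows accumulate into multi-valued annotation, so a
#' gene can carry several COG categories, pathways or EC numbers.
#'
#' @slot genes data.frame with columns \code{species_id}, \code{gene_id};
#'   gene ids are unique across the whole community.
#' @slot sequences \linkS4class{AAStringSet} named by gene id (subset of
#'   \code{genes$gene_id}); letters restricted to the 20 standard amino
#'   acids plus X.
#' @slot annotation data.frame(species_id, gene_id, item, value).
#' @slot itemCatalog named list: species id -> character vector of declared
#'   annotation item names (no duplicates).
#'
#' @exportClass Community
setClass("Community", slots = c(
  genes = "data.frame",
  sequences = "AAStringSet",
  annotation = "data.frame",
  itemCatalog = "list"
))

setValidity("Community", function(object) {
  g <- object@genes
  msgs <- character(0)
  if (!all(c("species_id", "gene_id") %in% names(g)))
    return("genes must have columns species_id, gene_id")
  if (anyDuplicated(g$gene_id))
    msgs <- c(msgs, sprintf("duplicate gene_id: %s",
                            g$gene_id[duplicated(g$gene_id)][1]))
  if (any(!nzchar(g$gene_id)))
    msgs <- c(msgs, "empty gene_id")
  sq <- names(object@sequences)
  if (length(sq) && !all(sq %in% g$gene_id))
    msgs <- c(msgs, "sequences present for unknown gene ids")
  a <- object@annotation
  if (nrow(a)) {
    if (!all(c("species_id", "gene_id", "item", "value") %in% names(a)))
      return("annotation must have columns species_id, gene_id, item, value")
    if (!all(a$gene_id %in% g$gene_id))
      msgs <- c(msgs, "annotation rows for unknown gene ids")
    for (sp in unique(a$species_id)) {
      cat_sp <- object@itemCatalog[[sp]]
      extra <- setdiff(unique(a$item[a$species_id == sp]), cat_sp)
      if (length(extra))
        msgs <- c(msgs, sprintf(
          "annotation item(s) not in catalog of %s: %s", sp,
          paste(extra, collapse = ", ")))
    }
  }
  if (any(vapply(object@itemCatalog, anyDuplicated, 1L) > 0))
    msgs <- c(msgs, "duplicated item names in item catalog")
  if (length(msgs)) msgs else TRUE
})

#' Scored cross-species ortholog pairing
#'
#' Result of all-vs-all global alignment between the proteomes of two
#' species followed by top-hit selection. In \code{"one-way"} mode every
#' species-B gene is paired with its top-scoring species-A partner (so one A
#' gene may serve several B genes); in \code{"rbh"} (reciprocal best hit)
#' mode a pair is kept only when each gene is the other's top hit, making
#' the pairing one-to-one.
#'
#' @slot speciesA,speciesB species ids of the two proteomes.
#' @slot mode \code{"one-way"} or \code{"rbh"}.
#' @slot pairs data.frame(gene_a, gene_b, score, identity).
#'
#' @exportClass OrthologMap
setClass("OrthologMap", slots = c(
  speciesA = "character",
  speciesB = "character",
  mode = "character",
  pairs = "data.frame"
))

setValidity("OrthologMap", function(object) {
  msgs <- character(0)
  if (!object@mode %in% c("one-way", "rbh"))
    msgs <- c(msgs, "mode must be 'one-way' or 'rbh'")
  p <- object@pairs
  if (!all(c("gene_a", "gene_b", "score", "identity") %in% names(p)))
    return("pairs must have columns gene_a, gene_b, score, identity")
  if (anyDuplicated(p$gene_b))
    msgs <- c(msgs, "a species-B gene appears in more than one pair")
  if (identical(object@mode, "rbh") && anyDuplicated(p$gene_a))
    msgs <- c(msgs, "rbh mode but a species-A gene appears in several pairs")
  if (length(msgs)) msgs else TRUE
})

#' Simple undirected scored interaction network over genes
#'
#' Simple graph (no self-loops, no duplicate edges) over gene ids. Each
#' edge carries an optional score and a set of evidence source tags
#' (\code{"string-like"}, \code{"pathway-comembership"}, \code{"imported"},
#' ...) joined by \code{";"}; evidence for the same pair from several
#' sources merges into one edge keeping the maximum score and the union of
#' tags. Edges are stored canonically with \code{from < to}.
#'
#' @slot scope species id the network refers to, or a label such as
#'   \code{"ortholog-superset"}.
#' @slot nodes character vector of gene ids (isolated nodes allowed).
#' @slot edges data.frame(from, to, score, sources).
#'
#' @exportClass InteractionNetwork
setClass("InteractionNetwork", slots = c(
  scope = "character",
  nodes = "character",
  edges = "data.frame"
))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  msgs <- character(0)
  if (!all(c("from", "to", "score", "sources") %in% names(e)))
    return("edges must have columns from, to, score, sources")
  if (nrow(e)) {
    if (any(e$from == e$to)) msgs <- c(msgs, "self-loop present")
    if (any(e$to < e$from)) msgs <- c(msgs, "edges not in canonical order")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msgs <- c(msgs, "duplicate edges present")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msgs <- c(msgs, "edge endpoint not in nodes")
  }
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "duplicate node ids")
  if (length(msgs)) msgs else TRUE
})

#' One MCODE-derived molecular unit
#'
#' A densely connected segment of an interaction network, interpreted as a
#' molecular process shared by the community. Units are ranked by
#' \code{score = density * size} and numbered consecutively from 1.
#'
#' @slot unitId integer rank (1 = highest scoring).
#' @slot members gene ids in the unit (at least 2).
#' @slot seed the gene the unit was grown from.
#' @slot score density times size.
#' @slot density 2e/(n(n-1)) of the unit-induced subgraph.
#'
#' @exportClass FunctionalUnit
setClass("FunctionalUnit", slots = c(
  unitId = "integer",
  members = "character",
  seed = "character",
  score = "numeric",
  density = "numeric"
))

setValidity("FunctionalUnit", function(object) {
  msgs <- character(0)
  if (length(object@members) < 2L) msgs <- c(msgs, "unit has < 2 members")
  if (!object@seed %in% object@members) msgs <- c(msgs, "seed not a member")
  if (object@density < 0 || object@density > 1)
    msgs <- c(msgs, "density outside [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Molecular process model
#'
#' The community-level model assembled from MCODE units: weighted
#' inter-unit edges (number of distinct network edges joining members of
#' the two units), an overlay attaching species-specific (non-ortholog)
#' genes to units through that species' own interactions, and per-unit
#' annotation tallies (e.g. genes in the energy COG category versus
#' transport categories).
#'
#' @slot units list of \linkS4class{FunctionalUnit}.
#' @slot unitEdges data.frame(unit_a, unit_b, weight).
#' @slot overlay data.frame(unit_id, gene_id, n_links).
#' @slot tallies data.frame(unit_id, group, n_genes).
#'
#' @exportClass ProcessModel
setClass("ProcessModel", slots = c(
  units = "list",
  unitEdges = "data.frame",
  overlay = "data.frame",
  tallies = "data.frame"
))

setValidity("ProcessModel", function(object) {
  ok <- vapply(object@units, is, TRUE, class2 = "FunctionalUnit")
  if (!all(ok)) return("units must all be FunctionalUnit objects")
  ids <- vapply(object@units, function(u) u@unitId, 1L)
  if (length(ids) && !identical(ids, seq_along(ids)))
    return("unit ids must be consecutive from 1 in rank order")
  TRUE
})

#' COG-level aggregate graph
#'
#' Nodes are (species, COG label) pairs with gene counts and ortholog
#' statistics; edges join categories across species (or co-annotated
#' terms within one species) with a weight: the ortholog percentage
#' normalised to the species holding fewer genes in the category, or the
#' co-annotation gene count.
#'
#' @slot nodes data.frame(species_id, label, n_genes, n_genes_ortholog,
#'   n_pairs).
#' @slot edges data.frame(species_a, label_a, species_b, label_b, weight).
#'
#' @exportClass CogAggregateGraph
setClass("CogAggregateGraph", slots = c(
  nodes = "data.frame",
  edges = "data.frame"
))
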