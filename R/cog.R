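#' @include AllClasses.R AllGenerics.R community.R
NULL

# invert gene -> categories into category -> sorted gene vector
genesByLabel <- function(perGene, subset = NULL) {
  if (!is.null(subset))
    perGene <- perGene[names(perGene) %in% subset]
  if (!length(perGene)) return(list())
  long <- data.frame(gene = rep(names(perGene), lengths(perGene)),
                     label = unlist(perGene, use.names = FALSE),
                     stringsAsFactors = FALSE)
  lapply(split(long$gene, long$label), function(g) sort(unique(g)))
}

# map pairs oriented so that column `s` is the side of species `sp`
orientedPairs <- function(map, sp) {
  p <- map@pairs
  if (identical(sp, map@speciesA))
    data.frame(s = p$gene_a, o = p$gene_b, stringsAsFactors = FALSE)
  else if (identical(sp, map@speciesB))
    data.frame(s = p$gene_b, o = p$gene_a, stringsAsFactors = FALSE)
  else stop(sprintf("species '%s' is not part of the ortholog map", sp),
            call. = FALSE)
}

#' Per-category ortholog statistics
#'
#' For every (species, COG category): the number of genes assigned to the
#' category, the number of those genes that have at least one ortholog
#' whose partner is annotated to the same category in the other species,
#' and the total number of such ortholog pairs (multiple assignments
#' counted). An optional gene subset restricts the computation to a gene
#' list (e.g. the genes of a pathway of interest) on both sides.
#'
#' @param community a \linkS4class{Community} with COG category annotation.
#' @param map an \linkS4class{OrthologMap} between the two species.
#' @param geneSubset optional character vector of gene ids.
#' @return data.frame(species_id, category, n_genes, n_genes_ortholog,
#'   n_pairs).
#' @export
categoryStats <- function(community, map, geneSubset = NULL) {
  species <- c(map@speciesA, map@speciesB)
  byCat <- lapply(setNames(nm = species), function(sp)
    genesByLabel(cogCategories(community, sp), geneSubset))
  out <- NULL
  for (sp in species) {
    other <- setdiff(species, sp)
    op <- orientedPairs(map, sp)
    for (cat in names(byCat[[sp]])) {
      gs <- byCat[[sp]][[cat]]
      go <- byCat[[other]][[cat]]
      hit <- op$s %in% gs & op$o %in% go
      out <- rbind(out, data.frame(
        species_id = sp, category = cat, n_genes = length(gs),
        n_genes_ortholog = length(unique(op$s[hit])),
        n_pairs = sum(hit), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(species_id = character(0), category = character(0),
                      n_genes = integer(0), n_genes_ortholog = integer(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ortholog percentage between two category stats rows
#'
#' The cross-species edge weight of the COG aggregate graph: the
#' percentage of ortholog-matched genes, normalised to the species holding
#' the lower number of genes in the category. Counting genes of the
#' smaller side (rather than ortholog pairs) guarantees the weight stays
#' in [0, 100] even with multiple ortholog assignments. When the two gene
#' counts tie, the numerator is taken from the first argument.
#'
#' @param statsA,statsB single rows of \code{\link{categoryStats}} output
#'   for the same category in the two species.
#' @return Percentage in [0, 100], or \code{NA} when either species has no
#'   genes in the category (edge omitted).
#' @export
categoryEdgeWeight <- function(statsA, statsB) {
  if (!identical(statsA$category, statsB$category))
    stop("category mismatch", call. = FALSE)
  nA <- statsA$n_genes; nB <- statsB$n_genes
  if (nA == 0L || nB == 0L) return(NA_real_)
  minSide <- if (nB < nA) statsB else statsA
  100 * minSide$n_genes_ortholog / min(nA, nB)
}

#' Cross-category ortholog map around a focal COG category
#'
#' Starting from one (species, category) node, finds every category of the
#' other species holding at least one ortholog partner of a focal-category
#' gene and connects it with an edge weighted by the ortholog percentage
#' (\code{\link{categoryEdgeWeight}} semantics computed on the two
#' restricted gene sets).
#'
#' @param community a \linkS4class{Community}.
#' @param map an \linkS4class{OrthologMap}.
#' @param focalCategory one-letter COG code.
#' @param focalSpecies species id holding the focal category.
#' @param geneSubset optional gene-id restriction applied before counting.
#' @return A \linkS4class{CogAggregateGraph}.
#' @export
crossCategoryMap <- function(community, map, focalCategory, focalSpecies,
                             geneSubset = NULL) {
  other <- setdiff(c(map@speciesA, map@speciesB), focalSpecies)
  if (!length(other))
    stop("focal species not in ortholog map", call. = FALSE)
  focalGenes <- genesByLabel(cogCategories(community, focalSpecies),
                             geneSubset)[[focalCategory]]
  if (is.null(focalGenes) || !length(focalGenes))
    stop(sprintf("focal category '%s' empty in species '%s'",
                 focalCategory, focalSpecies), call. = FALSE)
  otherByCat <- genesByLabel(cogCategories(community, other), geneSubset)
  op <- orientedPairs(map, focalSpecies)
  nodes <- data.frame(species_id = focalSpecies, label = focalCategory,
                      n_genes = length(focalGenes),
                      n_genes_ortholog = NA_integer_,
                      n_pairs = NA_integer_, stringsAsFactors = FALSE)
  edges <- NULL
  for (cat in names(otherByCat)) {
    go <- otherByCat[[cat]]
    hit <- op$s %in% focalGenes & op$o %in% go
    if (!any(hit)) next
    nF <- length(focalGenes); nO <- length(go)
    withF <- length(unique(op$s[hit]))
    withO <- length(unique(op$o[hit]))
    weight <- if (nO < nF) 100 * withO / nO else 100 * withF / nF
    nodes <- rbind(nodes, data.frame(
      species_id = other, label = cat, n_genes = nO,
      n_genes_ortholog = withO, n_pairs = sum(hit),
      stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(
      species_a = focalSpecies, label_a = focalCategory,
      species_b = other, label_b = cat, weight = weight,
      stringsAsFactors = FALSE))
  }
  nodes$n_genes_ortholog[1] <- if (is.null(edges)) 0L else
    length(unique(op$s[op$s %in% focalGenes &
                         op$o %in% unlist(otherByCat, use.names = FALSE)]))
  if (is.null(edges))
    edges <- data.frame(species_a = character(0), label_a = character(0),
                        species_b = character(0), label_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(edges) <- NULL
  new("CogAggregateGraph", nodes = nodes, edges = edges)
}

#' Cross-species COG category graph
#'
#' Builds the full two-species aggregate graph: one node per (species,
#' category) and, for every category annotated in both species, an edge
#' weighted by \code{\link{categoryEdgeWeight}}.
#'
#' @inheritParams categoryStats
#' @return A \linkS4class{CogAggregateGraph}.
#' @export
cogCategoryGraph <- function(community, map, geneSubset = NULL) {
  st <- categoryStats(community, map, geneSubset)
  edges <- NULL
  cats <- sort(unique(st$category))
  for (cat in cats) {
    a <- st[st$species_id == map@speciesA & st$category == cat, ]
    b <- st[st$species_id == map@speciesB & st$category == cat, ]
    if (nrow(a) != 1L || nrow(b) != 1L) next
    w <- categoryEdgeWeight(a, b)
    if (is.na(w)) next
    edges <- rbind(edges, data.frame(
      species_a = map@speciesA, label_a = cat,
      species_b = map@speciesB, label_b = cat, weight = w,
      stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(species_a = character(0), label_a = character(0),
                        species_b = character(0), label_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  names(st)[names(st) == "category"] <- "label"
  new("CogAggregateGraph", nodes = st, edges = edges)
}

#' Within-species COG co-annotation network
#'
#' Reciprocal assignment of genes to two COG labels is read as functional
#' closeness of the labels: the edge weight is the number of genes
#' annotated to both. Zero-weight edges are absent; single-labelled
#' annotation yields an edgeless graph.
#'
#' @param community a \linkS4class{Community}.
#' @param species species id.
#' @param level \code{"category"} (one-letter codes) or \code{"term"}
#'   (COG entries).
#' @return A \linkS4class{CogAggregateGraph}.
#' @export
coannotationNetwork <- function(community, species,
                                level = c("category", "term")) {
  level <- match.arg(level)
  perGene <- if (level == "category") cogCategories(community, species)
             else cogTerms(community, species)
  byLab <- genesByLabel(perGene)
  labs <- sort(names(byLab))
  nodes <- data.frame(species_id = species, label = labs,
                      n_genes = vapply(byLab[labs], length, 1L),
                      n_genes_ortholog = NA_integer_,
                      n_pairs = NA_integer_, stringsAsFactors = FALSE)
  edges <- NULL
  if (length(labs) > 1L) {
    cmb <- combn(labs, 2L)
    for (k in seq_len(ncol(cmb))) {
      w <- length(intersect(byLab[[cmb[1, k]]], byLab[[cmb[2, k]]]))
      if (w == 0L) next
      edges <- rbind(edges, data.frame(
        species_a = species, label_a = cmb[1, k],
        species_b = species, label_b = cmb[2, k], weight = w,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(species_a = character(0), label_a = character(0),
                        species_b = character(0), label_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(edges) <- NULL
  new("CogAggregateGraph", nodes = nodes, edges = edges)
}

#' Read a gene-set file
#'
#' Plain-text gene sets: a header line starting with \code{>} names the
#' set, followed by one gene id per line.
#'
#' @param file path.
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1])
    stop("gene-set file must start with a '>' header", call. = FALSE)
  grp <- cumsum(hdr)
  sets <- split(lines[!hdr], grp[!hdr])
  names(sets) <- sub("^>\\s*", "", lines[hdr])[unique(grp[!hdr])]
  lapply(sets, unique)
}

## ---- methods -------------------------------------------------------------

#' @describeIn CogAggregateGraph node table.
#' @param x a \linkS4class{CogAggregateGraph}.
#' @export
setMethod("cogNodes", "CogAggregateGraph", function(x) x@nodes)

#' @describeIn CogAggregateGraph edge table.
#' @export
setMethod("cogEdges", "CogAggregateGraph", function(x) x@edges)

setMethod("show", "CogAggregateGraph", function(object) {
  cat(sprintf("CogAggregateGraph: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
})

#' @describeIn CogAggregateGraph convert to an \pkg{igraph} graph with a
#'   \code{weight} edge attribute.
#' @param ... unused.
#' @export
setMethod("asIgraph", "CogAggregateGraph", function(x, ...) {
  nid <- function(sp, lab) paste(sp, lab, sep = ":")
  nodes <- data.frame(name = nid(x@nodes$species_id, x@nodes$label),
                      species = x@nodes$species_id, label = x@nodes$label,
                      n_genes = x@nodes$n_genes, stringsAsFactors = FALSE)
  if (nrow(x@edges)) {
    e <- data.frame(from = nid(x@edges$species_a, x@edges$label_a),
                    to = nid(x@edges$species_b, x@edges$label_b),
                    weight = x@edges$weight, stringsAsFactors = FALSE)
  } else {
    e <- data.frame(from = character(0), to = character(0),
                    weight = numeric(0), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = nodes)
})

#' @describeIn CogAggregateGraph export as GraphML.
#' @param file output path.
#' @export
setMethod("writeGraphML", "CogAggregateGraph", function(x, file, ...) {
  igraph::write_graph(asIgraph(x), file, format = "graphml")
  invisible(file)
})
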