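#' @include AllClasses.R AllGenerics.R utils.R
#' @importFrom igraph graph_from_data_frame components coreness degree
#'   induced_subgraph V write_graph vcount ecount make_empty_graph
#'   as_edgelist edge_density neighbors add_vertices
NULL

#' Construct an InteractionNetwork
#'
#' Canonicalises an edge table into a simple undirected graph: self-loops
#' are dropped (with a warning), each unordered pair becomes one edge with
#' the maximum score and the union of source tags, endpoints are ordered
#' \code{from < to} and rows sorted.
#'
#' @param nodes character vector of gene ids (endpoints are added
#'   automatically).
#' @param edges data.frame with columns \code{from}, \code{to} and
#'   optionally \code{score}, \code{sources}.
#' @param scope species id or a label such as \code{"ortholog-superset"}.
#' @param warnLoops warn when self-loop rows are dropped.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(nodes = character(0), edges = NULL,
                               scope = NA_character_, warnLoops = TRUE) {
  if (is.null(edges) || !nrow(edges)) {
    e <- emptyEdgeFrame()
  } else {
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    score <- if ("score" %in% names(edges)) as.numeric(edges$score)
             else rep(NA_real_, length(from))
    sources <- if ("sources" %in% names(edges)) as.character(edges$sources)
               else rep("", length(from))
    loops <- from == to
    if (any(loops)) {
      if (warnLoops)
        warning(sprintf("dropped %d self-loop edge(s) (e.g. %s)",
                        sum(loops), from[which(loops)[1]]), call. = FALSE)
      from <- from[!loops]; to <- to[!loops]
      score <- score[!loops]; sources <- sources[!loops]
    }
    if (!length(from)) {
      nodes <- sort(unique(as.character(nodes)))
      return(new("InteractionNetwork", scope = as.character(scope),
                 nodes = nodes, edges = emptyEdgeFrame()))
    }
    pk <- pairKey(from, to)
    e <- data.frame(from = pk$a, to = pk$b, score = score,
                    sources = sources, key = pk$key,
                    stringsAsFactors = FALSE)
    merged <- lapply(split(e, e$key), function(d) {
      srcs <- sort(unique(unlist(strsplit(d$sources, ";", fixed = TRUE))))
      srcs <- srcs[nzchar(srcs)]
      data.frame(from = d$from[1], to = d$to[1],
                 score = if (all(is.na(d$score))) NA_real_
                         else max(d$score, na.rm = TRUE),
                 sources = paste(srcs, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    e <- do.call(rbind, merged)
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), e$from, e$to)))
  new("InteractionNetwork", scope = as.character(scope), nodes = nodes,
      edges = e)
}

#' Read a scored edge list
#'
#' Tab-separated file with header and columns \code{gene_a}, \code{gene_b},
#' \code{source} and optionally \code{score}. Rows with \code{gene_a ==
#' gene_b} are dropped with a warning; duplicate pairs merge keeping the
#' maximum score and the union of sources. When a community is supplied,
#' every gene id must belong to it (ID mismatches fail early); otherwise
#' nodes are taken from the file.
#'
#' @param file path to the edge-list TSV.
#' @param community optional \linkS4class{Community} for id validation.
#' @param scope scope label for the network (default: inferred from the
#'   community species of the endpoint genes, else \code{NA}).
#' @param minScore optional score threshold; edges below it are dropped at
#'   read time.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readEdgeList <- function(file, community = NULL, scope = NULL,
                         minScore = NULL) {
  lines <- readLines(file)
  if (!length(lines)) stop("edge list is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  body <- which(seq_along(lines) > 1L & nzchar(lines))
  nf <- lengths(fields)
  bad <- body[nf[body] < 3L | nf[body] > 4L]
  if (length(bad))
    stop(sprintf("malformed edge row at line %d: expected 3 or 4 columns, got %d",
                 bad[1], nf[bad[1]]), call. = FALSE)
  e <- data.frame(
    from = vapply(fields[body], `[`, "", 1L),
    to = vapply(fields[body], `[`, "", 2L),
    sources = vapply(fields[body], `[`, "", 3L),
    score = vapply(fields[body], function(f)
      if (length(f) >= 4L) suppressWarnings(as.numeric(f[4L]))
      else NA_real_, 0),
    stringsAsFactors = FALSE)
  if (!is.null(minScore))
    e <- e[!is.na(e$score) & e$score >= minScore, , drop = FALSE]
  if (!is.null(community)) {
    unknown <- setdiff(unique(c(e$from, e$to)), geneIds(community))
    if (length(unknown))
      stop(sprintf("edge list references gene(s) not in the community: %s",
                   paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
    if (is.null(scope)) {
      sp <- unique(community@genes$species_id[
        community@genes$gene_id %in% c(e$from, e$to)])
      scope <- if (length(sp) == 1L) sp else "mixed"
    }
  }
  net <- InteractionNetwork(edges = e,
                            scope = if (is.null(scope)) NA_character_
                                    else scope)
  ouLog("edges: read %d edges over %d nodes from %s",
        nrow(net@edges), length(net@nodes), file)
  net
}

#' Infer interactions from pathway co-membership
#'
#' Places an edge between every pair of genes sharing a pathway (within a
#' species), the classical metabolic-network reading of pathway databases.
#' With \code{requireEC = TRUE} (default) genes lacking an Enzyme
#' Commission number in the community annotation are excluded before
#' pairing, restricting co-membership to enzymatic genes. Edges are
#' unioned over pathways and de-duplicated.
#'
#' @param community a \linkS4class{Community}.
#' @param pathwayTable data.frame or TSV path with columns
#'   \code{species_id}, \code{gene_id}, \code{pathway_id}.
#' @param requireEC restrict to EC-bearing genes (default \code{TRUE}).
#' @return An \linkS4class{InteractionNetwork} with source tag
#'   \code{"pathway-comembership"}.
#' @export
inferComembership <- function(community, pathwayTable, requireEC = TRUE) {
  if (is.character(pathwayTable))
    pathwayTable <- read.delim(pathwayTable, stringsAsFactors = FALSE)
  stopifnot(all(c("species_id", "gene_id", "pathway_id") %in%
                names(pathwayTable)))
  unknown <- setdiff(unique(pathwayTable$gene_id), geneIds(community))
  if (length(unknown))
    stop(sprintf("pathway table references unknown gene(s): %s",
                 paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
  if (requireEC) {
    ecg <- names(ecNumbers(community))
    pathwayTable <- pathwayTable[pathwayTable$gene_id %in% ecg, ,
                                 drop = FALSE]
  }
  edges <- NULL
  grp <- split(pathwayTable$gene_id,
               paste(pathwayTable$species_id, pathwayTable$pathway_id,
                     sep = "\r"))
  for (members in grp) {
    members <- sort(unique(members))
    if (length(members) < 2L) next
    cmb <- combn(members, 2L)
    edges <- rbind(edges, data.frame(from = cmb[1, ], to = cmb[2, ],
                                     sources = "pathway-comembership",
                                     stringsAsFactors = FALSE))
  }
  sp <- unique(pathwayTable$species_id)
  InteractionNetwork(edges = edges,
                     scope = if (length(sp) == 1L) sp else "mixed")
}

#' Impute interactions across species by orthology (interolog transfer)
#'
#' For every edge (a1, a2) of the species-A network whose endpoints both
#' have ortholog partners, an edge is created between the partner genes of
#' species B, tagged \code{"imported"} and carrying the original score.
#' Pairs collapsing onto a single B gene would create self-loops and are
#' dropped (logged). In one-way mode a species-A gene may serve several B
#' genes, so one A edge can yield several imputed B edges.
#'
#' @param net an \linkS4class{InteractionNetwork} over species-A genes.
#' @param map an \linkS4class{OrthologMap} from species A to species B.
#' @return An \linkS4class{InteractionNetwork} scoped to species B.
#' @export
imputeInteractions <- function(net, map) {
  p <- map@pairs
  e <- net@edges
  out <- NULL
  if (nrow(e) && nrow(p)) {
    bOf <- split(p$gene_b, p$gene_a)
    keep <- e$from %in% names(bOf) & e$to %in% names(bOf)
    e <- e[keep, , drop = FALSE]
    if (nrow(e)) {
      lst <- vector("list", nrow(e))
      for (i in seq_len(nrow(e))) {
        g <- expand.grid(b1 = bOf[[e$from[i]]], b2 = bOf[[e$to[i]]],
                         stringsAsFactors = FALSE)
        lst[[i]] <- data.frame(from = g$b1, to = g$b2, score = e$score[i],
                               sources = "imported",
                               stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, lst)
      loops <- sum(out$from == out$to)
      if (loops)
        ouLog("impute: dropped %d ortholog-collision self-loop(s)", loops)
      out <- out[out$from != out$to, , drop = FALSE]
    }
  }
  net2 <- InteractionNetwork(nodes = unique(p$gene_b), edges = out,
                             scope = map@speciesB, warnLoops = FALSE)
  ouLog("impute: %d imputed edges over %d genes of %s",
        nrow(net2@edges), length(net2@nodes), map@speciesB)
  net2
}

#' Induced subgraph with zero-connectivity elimination
#'
#' Restricts the network to a gene set and removes every gene left without
#' a single interaction inside the subgraph (degree 0). Unknown ids in the
#' input set are ignored with a warning. The operation is idempotent.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param geneSet character vector of gene ids.
#' @param dropIsolated remove degree-0 nodes (default \code{TRUE}).
#' @return An \linkS4class{InteractionNetwork}.
#' @export
inducedSubgraph <- function(net, geneSet, dropIsolated = TRUE) {
  geneSet <- unique(as.character(geneSet))
  unknown <- setdiff(geneSet, net@nodes)
  if (length(unknown))
    warning(sprintf("%d id(s) not in network ignored (e.g. %s)",
                    length(unknown), unknown[1]), call. = FALSE)
  keep <- intersect(geneSet, net@nodes)
  e <- net@edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  nodes <- if (dropIsolated) unique(c(e$from, e$to)) else keep
  InteractionNetwork(nodes = nodes, edges = e, scope = net@scope)
}

#' Index of aggregation
#'
#' Fraction of nodes in the largest connected component; equals 1.0
#' exactly when every node holds a path to all other nodes.
#'
#' @param net a non-empty \linkS4class{InteractionNetwork}.
#' @return Numeric in (0, 1].
#' @export
indexOfAggregation <- function(net) {
  if (!length(net@nodes)) stop("empty network", call. = FALSE)
  g <- asIgraph(net)
  comp <- igraph::components(g)
  max(comp$csize) / igraph::vcount(g)
}

#' Interaction coverage of a species
#'
#' Percentage of the species' genes holding at least one interaction to
#' another gene in the network (degree >= 1), rounded half-up to two
#' decimals.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param community a \linkS4class{Community}.
#' @param species species id.
#' @return Numeric percentage in [0, 100].
#' @export
interactionCoverage <- function(net, community, species) {
  ids <- geneIds(community, species)
  if (!length(ids))
    stop(sprintf("species '%s' has no genes", species), call. = FALSE)
  connected <- unique(c(net@edges$from, net@edges$to))
  roundHalfUp(100 * sum(ids %in% connected) / length(ids), 2)
}

## ---- methods -------------------------------------------------------------

#' @describeIn InteractionNetwork node ids.
#' @param x an \linkS4class{InteractionNetwork}.
#' @export
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)

#' @describeIn InteractionNetwork canonical edge table.
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @describeIn InteractionNetwork scope label.
#' @export
setMethod("networkScope", "InteractionNetwork", function(x) x@scope)

#' @describeIn InteractionNetwork convert to an \pkg{igraph} graph
#'   (undirected, with \code{score} and \code{sources} edge attributes).
#' @param ... unused.
#' @export
setMethod("asIgraph", "InteractionNetwork", function(x, ...) {
  if (!length(x@nodes)) return(igraph::make_empty_graph(directed = FALSE))
  igraph::graph_from_data_frame(
    x@edges, directed = FALSE,
    vertices = data.frame(name = x@nodes, stringsAsFactors = FALSE))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork (scope: %s): %d nodes, %d edges\n",
              object@scope, length(object@nodes), nrow(object@edges)))
})

#' @describeIn InteractionNetwork export as GraphML.
#' @param file output path.
#' @export
setMethod("writeGraphML", "InteractionNetwork", function(x, file, ...) {
  igraph::write_graph(asIgraph(x), file, format = "graphml")
  invisible(file)
})

#' Write a network as an edge-list TSV
#' @param net an \linkS4class{InteractionNetwork}.
#' @param file output path.
#' @export
writeEdgeList <- function(net, file) {
  e <- net@edges
  lines <- c("gene_a\tgene_b\tsource\tscore",
             if (nrow(e)) paste(e$from, e$to, e$sources,
                                ifelse(is.na(e$score), "", e$score),
                                sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' @describeIn OrthologMap the (gene_a, gene_b, score, identity) table.
#' @param x an \linkS4class{OrthologMap}.
#' @export
setMethod("orthologPairs", "OrthologMap", function(x) x@pairs)

setMethod("show", "OrthologMap", function(object) {
  cat(sprintf("OrthologMap %s -> %s (%s): %d pairs\n", object@speciesA,
              object@speciesB, object@mode, nrow(object@pairs)))
})
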