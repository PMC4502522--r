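#' @include AllClasses.R AllGenerics.R mcode.R
NULL

#' Default COG category partition for unit tallies
#'
#' Energy = category C (energy production and conversion); transport =
#' categories E (amino acid transport and metabolism), H (coenzyme
#' transport and metabolism), P (inorganic ion transport and metabolism)
#' and Q (secondary metabolites biosynthesis, transport and catabolism).
#' @return Named list of character vectors of COG codes.
#' @export
defaultCategoryPartition <- function() {
  list(energy = "C", transport = c("E", "H", "P", "Q"))
}

#' Aggregate interaction edges between molecular units
#'
#' The weight of a unit pair is the number of distinct network edges with
#' one endpoint in each unit; members shared by both units (possible with
#' fluff) are excluded via the \code{U_i \\ U_j} convention so that a
#' shared gene never contributes to the pair's weight. Pairs below
#' \code{minEdgeThreshold} are omitted.
#'
#' @param units list of \linkS4class{FunctionalUnit}.
#' @param net the \linkS4class{InteractionNetwork} the units were derived
#'   from.
#' @param minEdgeThreshold minimum cross-edge count (default 1).
#' @return data.frame(unit_a, unit_b, weight) with unit_a < unit_b.
#' @export
unitEdges <- function(units, net, minEdgeThreshold = 1L) {
  memb <- lapply(units, unitMembers)
  unknown <- setdiff(unique(unlist(memb)), net@nodes)
  if (length(unknown))
    stop(sprintf("unit member(s) not in network: %s",
                 paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
  e <- net@edges
  out <- NULL
  n <- length(units)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ui <- setdiff(memb[[i]], memb[[j]])
    uj <- setdiff(memb[[j]], memb[[i]])
    w <- sum((e$from %in% ui & e$to %in% uj) |
               (e$from %in% uj & e$to %in% ui))
    if (w >= minEdgeThreshold)
      out <- rbind(out, data.frame(unit_a = i, unit_b = j, weight = w))
  }
  if (is.null(out))
    out <- data.frame(unit_a = integer(0), unit_b = integer(0),
                      weight = integer(0))
  out
}

#' Overlay species-specific genes onto units
#'
#' Attaches non-ortholog (species-specific) genes to units through the
#' species' own interaction network: for each unit and specific gene,
#' \code{n_links} is the number of edges from the gene to unit members.
#' Genes linking to no unit at all are omitted.
#'
#' @param units list of \linkS4class{FunctionalUnit}.
#' @param specificGenes character vector of species-specific gene ids;
#'   none of them may be a unit member.
#' @param netSpecific \linkS4class{InteractionNetwork} containing both the
#'   specific genes and the unit members.
#' @return data.frame(unit_id, gene_id, n_links).
#' @export
overlaySpecificGenes <- function(units, specificGenes, netSpecific) {
  memb <- lapply(units, unitMembers)
  clash <- intersect(specificGenes, unlist(memb))
  if (length(clash))
    stop(sprintf("gene(s) both specific and unit member: %s",
                 paste(head(clash, 5), collapse = ", ")), call. = FALSE)
  e <- netSpecific@edges
  out <- NULL
  for (g in sort(unique(specificGenes))) {
    nb <- c(e$to[e$from == g], e$from[e$to == g])
    for (i in seq_along(units)) {
      nl <- sum(nb %in% memb[[i]])
      if (nl > 0L)
        out <- rbind(out, data.frame(unit_id = i, gene_id = g,
                                     n_links = nl,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(unit_id = integer(0), gene_id = character(0),
                      n_links = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-unit COG group tallies
#'
#' Counts, for each unit, how many member genes fall into each group of a
#' COG category partition (a gene annotated to categories of several
#' groups counts once in each).
#'
#' @param units list of \linkS4class{FunctionalUnit}.
#' @param community a \linkS4class{Community}.
#' @param partition named list group -> COG category codes.
#' @return data.frame(unit_id, group, n_genes).
#' @export
annotateUnits <- function(units, community,
                          partition = defaultCategoryPartition()) {
  cats <- cogCategories(community)
  out <- NULL
  for (i in seq_along(units)) {
    for (grp in names(partition)) {
      n <- sum(vapply(unitMembers(units[[i]]), function(g)
        any(cats[[g]] %in% partition[[grp]]), TRUE))
      out <- rbind(out, data.frame(unit_id = i, group = grp, n_genes = n,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(unit_id = integer(0), group = character(0),
                      n_genes = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a molecular process model
#'
#' Combines MCODE units with inter-unit aggregate edges, the
#' species-specific gene overlay and per-unit COG tallies into one
#' \linkS4class{ProcessModel}.
#'
#' @param units list of \linkS4class{FunctionalUnit}.
#' @param net segmentation input network (for unit edges).
#' @param community a \linkS4class{Community} (for tallies);
#'   optional.
#' @param specificGenes,netSpecific overlay inputs; optional.
#' @param minEdgeThreshold see \code{\link{unitEdges}}.
#' @param partition see \code{\link{annotateUnits}}.
#' @return A \linkS4class{ProcessModel}.
#' @export
buildProcessModel <- function(units, net, community = NULL,
                              specificGenes = NULL, netSpecific = NULL,
                              minEdgeThreshold = 1L,
                              partition = defaultCategoryPartition()) {
  ue <- unitEdges(units, net, minEdgeThreshold)
  ov <- if (!is.null(specificGenes) && !is.null(netSpecific))
    overlaySpecificGenes(units, specificGenes, netSpecific)
  else data.frame(unit_id = integer(0), gene_id = character(0),
                  n_links = integer(0), stringsAsFactors = FALSE)
  ta <- if (!is.null(community)) annotateUnits(units, community, partition)
  else data.frame(unit_id = integer(0), group = character(0),
                  n_genes = integer(0), stringsAsFactors = FALSE)
  new("ProcessModel", units = units, unitEdges = ue, overlay = ov,
      tallies = ta)
}

## ---- methods -------------------------------------------------------------

#' @describeIn ProcessModel the ranked unit list.
#' @param x a \linkS4class{ProcessModel}.
#' @export
setMethod("modelUnits", "ProcessModel", function(x) x@units)
#' @describeIn ProcessModel weighted unit-pair edges.
#' @export
setMethod("modelUnitEdges", "ProcessModel", function(x) x@unitEdges)
#' @describeIn ProcessModel species-specific gene overlay.
#' @export
setMethod("modelOverlay", "ProcessModel", function(x) x@overlay)
#' @describeIn ProcessModel per-unit COG group tallies.
#' @export
setMethod("modelTallies", "ProcessModel", function(x) x@tallies)

setMethod("show", "ProcessModel", function(object) {
  cat(sprintf("ProcessModel: %d units, %d unit edges, %d overlay genes\n",
              length(object@units), nrow(object@unitEdges),
              length(unique(object@overlay$gene_id))))
})

#' Serialise a process model to JSON
#'
#' Deterministic JSON with units, inter-unit edges, overlay and tallies;
#' identical inputs produce byte-identical files.
#'
#' @param model a \linkS4class{ProcessModel}.
#' @param file output path.
#' @export
writeProcessModel <- function(model, file) {
  obj <- list(
    units = unitsToList(model@units),
    unit_edges = model@unitEdges,
    overlay = model@overlay,
    tallies = model@tallies)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  invisible(file)
}

#' @describeIn ProcessModel export the unit graph as GraphML (nodes carry
#'   size, score and per-group tallies; edges carry the cross-interaction
#'   weight).
#' @param file output path.
#' @param ... unused.
#' @export
setMethod("writeGraphML", "ProcessModel", function(x, file, ...) {
  n <- length(x@units)
  nodes <- data.frame(
    name = paste0("unit", seq_len(n)),
    size = vapply(x@units, function(u) length(u@members), 1L),
    score = vapply(x@units, function(u) u@score, 0),
    overlay_links = vapply(seq_len(n), function(i)
      sum(x@overlay$n_links[x@overlay$unit_id == i]), 0),
    stringsAsFactors = FALSE)
  for (grp in unique(x@tallies$group))
    nodes[[paste0("n_", grp)]] <- vapply(seq_len(n), function(i) {
      v <- x@tallies$n_genes[x@tallies$unit_id == i &
                               x@tallies$group == grp]
      if (length(v)) v else 0L
    }, 0L)
  e <- if (nrow(x@unitEdges)) {
    data.frame(from = paste0("unit", x@unitEdges$unit_a),
               to = paste0("unit", x@unitEdges$unit_b),
               weight = x@unitEdges$weight, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(e, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
})
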