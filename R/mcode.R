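#' @include AllClasses.R AllGenerics.R network.R
NULL

#' MCODE parameters
#'
#' Defaults follow the documented defaults of the Cytoscape MCODE plugin:
#' loops excluded, degree cutoff 2, node score cutoff 0.2, 2-core
#' requirement, maximum expansion depth 100, haircut on, fluff off with
#' fluff density cutoff 0.1.
#'
#' @param includeLoops ignored for scoring (networks here are simple);
#'   kept for interface completeness.
#' @param degreeCutoff vertices below this degree get weight 0.
#' @param nodeScoreCutoff fraction in [0,1]: a neighbour joins a complex
#'   when its weight is at least \code{(1 - nodeScoreCutoff)} times the
#'   seed weight.
#' @param kCore complexes without a k-core of this order are discarded.
#' @param maxDepth maximum breadth-first distance from the seed.
#' @param haircut iteratively remove degree-1 members (to a fixpoint).
#' @param fluff add unvisited neighbours whose closed-neighbourhood
#'   density exceeds \code{fluffDensityCutoff}; may create overlaps.
#' @param fluffDensityCutoff density threshold for fluff.
#' @return Named list of validated parameters.
#' @export
mcodeParams <- function(includeLoops = FALSE, degreeCutoff = 2L,
                        nodeScoreCutoff = 0.2, kCore = 2L,
                        maxDepth = 100L, haircut = TRUE, fluff = FALSE,
                        fluffDensityCutoff = 0.1) {
  stopifnot(nodeScoreCutoff >= 0, nodeScoreCutoff <= 1, degreeCutoff >= 0,
            kCore >= 0, maxDepth >= 1, fluffDensityCutoff >= 0)
  list(includeLoops = isTRUE(includeLoops),
       degreeCutoff = as.integer(degreeCutoff),
       nodeScoreCutoff = nodeScoreCutoff, kCore = as.integer(kCore),
       maxDepth = as.integer(maxDepth), haircut = isTRUE(haircut),
       fluff = isTRUE(fluff), fluffDensityCutoff = fluffDensityCutoff)
}

graphDensity <- function(n, e) {
  if (n < 2L) return(0)
  2 * e / (n * (n - 1))
}

# adjacency as named list of character vectors, nodes sorted
adjacencyList <- function(net) {
  adj <- setNames(vector("list", length(net@nodes)), net@nodes)
  for (v in net@nodes) adj[[v]] <- character(0)
  e <- net@edges
  if (nrow(e)) {
    sp1 <- split(e$to, e$from)
    sp2 <- split(e$from, e$to)
    for (v in names(sp1)) adj[[v]] <- c(adj[[v]], sp1[[v]])
    for (v in names(sp2)) adj[[v]] <- c(adj[[v]], sp2[[v]])
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

countInternalEdges <- function(net, members) {
  e <- net@edges
  sum(e$from %in% members & e$to %in% members)
}

# highest k-core of the subgraph induced on `members`: returns list(k,
# vertices) via igraph coreness
highestKCore <- function(net, members) {
  e <- net@edges
  e <- e[e$from %in% members & e$to %in% members, , drop = FALSE]
  if (!nrow(e)) return(list(k = 0L, vertices = members))
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = members, stringsAsFactors = FALSE))
  core <- igraph::coreness(g)
  kmax <- max(core)
  list(k = as.integer(kmax), vertices = names(core)[core >= kmax])
}

#' MCODE vertex weighting
#'
#' Scores each vertex by the density of the highest k-core of its closed
#' neighbourhood: the induced subgraph on the vertex plus its neighbours
#' is peeled to the non-empty k-core with maximal k, and the weight is
#' \code{k_max * density(core)}. Vertices below the degree cutoff score 0.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param params \code{\link{mcodeParams}}.
#' @return Named numeric vector of weights (one per node).
#' @export
vertexWeights <- function(net, params = mcodeParams()) {
  adj <- adjacencyList(net)
  w <- setNames(numeric(length(net@nodes)), net@nodes)
  for (v in net@nodes) {
    if (length(adj[[v]]) < params$degreeCutoff) next
    nb <- c(v, adj[[v]])
    core <- highestKCore(net, nb)
    if (core$k == 0L) next
    eInt <- countInternalEdges(net, core$vertices)
    w[v] <- core$k * graphDensity(length(core$vertices), eInt)
  }
  w
}

#' MCODE complex prediction
#'
#' Segments the network into densely connected molecular units. Vertices
#' are seeded in decreasing weight order (ties by lexicographic gene id);
#' from each unvisited seed a breadth-first expansion adds a neighbour
#' when its weight is at least \code{(1 - nodeScoreCutoff)} times the seed
#' weight, up to \code{maxDepth} steps from the seed. Vertices already in
#' a complex are neither re-seeded nor re-added, so complexes are disjoint
#' unless fluff is enabled. Post-processing per complex: complexes
#' without a \code{kCore}-core are discarded; haircut removes degree-1
#' members iteratively to a fixpoint; fluff (off by default) adds
#' unvisited neighbours whose closed-neighbourhood density exceeds the
#' fluff cutoff and may create overlaps between units; complexes with
#' fewer than 2 members are dropped. Units are ranked by
#' \code{score = density * size}, ties by larger size then by
#' lexicographically smallest member, and numbered from 1. The procedure
#' is fully deterministic.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param params \code{\link{mcodeParams}}.
#' @return List of \linkS4class{FunctionalUnit}, ranked.
#' @export
findComplexes <- function(net, params = mcodeParams()) {
  nodes <- net@nodes
  if (!length(nodes)) return(list())
  adj <- adjacencyList(net)
  w <- vertexWeights(net, params)
  order_ <- nodes[order(-w[nodes], nodes)]
  visited <- setNames(logical(length(nodes)), nodes)

  complexes <- list()
  for (seed in order_) {
    if (visited[[seed]]) next
    thr <- w[[seed]] * (1 - params$nodeScoreCutoff)
    members <- seed
    depth <- setNames(0L, seed)
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (depth[[v]] >= params$maxDepth) next
      for (u in adj[[v]]) {
        if (visited[[u]] || u %in% members) next
        if (w[[u]] >= thr) {
          members <- c(members, u)
          depth[u] <- depth[[v]] + 1L
          queue <- c(queue, u)
        }
      }
    }
    visited[members] <- TRUE
    complexes[[length(complexes) + 1L]] <- list(seed = seed,
                                                members = sort(members))
  }

  units <- list()
  for (cx in complexes) {
    members <- cx$members
    core <- highestKCore(net, members)
    if (core$k < params$kCore) next
    if (params$haircut) {
      # iterated degree-1 removal to fixpoint (= 2-core of the complex)
      repeat {
        e <- net@edges
        e <- e[e$from %in% members & e$to %in% members, , drop = FALSE]
        deg <- table(factor(c(e$from, e$to), levels = members))
        drop <- names(deg)[deg < 2L]
        if (!length(drop)) break
        members <- setdiff(members, drop)
        if (!length(members)) break
      }
    }
    if (params$fluff && length(members)) {
      nbrs <- setdiff(sort(unique(unlist(adj[members]))), members)
      add <- character(0)
      for (u in nbrs) {
        if (visited[[u]]) next
        cn <- c(u, adj[[u]])
        dens <- graphDensity(length(cn), countInternalEdges(net, cn))
        if (dens > params$fluffDensityCutoff) add <- c(add, u)
      }
      members <- sort(c(members, add))
    }
    if (length(members) < 2L) next
    seed <- if (cx$seed %in% members) cx$seed else
      members[order(-w[members], members)][1]
    n <- length(members)
    dens <- graphDensity(n, countInternalEdges(net, members))
    units[[length(units) + 1L]] <- list(members = sort(members),
                                        seed = seed, density = dens,
                                        score = dens * n)
  }

  if (!length(units)) return(list())
  sz <- vapply(units, function(u) length(u$members), 1L)
  sc <- vapply(units, function(u) u$score, 0)
  first <- vapply(units, function(u) u$members[1], "")
  ord <- order(-sc, -sz, first)
  out <- vector("list", length(units))
  for (i in seq_along(ord)) {
    u <- units[[ord[i]]]
    out[[i]] <- new("FunctionalUnit", unitId = i, members = u$members,
                    seed = u$seed, score = u$score, density = u$density)
  }
  ouLog("mcode: %d units (sizes %s)", length(out),
        paste(vapply(out, function(u) length(u@members), 1L),
              collapse = ","))
  out
}

## ---- FunctionalUnit methods ---------------------------------------------

#' @describeIn FunctionalUnit member gene ids.
#' @param x a \linkS4class{FunctionalUnit}.
#' @export
setMethod("unitMembers", "FunctionalUnit", function(x) x@members)
#' @describeIn FunctionalUnit seed gene.
#' @export
setMethod("unitSeed", "FunctionalUnit", function(x) x@seed)
#' @describeIn FunctionalUnit density * size score.
#' @export
setMethod("unitScore", "FunctionalUnit", function(x) x@score)
#' @describeIn FunctionalUnit internal edge density.
#' @export
setMethod("unitDensity", "FunctionalUnit", function(x) x@density)
#' @describeIn FunctionalUnit rank (1 = best).
#' @export
setMethod("unitId", "FunctionalUnit", function(x) x@unitId)

setMethod("show", "FunctionalUnit", function(object) {
  cat(sprintf("FunctionalUnit %d: %d members, density %.3f, score %.3f (seed %s)\n",
              object@unitId, length(object@members), object@density,
              object@score, object@seed))
})

#' Write units as TSV (unit_id, gene_id, is_seed)
#' @param units list of \linkS4class{FunctionalUnit}.
#' @param file output path.
#' @export
writeUnits <- function(units, file) {
  lines <- "unit_id\tgene_id\tis_seed"
  for (u in units)
    lines <- c(lines, paste(u@unitId, u@members,
                            as.integer(u@members == u@seed), sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

unitsToList <- function(units) {
  lapply(units, function(u) list(
    unit_id = u@unitId, seed = u@seed, size = length(u@members),
    density = u@density, score = u@score, members = u@members))
}

#' Write units as JSON
#' @inheritParams writeUnits
#' @export
writeUnitsJSON <- function(units, file) {
  jsonlite::write_json(unitsToList(units), file, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(file)
}
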