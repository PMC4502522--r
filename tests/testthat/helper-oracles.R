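# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately share no code
# with the package internals.

options(OrthoUnits.quiet = TRUE)

# Exhaustive global alignment score under the affine gap model
# (gap of length L costs gapOpen + L * gapExtend): depth-first search over
# every monotone alignment, maximising the score. Exponential; only for
# short sequences.
oracleGlobalAlign <- function(a, b, mat, gapOpen = 10, gapExtend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  sub <- matrix(mat[A, B, drop = FALSE], nrow = na)
  openCost <- gapOpen + gapExtend
  best <- -Inf
  rec <- function(i, j, sc, prev) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) rec(i + 1L, j + 1L, sc + sub[i, j], 0L)
    if (i <= na)
      rec(i + 1L, j, sc - if (prev == 1L) gapExtend else openCost, 1L)
    if (j <= nb)
      rec(i, j + 1L, sc - if (prev == 2L) gapExtend else openCost, 2L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

randomProteinStr <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}

# adjacency list from a 2-column character edge matrix
oracleAdjacency <- function(nodes, edges) {
  adj <- lapply(setNames(nm = nodes), function(x) character(0))
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1]]] <- union(adj[[edges[r, 1]]], edges[r, 2])
    adj[[edges[r, 2]]] <- union(adj[[edges[r, 2]]], edges[r, 1])
  }
  adj
}

# highest k-core by literal iterative pruning over increasing k
oracleHighestKCore <- function(nodes, edges) {
  adj <- oracleAdjacency(nodes, edges)
  bestK <- 0L; bestV <- nodes
  k <- 1L
  repeat {
    keep <- nodes
    repeat {
      deg <- vapply(keep, function(v) length(intersect(adj[[v]], keep)), 1L)
      drop <- keep[deg < k]
      if (!length(drop)) break
      keep <- setdiff(keep, drop)
      if (!length(keep)) break
    }
    if (!length(keep)) break
    bestK <- k; bestV <- keep
    k <- k + 1L
  }
  list(k = bestK, vertices = sort(bestV))
}

oracleDensity <- function(vertices, edges) {
  n <- length(vertices)
  if (n < 2L) return(0)
  e <- sum(edges[, 1] %in% vertices & edges[, 2] %in% vertices)
  2 * e / (n * (n - 1))
}

# MCODE vertex weight by brute force: highest k-core of the closed
# neighbourhood, weight = k * density(core)
oracleMcodeWeights <- function(nodes, edges, degreeCutoff = 2L) {
  adj <- oracleAdjacency(nodes, edges)
  w <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    if (length(adj[[v]]) < degreeCutoff) next
    nb <- c(v, adj[[v]])
    sub <- edges[edges[, 1] %in% nb & edges[, 2] %in% nb, , drop = FALSE]
    core <- oracleHighestKCore(nb, sub)
    if (core$k > 0L)
      w[v] <- core$k * oracleDensity(core$vertices, sub)
  }
  w
}

# connected components by flood fill
oracleComponents <- function(nodes, edges) {
  adj <- oracleAdjacency(nodes, edges)
  seen <- setNames(logical(length(nodes)), nodes)
  sizes <- integer(0)
  for (v in nodes) {
    if (seen[[v]]) next
    queue <- v; comp <- 0L
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[[u]]) next
      seen[u] <- TRUE; comp <- comp + 1L
      queue <- c(queue, adj[[u]][!seen[adj[[u]]]])
    }
    sizes <- c(sizes, comp)
  }
  sizes
}

# Erdos-Renyi style random edge table over given node ids
randomEdgeTable <- function(nodes, p) {
  prs <- t(combn(nodes, 2L))
  prs[runif(nrow(prs)) < p, , drop = FALSE]
}

edgeKey <- function(df) {
  if (!nrow(df)) return(character(0))
  a <- pmin(df[[1]], df[[2]]); b <- pmax(df[[1]], df[[2]])
  sort(paste(a, b, sep = "|"))
}

# small community builder for annotation tests
makeTestCommunity <- function(rows, fastaSeqs = NULL) {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("species_id\tgene_id\titem\tvalue", rows), tsv)
  fastas <- character(0)
  if (!is.null(fastaSeqs)) {
    for (sp in names(fastaSeqs)) {
      fa <- tempfile(fileext = ".fasta")
      writeLines(unlist(lapply(names(fastaSeqs[[sp]]), function(g)
        c(paste0(">", g), fastaSeqs[[sp]][[g]]))), fa)
      fastas[sp] <- fa
    }
  }
  readCommunity(tsv, fastas)
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
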