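writeEdgeTSV <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tsource\tscore", rows), f)
  f
}

test_that("edge lists deduplicate undirected pairs and drop self-loops", {
  net <- readEdgeList(writeEdgeTSV(c("x\ty\tstring-like\t0.5",
                                     "y\tx\tkegg\t0.9")))
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_equal(e$score, 0.9)
  expect_equal(e$sources, "kegg;string-like")
  expect_warning(net2 <- readEdgeList(writeEdgeTSV("x\tx\tstring-like\t0.5")),
                 "self-loop")
  expect_equal(nrow(networkEdges(net2)), 0L)
  f <- writeEdgeTSV(c("x\ty\tsrc\t0.1", "x\ty"))
  expect_error(readEdgeList(f), "line 3")
})

test_that("edge lists validate gene ids against the community", {
  comm <- makeTestCommunity(c("sp1\tx\tpatric_id\t1",
                              "sp1\ty\tpatric_id\t2"))
  f <- writeEdgeTSV("x\tz\tstring-like\t0.5")
  expect_error(readEdgeList(f, comm), "z")
})

test_that("pathway co-membership wires EC-bearing genes pairwise", {
  rows <- c(sprintf("sp1\tg%d\tec_number\t1.1.1.%d", 1:3, 1:3),
            "sp1\tg4\tpatric_id\tnoEC")
  comm <- makeTestCommunity(rows)
  pw <- data.frame(species_id = "sp1", gene_id = paste0("g", 1:3),
                   pathway_id = "pwy1")
  net <- inferComembership(comm, pw)
  expect_equal(nrow(networkEdges(net)), 3L)  # triangle
  # one gene lacking EC -> only the remaining pair
  pw2 <- data.frame(species_id = "sp1", gene_id = paste0("g", c(1, 2, 4)),
                    pathway_id = "pwy1")
  expect_equal(nrow(networkEdges(inferComembership(comm, pw2))), 1L)
  expect_equal(nrow(networkEdges(inferComembership(comm, pw2,
                                                   requireEC = FALSE))), 3L)
  expect_error(inferComembership(comm, data.frame(
    species_id = "sp1", gene_id = "nope", pathway_id = "p")), "nope")
})

test_that("co-membership edge count is n(n-1)/2 per pathway", {
  for (n in c(2, 5, 9)) {
    rows <- sprintf("sp1\tg%02d\tec_number\t1.1.1.1", 1:n)
    comm <- makeTestCommunity(rows)
    pw <- data.frame(species_id = "sp1",
                     gene_id = sprintf("g%02d", 1:n), pathway_id = "p")
    expect_equal(nrow(networkEdges(inferComembership(comm, pw))),
                 n * (n - 1) / 2)
  }
})

test_that("interolog imputation maps edges through the ortholog pairing", {
  map <- new("OrthologMap", speciesA = "A", speciesB = "B",
             mode = "one-way",
             pairs = data.frame(gene_a = c("a1", "a2"),
                                gene_b = c("b1", "b2"),
                                score = c(1, 1), identity = c(99, 99)))
  empty <- InteractionNetwork(scope = "A")
  expect_equal(nrow(networkEdges(imputeInteractions(empty, map))), 0L)
  net <- InteractionNetwork(edges = data.frame(
    from = "a1", to = "a2", score = 0.7, sources = "string-like"),
    scope = "A")
  out <- imputeInteractions(net, map)
  e <- networkEdges(out)
  expect_equal(e$from, "b1")
  expect_equal(e$to, "b2")
  expect_equal(e$score, 0.7)
  expect_equal(e$sources, "imported")
  expect_equal(networkScope(out), "B")
})

test_that("induced subgraph drops zero-connectivity genes and is idempotent", {
  # 386-style fixture: connected set plus one isolated input gene
  edges <- data.frame(from = paste0("g", 1:9), to = paste0("g", c(2:9, 1)))
  net <- InteractionNetwork(nodes = paste0("g", 1:10), edges = edges)
  sub <- inducedSubgraph(net, paste0("g", 1:10))
  expect_equal(length(networkNodes(sub)), 9L)
  # no internal edges -> empty graph
  sub2 <- inducedSubgraph(net, c("g1", "g3", "g10"))
  expect_equal(length(networkNodes(sub2)), 0L)
  expect_warning(inducedSubgraph(net, c("g1", "g2", "unknown")), "unknown")
  set.seed(404)
  for (i in 1:10) {
    nodes <- sprintf("n%02d", 1:12)
    em <- randomEdgeTable(nodes, 0.25)
    net <- InteractionNetwork(nodes = nodes,
                              edges = as.data.frame(em) |>
                                setNames(c("from", "to")))
    keep <- sample(nodes, 7)
    sub <- inducedSubgraph(net, keep)
    # oracle: direct filter, then degree>=1 filter
    inKeep <- em[, 1] %in% keep & em[, 2] %in% keep
    expect_equal(edgeKey(networkEdges(sub)[, c("from", "to")]),
                 edgeKey(as.data.frame(em[inKeep, , drop = FALSE])))
    again <- inducedSubgraph(sub, networkNodes(sub))
    expect_equal(networkEdges(again), networkEdges(sub))
    expect_equal(networkNodes(again), networkNodes(sub))
  }
})

test_that("index of aggregation is the largest-component fraction", {
  conn <- InteractionNetwork(edges = data.frame(
    from = paste0("g", 1:5), to = paste0("g", c(2:5, 1))))
  expect_identical(indexOfAggregation(conn), 1)
  two <- InteractionNetwork(edges = data.frame(
    from = c("a1", "b1"), to = c("a2", "b2")))
  expect_equal(indexOfAggregation(two), 0.5)
  expect_error(indexOfAggregation(InteractionNetwork()), "empty")
  set.seed(505)
  for (i in 1:15) {
    nodes <- sprintf("n%02d", 1:14)
    em <- randomEdgeTable(nodes, runif(1, 0.05, 0.3))
    net <- InteractionNetwork(nodes = nodes,
                              edges = setNames(as.data.frame(em),
                                               c("from", "to")))
    expect_equal(indexOfAggregation(net),
                 max(oracleComponents(nodes, em)) / length(nodes))
  }
})

test_that("interaction coverage counts genes with at least one edge", {
  comm <- makeTestCommunity(sprintf("sp1\tg%02d\tpatric_id\t%d", 1:8, 1:8))
  isolated <- InteractionNetwork(nodes = sprintf("g%02d", 1:8))
  expect_equal(interactionCoverage(isolated, comm, "sp1"), 0)
  clique <- InteractionNetwork(edges = setNames(as.data.frame(
    t(combn(sprintf("g%02d", 1:8), 2))), c("from", "to")))
  expect_equal(interactionCoverage(clique, comm, "sp1"), 100)
  cov <- coverageTable(comm, networks = list(string = clique))
  expect_equal(cov$coverage[cov$section == "interaction"], 100)
})

test_that("GraphML and edge-list export round-trips the topology", {
  net <- InteractionNetwork(edges = data.frame(
    from = c("a", "b", "c"), to = c("b", "c", "d"),
    score = c(0.5, 0.6, 0.7), sources = "string-like"))
  gml <- tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  tsv <- tempfile(fileext = ".tsv")
  writeEdgeList(net, tsv)
  back <- readEdgeList(tsv)
  expect_equal(networkEdges(back)[, c("from", "to", "score")],
               networkEdges(net)[, c("from", "to", "score")])
})
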