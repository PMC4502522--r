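mkUnit <- function(id, members, net) {
  e <- networkEdges(net)
  eInt <- sum(e$from %in% members & e$to %in% members)
  n <- length(members)
  dens <- if (n > 1) 2 * eInt / (n * (n - 1)) else 0
  new("FunctionalUnit", unitId = as.integer(id), members = sort(members),
      seed = sort(members)[1], score = dens * n, density = dens)
}

test_that("unit edge weights count distinct cross-unit interactions", {
  net <- InteractionNetwork(edges = data.frame(
    from = c("a", "a", "b", "c"), to = c("b", "c", "c", "d")))
  units <- list(mkUnit(1, c("a", "b"), net), mkUnit(2, c("c", "d"), net))
  ue <- unitEdges(units, net)
  expect_equal(ue$weight, 2L)  # edges (a,c) and (b,c)
  # disconnected units produce no edge
  net2 <- InteractionNetwork(nodes = letters[1:4], edges = data.frame(
    from = c("a", "c"), to = c("b", "d")))
  expect_equal(nrow(unitEdges(list(mkUnit(1, c("a", "b"), net2),
                                   mkUnit(2, c("c", "d"), net2)), net2)), 0L)
  expect_error(unitEdges(list(mkUnit(1, c("a", "zz"), net)), net), "zz")
})

test_that("unit edges match the exhaustive cross-edge oracle", {
  set.seed(321)
  for (rep in 1:10) {
    nodes <- sprintf("n%02d", 1:15)
    em <- randomEdgeTable(nodes, 0.3)
    net <- InteractionNetwork(nodes = nodes,
                              edges = setNames(as.data.frame(em),
                                               c("from", "to")))
    part <- split(nodes, sample(rep(1:3, length.out = 15)))
    units <- lapply(seq_along(part), function(i)
      mkUnit(i, part[[i]], net))
    ue <- unitEdges(units, net, minEdgeThreshold = 0)
    for (i in 1:2) for (j in (i + 1):3) {
      cnt <- sum((em[, 1] %in% part[[i]] & em[, 2] %in% part[[j]]) |
                   (em[, 1] %in% part[[j]] & em[, 2] %in% part[[i]]))
      row <- ue[ue$unit_a == i & ue$unit_b == j, ]
      expect_equal(if (nrow(row)) row$weight else 0L, cnt)
    }
    # total cross weight can never exceed the network edge count
    expect_lte(sum(ue$weight), nrow(networkEdges(net)))
  }
})

test_that("overlay links species-specific genes to units by edge count", {
  net <- InteractionNetwork(edges = data.frame(
    from = c("u1a", "u1b", "u1a", "s1", "s1", "s1", "s1"),
    to   = c("u1b", "u1c", "u1c", "u1a", "u1b", "u1c", "u2a")))
  net <- InteractionNetwork(
    nodes = c(networkNodes(net), "u2b", "s2"),
    edges = rbind(networkEdges(net)[, c("from", "to")],
                  data.frame(from = "u2a", to = "u2b")))
  units <- list(mkUnit(1, c("u1a", "u1b", "u1c"), net),
                mkUnit(2, c("u2a", "u2b"), net))
  ov <- overlaySpecificGenes(units, c("s1", "s2"), net)
  expect_equal(ov$n_links[ov$gene_id == "s1" & ov$unit_id == 1], 3L)
  expect_equal(ov$n_links[ov$gene_id == "s1" & ov$unit_id == 2], 1L)
  expect_false("s2" %in% ov$gene_id)  # no links anywhere -> omitted
  expect_error(overlaySpecificGenes(units, c("u1a"), net), "u1a")
  expect_true(all(ov$n_links > 0))
})

test_that("unit tallies count genes per COG group, multi-group once each", {
  rows <- c(sprintf("A\tg%d\tcog_category\tC", 1:5),
            "A\tg5\tcog_category\tP",
            "A\tg6\tcog_category\tE")
  comm <- makeTestCommunity(rows)
  net <- InteractionNetwork(nodes = sprintf("g%d", 1:6),
                            edges = data.frame(from = sprintf("g%d", 1:5),
                                               to = sprintf("g%d", c(2:5, 1))))
  units <- list(mkUnit(1, sprintf("g%d", 1:5), net))
  ta <- annotateUnits(units, comm)
  expect_equal(ta$n_genes[ta$group == "energy"], 5L)
  expect_equal(ta$n_genes[ta$group == "transport"], 1L)  # g5 via P
})

test_that("a process model assembles and serialises deterministically", {
  g <- generateCommunity(synthConfig(seed = 23, nGenesA = 60, nGenesB = 10,
                                     orthologFraction = 0, nModules = 3,
                                     moduleSizeRange = c(5, 6)))
  units <- findComplexes(g$network)
  model <- buildProcessModel(units, g$network, community = g$community,
                             specificGenes = setdiff(
                               geneIds(g$community, "spA"),
                               unlist(lapply(units, unitMembers))),
                             netSpecific = g$network)
  expect_s4_class(model, "ProcessModel")
  expect_true(all(modelOverlay(model)$n_links >= 1))
  f1 <- tempfile(); f2 <- tempfile()
  writeProcessModel(model, f1)
  writeProcessModel(model, f2)
  expect_identical(readLines(f1), readLines(f2))
  gml <- tempfile(fileext = ".graphml")
  writeGraphML(model, gml)
  gg <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(gg), length(units))
})
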