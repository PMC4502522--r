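cliqueEdges <- function(ids) setNames(as.data.frame(t(combn(ids, 2))),
                                      c("from", "to"))

test_that("vertex weights equal k * density of the closed-neighbourhood core", {
  # isolated vertex scores 0; K4 vertices score 3 * 1.0
  net <- InteractionNetwork(nodes = c(paste0("k", 1:4), "iso"),
                            edges = cliqueEdges(paste0("k", 1:4)))
  w <- vertexWeights(net)
  expect_equal(unname(w[paste0("k", 1:4)]), rep(3, 4))
  expect_equal(unname(w["iso"]), 0)
})

test_that("vertex weights match the brute-force peeling oracle on random graphs", {
  set.seed(909)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    nodes <- sprintf("v%02d", 1:n)
    em <- randomEdgeTable(nodes, runif(1, 0.3, 0.7))
    net <- InteractionNetwork(nodes = nodes,
                              edges = setNames(as.data.frame(em),
                                               c("from", "to")))
    expect_equal(vertexWeights(net), oracleMcodeWeights(nodes, em),
                 info = paste("graph", i))
  }
})

test_that("haircut trims a pendant vertex off a clique unit", {
  e <- rbind(cliqueEdges(paste0("k", 1:5)),
             data.frame(from = "k5", to = "pendant"))
  units <- findComplexes(InteractionNetwork(edges = e))
  expect_length(units, 1L)
  expect_equal(unitMembers(units[[1]]), paste0("k", 1:5))
  expect_equal(unitDensity(units[[1]]), 1)
  expect_equal(unitScore(units[[1]]), 5)
})

test_that("two cliques joined through a connector vertex form two units", {
  e <- rbind(cliqueEdges(paste0("a", 1:5)), cliqueEdges(paste0("b", 1:5)),
             data.frame(from = c("a1", "x"), to = c("x", "b1")))
  units <- findComplexes(InteractionNetwork(edges = e))
  expect_length(units, 2L)
  expect_equal(unitMembers(units[[1]]), paste0("a", 1:5))
  expect_equal(unitMembers(units[[2]]), paste0("b", 1:5))
})

test_that("a direct bridge edge lets expansion merge equal-weight cliques", {
  # both endpoints keep the full clique weight, so the seeded expansion
  # walks across the bridge: one 10-vertex unit, not two
  e <- rbind(cliqueEdges(paste0("a", 1:5)), cliqueEdges(paste0("b", 1:5)),
             data.frame(from = "a1", to = "b1"))
  units <- findComplexes(InteractionNetwork(edges = e))
  expect_length(units, 1L)
  expect_length(unitMembers(units[[1]]), 10L)
})

test_that("units are disjoint with fluff off and overlap only via fluff", {
  set.seed(111)
  g <- generateCommunity(synthConfig(seed = 17, nGenesA = 120, nGenesB = 10,
                                     orthologFraction = 0, nModules = 5,
                                     moduleSizeRange = c(6, 8)))
  units <- findComplexes(g$network)
  memb <- unlist(lapply(units, unitMembers))
  expect_equal(anyDuplicated(memb), 0L)
  expect_true(all(memb %in% networkNodes(g$network)))
  # every unit holds >= 2 members and contains a 2-core
  for (u in units) {
    expect_gte(length(unitMembers(u)), 2L)
    sub <- networkEdges(g$network)
    sub <- sub[sub$from %in% unitMembers(u) & sub$to %in% unitMembers(u), ]
    core <- oracleHighestKCore(unitMembers(u), as.matrix(sub[, 1:2]))
    expect_gte(core$k, 2L)
  }
  fluffed <- findComplexes(g$network, mcodeParams(fluff = TRUE))
  for (u in units)
    expect_true(any(vapply(fluffed, function(f)
      all(unitMembers(u) %in% unitMembers(f)), TRUE)))
})

test_that("unit ranking is by score, deterministically tie-broken", {
  # K5 (score 5) ranks above K4 (score 4)
  e <- rbind(cliqueEdges(paste0("z", 1:5)), cliqueEdges(paste0("a", 1:4)))
  units <- findComplexes(InteractionNetwork(edges = e))
  expect_equal(vapply(units, unitScore, 0), c(5, 4))
  expect_equal(vapply(units, unitId, 1L), 1:2)
  # identical runs give identical output
  units2 <- findComplexes(InteractionNetwork(edges = e))
  expect_identical(lapply(units, unitMembers), lapply(units2, unitMembers))
})

test_that("segmentation output is invariant under node relabeling", {
  set.seed(222)
  nodes <- sprintf("v%02d", 1:20)
  em <- rbind(as.matrix(cliqueEdges(nodes[1:6])),
              randomEdgeTable(nodes, 0.08))
  net <- InteractionNetwork(nodes = nodes,
                            edges = setNames(as.data.frame(em),
                                             c("from", "to")))
  perm <- setNames(sprintf("w%02d", sample(20)), nodes)
  net2 <- InteractionNetwork(nodes = unname(perm[nodes]),
                             edges = data.frame(from = perm[em[, 1]],
                                                to = perm[em[, 2]]))
  u1 <- lapply(findComplexes(net), function(u) sort(unname(perm[unitMembers(u)])))
  u2 <- lapply(findComplexes(net2), function(u) sort(unitMembers(u)))
  expect_setequal(vapply(u1, paste, "", collapse = ","),
                  vapply(u2, paste, "", collapse = ","))
})

test_that("unit serialisation formats are stable", {
  e <- cliqueEdges(paste0("k", 1:4))
  units <- findComplexes(InteractionNetwork(edges = e))
  tsv <- tempfile(); js <- tempfile()
  writeUnits(units, tsv)
  writeUnitsJSON(units, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$is_seed), 1L)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$size, 4L)
  expect_equal(obj$density, 1)
})
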