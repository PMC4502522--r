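# community with explicit COG annotation and a hand-built ortholog map
cogFixture <- function(catsA, catsB, pairs) {
  rows <- c(
    unlist(lapply(names(catsA), function(g)
      sprintf("A\t%s\tcog_category\t%s", g, catsA[[g]]))),
    unlist(lapply(names(catsB), function(g)
      sprintf("B\t%s\tcog_category\t%s", g, catsB[[g]]))))
  comm <- makeTestCommunity(rows)
  map <- new("OrthologMap", speciesA = "A", speciesB = "B",
             mode = "one-way",
             pairs = data.frame(gene_a = pairs$gene_a,
                                gene_b = pairs$gene_b,
                                score = rep(1, nrow(pairs)),
                                identity = rep(99, nrow(pairs)),
                                stringsAsFactors = FALSE))
  list(comm = comm, map = map)
}

test_that("category stats count in-category ortholog partners", {
  fx <- cogFixture(
    catsA = list(a1 = "C", a2 = "C", a3 = "C"),
    catsB = list(b1 = "C", b2 = "C", b3 = "C"),
    pairs = data.frame(gene_a = c("a1", "a2", "a3"),
                       gene_b = c("b1", "b2", "b3")))
  st <- categoryStats(fx$comm, fx$map)
  expect_equal(st$n_genes, c(3L, 3L))
  expect_equal(st$n_genes_ortholog, c(3L, 3L))
  expect_equal(st$n_pairs, c(3L, 3L))
})

test_that("category stats match an exhaustive pair-scan oracle", {
  set.seed(606)
  cats <- c("C", "E", "P", "H")
  for (rep in 1:8) {
    gA <- sprintf("a%02d", 1:10); gB <- sprintf("b%02d", 1:10)
    catsA <- lapply(setNames(nm = gA), function(g)
      sample(cats, sample(1:2, 1)))
    catsB <- lapply(setNames(nm = gB), function(g)
      sample(cats, sample(1:2, 1)))
    nb <- sample(5:10, 1)
    pairs <- data.frame(gene_a = sample(gA, nb, replace = TRUE),
                        gene_b = sample(gB, nb))
    fx <- cogFixture(catsA, catsB, pairs)
    st <- categoryStats(fx$comm, fx$map)
    for (r in seq_len(nrow(st))) {
      sp <- st$species_id[r]; cat <- st$category[r]
      mine <- if (sp == "A") catsA else catsB
      theirs <- if (sp == "A") catsB else catsA
      sCol <- if (sp == "A") "gene_a" else "gene_b"
      oCol <- if (sp == "A") "gene_b" else "gene_a"
      inCat <- names(mine)[vapply(mine, function(x) cat %in% x, TRUE)]
      hits <- vapply(seq_len(nb), function(k)
        pairs[[sCol]][k] %in% inCat &&
          cat %in% theirs[[pairs[[oCol]][k]]], TRUE)
      expect_equal(st$n_genes[r], length(inCat))
      expect_equal(st$n_pairs[r], sum(hits))
      expect_equal(st$n_genes_ortholog[r],
                   length(unique(pairs[[sCol]][hits])))
    }
    # subset restriction never exceeds unrestricted counts
    sub <- sample(c(gA, gB), 12)
    stSub <- categoryStats(fx$comm, fx$map, geneSubset = sub)
    for (r in seq_len(nrow(stSub))) {
      full <- st[st$species_id == stSub$species_id[r] &
                   st$category == stSub$category[r], ]
      expect_true(stSub$n_genes[r] <= full$n_genes)
      expect_true(stSub$n_pairs[r] <= full$n_pairs)
    }
  }
})

test_that("edge weight normalises to the species with fewer genes", {
  w <- categoryEdgeWeight(
    data.frame(category = "C", n_genes = 10L, n_genes_ortholog = 9L),
    data.frame(category = "C", n_genes = 5L, n_genes_ortholog = 5L))
  expect_equal(w, 100)
  w2 <- categoryEdgeWeight(
    data.frame(category = "C", n_genes = 4L, n_genes_ortholog = 2L),
    data.frame(category = "C", n_genes = 8L, n_genes_ortholog = 6L))
  expect_equal(w2, 50)
  expect_true(is.na(categoryEdgeWeight(
    data.frame(category = "C", n_genes = 0L, n_genes_ortholog = 0L),
    data.frame(category = "C", n_genes = 3L, n_genes_ortholog = 1L))))
})

test_that("edge weights stay within [0,100] and are symmetric on random fixtures", {
  set.seed(707)
  cats <- c("C", "E", "P")
  for (rep in 1:60) {
    gA <- sprintf("a%02d", 1:8); gB <- sprintf("b%02d", 1:8)
    catsA <- lapply(setNames(nm = gA), function(g)
      sample(cats, sample(1:2, 1)))
    catsB <- lapply(setNames(nm = gB), function(g)
      sample(cats, sample(1:2, 1)))
    nb <- sample(3:8, 1)
    pairs <- data.frame(gene_a = sample(gA, nb, replace = TRUE),
                        gene_b = sample(gB, nb))
    fx <- cogFixture(catsA, catsB, pairs)
    st <- categoryStats(fx$comm, fx$map)
    for (cat in unique(st$category)) {
      a <- st[st$species_id == "A" & st$category == cat, ]
      b <- st[st$species_id == "B" & st$category == cat, ]
      if (nrow(a) != 1 || nrow(b) != 1) next
      w <- categoryEdgeWeight(a, b)
      expect_true(is.na(w) || (w >= 0 && w <= 100))
      if (a$n_genes != b$n_genes)  # tie resolves to the first argument
        expect_equal(categoryEdgeWeight(b, a), w)
    }
  }
})

test_that("cross-category map links the focal category across species", {
  # orthologs confined to the focal category on both sides -> one edge
  fx <- cogFixture(
    catsA = list(a1 = "C", a2 = "C", a3 = "E"),
    catsB = list(b1 = "C", b2 = "C", b3 = "P"),
    pairs = data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2")))
  g <- crossCategoryMap(fx$comm, fx$map, "C", "A")
  expect_equal(nrow(cogEdges(g)), 1L)
  expect_equal(cogEdges(g)$label_b, "C")
  expect_equal(cogEdges(g)$weight, 100)
  # planted cross-category orthologs fan out to the expected categories
  fx2 <- cogFixture(
    catsA = list(a1 = "C", a2 = "C", a3 = "C"),
    catsB = list(b1 = "C", b2 = "E", b3 = "P"),
    pairs = data.frame(gene_a = c("a1", "a2", "a3"),
                       gene_b = c("b1", "b2", "b3")))
  g2 <- crossCategoryMap(fx2$comm, fx2$map, "C", "A")
  expect_setequal(cogEdges(g2)$label_b, c("C", "E", "P"))
  # no orthologs -> node-only graph; empty focal category -> error
  fx3 <- cogFixture(catsA = list(a1 = "C"), catsB = list(b1 = "E"),
                    pairs = data.frame(gene_a = character(0),
                                       gene_b = character(0)))
  g3 <- crossCategoryMap(fx3$comm, fx3$map, "C", "A")
  expect_equal(nrow(cogEdges(g3)), 0L)
  expect_equal(nrow(cogNodes(g3)), 1L)
  expect_error(crossCategoryMap(fx3$comm, fx3$map, "Z", "A"), "empty")
})

test_that("co-annotation weight equals the pairwise intersection oracle", {
  # single-labelled genes -> edgeless; shared labels counted exactly
  rows <- c("A\tg1\tcog_category\tC", "A\tg2\tcog_category\tE")
  g0 <- coannotationNetwork(makeTestCommunity(rows), "A")
  expect_equal(nrow(cogEdges(g0)), 0L)
  rows4 <- unlist(lapply(sprintf("g%d", 1:4), function(g)
    sprintf("A\t%s\tcog_category\t%s", g, c("C", "P"))))
  g4 <- coannotationNetwork(makeTestCommunity(rows4), "A")
  expect_equal(cogEdges(g4)$weight, 4)
  set.seed(808)
  cats <- LETTERS[1:5]
  for (rep in 1:10) {
    perGene <- lapply(setNames(nm = sprintf("g%02d", 1:12)), function(g)
      sample(cats, sample(1:3, 1)))
    rows <- unlist(lapply(names(perGene), function(g)
      sprintf("A\t%s\tcog_category\t%s", g, perGene[[g]])))
    gr <- coannotationNetwork(makeTestCommunity(rows), "A")
    e <- cogEdges(gr)
    for (i in seq_along(cats)) for (j in seq_along(cats)) {
      if (i >= j) next
      w <- sum(vapply(perGene, function(x)
        all(c(cats[i], cats[j]) %in% x), TRUE))
      row <- e[e$label_a == cats[i] & e$label_b == cats[j], ]
      expect_equal(if (nrow(row)) row$weight else 0, w)
    }
  }
})

test_that("gene-set files parse into named id lists", {
  f <- tempfile()
  writeLines(c("> thiosulfate", sprintf("g%d", 1:9),
               "> iron_oxidation", sprintf("h%d", 1:18)), f)
  sets <- readGeneSets(f)
  expect_equal(names(sets), c("thiosulfate", "iron_oxidation"))
  expect_equal(lengths(sets), c(thiosulfate = 9L, iron_oxidation = 18L))
})
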