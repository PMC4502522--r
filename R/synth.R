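#' @include AllClasses.R AllGenerics.R community.R network.R
NULL

AA20 <- setdiff(AA_ALPHABET20X, "X")

#' Configuration for the synthetic two-species community generator
#'
#' Defaults describe a small two-species consortium with a substantial
#' shared (orthologous) proteome and a species-A interaction network made
#' of dense planted modules over sparse background noise: 150 genes per
#' species, 60\% of species-B genes planted as orthologs diverged by 5\%
#' per-position substitution, protein lengths 80-120, multi-label COG
#' annotation, 8 planted modules of 6-10 genes wired to internal density
#' 0.9, and background edge probability 0.01.
#'
#' @param seed integer driving every draw; same seed, same bytes.
#' @param speciesA,speciesB species ids.
#' @param nGenesA,nGenesB genes per species.
#' @param orthologFraction fraction of B genes copied from distinct A
#'   genes.
#' @param substitutionRate per-position substitution probability applied
#'   to planted ortholog sequences.
#' @param seqLengthRange integer pair, protein length bounds.
#' @param categories named probability vector over one-letter COG codes
#'   (normalised internally).
#' @param multilabelProb probability of a second COG category.
#' @param categoryConservation probability that a planted ortholog copies
#'   its source gene's COG annotation instead of drawing fresh labels.
#' @param ecProb probability a gene carries an EC number.
#' @param nModules,moduleSizeRange,moduleDensity planted dense modules in
#'   the species-A network.
#' @param backgroundEdgeProb independent background edge probability over
#'   all species-A gene pairs.
#' @param nPathways,pathwaySizeRange per-species pathway memberships.
#' @return Validated named list.
#' @export
synthConfig <- function(seed = 1L, speciesA = "spA", speciesB = "spB",
                        nGenesA = 150L, nGenesB = 150L,
                        orthologFraction = 0.6, substitutionRate = 0.05,
                        seqLengthRange = c(80L, 120L),
                        categories = c(C = 0.14, E = 0.10, G = 0.08,
                                       H = 0.07, J = 0.10, K = 0.08,
                                       L = 0.07, M = 0.08, O = 0.06,
                                       P = 0.10, Q = 0.04, T = 0.08),
                        multilabelProb = 0.3,
                        categoryConservation = 0.9, ecProb = 0.35,
                        nModules = 8L, moduleSizeRange = c(6L, 10L),
                        moduleDensity = 0.9, backgroundEdgeProb = 0.01,
                        nPathways = 6L, pathwaySizeRange = c(4L, 8L)) {
  stopifnot(orthologFraction >= 0, orthologFraction <= 1,
            substitutionRate >= 0, substitutionRate <= 1,
            moduleDensity > 0, moduleDensity <= 1,
            backgroundEdgeProb >= 0, backgroundEdgeProb < 1,
            multilabelProb >= 0, multilabelProb <= 1,
            length(seqLengthRange) == 2L,
            seqLengthRange[1] <= seqLengthRange[2],
            !is.null(names(categories)), all(categories > 0))
  if (nModules * moduleSizeRange[2] > nGenesA)
    stop("infeasible config: planted modules exceed species-A gene count",
         call. = FALSE)
  list(seed = as.integer(seed), speciesA = speciesA, speciesB = speciesB,
       nGenesA = as.integer(nGenesA), nGenesB = as.integer(nGenesB),
       orthologFraction = orthologFraction,
       substitutionRate = substitutionRate,
       seqLengthRange = as.integer(seqLengthRange),
       categories = categories / sum(categories),
       multilabelProb = multilabelProb,
       categoryConservation = categoryConservation, ecProb = ecProb,
       nModules = as.integer(nModules),
       moduleSizeRange = as.integer(moduleSizeRange),
       moduleDensity = moduleDensity,
       backgroundEdgeProb = backgroundEdgeProb,
       nPathways = as.integer(nPathways),
       pathwaySizeRange = as.integer(pathwaySizeRange))
}

randomProtein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                     collapse = "")

mutateProtein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- runif(length(s)) < rate
  for (i in which(hit)) s[i] <- sample(setdiff(AA20, s[i]), 1L)
  paste(s, collapse = "")
}

drawCategories <- function(cfg) {
  cats <- sample(names(cfg$categories), 1L, prob = cfg$categories)
  if (runif(1) < cfg$multilabelProb) {
    rest <- setdiff(names(cfg$categories), cats)
    p <- cfg$categories[rest]
    cats <- c(cats, sample(rest, 1L, prob = p / sum(p)))
  }
  cats
}

#' Generate a synthetic two-species community with ground truth
#'
#' Emits the exact file dialects the ingest functions consume (per-species
#' FASTA, long-format annotation TSV, pathway TSV, scored edge-list TSV)
#' plus truth tables for planted ortholog pairs, planted modules and
#' per-item annotation counts. Species-A sequences are uniform random
#' proteins; a fraction of species-B genes are per-position-substituted
#' copies of distinct A genes (the planted orthologs), the rest fresh
#' random proteins. The species-A interaction network consists of disjoint
#' planted modules wired to at least the configured internal density
#' (internal pairs sampled uniformly without replacement) plus independent
#' background edges; background edges always involve at least one gene of
#' the unassigned background proteome, so the planted modules are the only
#' dense structure and module recovery stays well-posed. All output is byte-deterministic given the seed.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param dir optional output directory; when given, all files are
#'   written there.
#' @return List with elements \code{community}
#'   (\linkS4class{Community}), \code{network} (species-A
#'   \linkS4class{InteractionNetwork}), \code{pathwayTable}, \code{truth}
#'   (list: \code{orthologPairs}, \code{modules},
#'   \code{annotationCounts}) and \code{files} (named paths, when
#'   \code{dir} was given).
#' @export
generateCommunity <- function(config = synthConfig(), dir = NULL) {
  cfg <- config
  withSeed(cfg$seed, {
    idsA <- sprintf("%s_g%04d", cfg$speciesA, seq_len(cfg$nGenesA))
    idsB <- sprintf("%s_g%04d", cfg$speciesB, seq_len(cfg$nGenesB))
    lensA <- sample(seq(cfg$seqLengthRange[1], cfg$seqLengthRange[2]),
                    cfg$nGenesA, replace = TRUE)
    seqA <- vapply(lensA, randomProtein, "")

    nOrtho <- round(cfg$orthologFraction * cfg$nGenesB)
    sources <- sample(idsA, nOrtho)
    orthoIdx <- sort(sample(seq_len(cfg$nGenesB), nOrtho))
    seqB <- character(cfg$nGenesB)
    srcOf <- setNames(rep(NA_character_, cfg$nGenesB), idsB)
    for (k in seq_len(nOrtho)) {
      j <- orthoIdx[k]
      srcOf[j] <- sources[k]
      seqB[j] <- mutateProtein(seqA[match(sources[k], idsA)],
                               cfg$substitutionRate)
    }
    for (j in setdiff(seq_len(cfg$nGenesB), orthoIdx)) {
      len <- sample(seq(cfg$seqLengthRange[1], cfg$seqLengthRange[2]), 1L)
      seqB[j] <- randomProtein(len)
    }

    # COG labels; planted orthologs usually inherit their source's labels
    catsA <- lapply(seq_len(cfg$nGenesA), function(i) drawCategories(cfg))
    names(catsA) <- idsA
    catsB <- vector("list", cfg$nGenesB)
    names(catsB) <- idsB
    for (j in seq_len(cfg$nGenesB)) {
      catsB[[j]] <- if (!is.na(srcOf[j]) &&
                        runif(1) < cfg$categoryConservation)
        catsA[[srcOf[j]]] else drawCategories(cfg)
    }
    termOf <- function(cat) sprintf("COG%s%02d", cat, sample(4L, 1L))

    annRow <- function(sp, g, item, value)
      data.frame(species_id = sp, gene_id = g, item = item, value = value,
                 stringsAsFactors = FALSE)
    ann <- vector("list", 0L)
    buildAnn <- function(sp, ids, cats) {
      rows <- vector("list", length(ids))
      for (i in seq_along(ids)) {
        g <- ids[i]
        r <- rbind(
          annRow(sp, g, ITEM_PROTEIN_NAME, paste("protein", g)),
          annRow(sp, g, "patric_id", sprintf("fig|%s", g)),
          do.call(rbind, lapply(cats[[i]], function(cc) rbind(
            annRow(sp, g, ITEM_COG_CATEGORY, cc),
            annRow(sp, g, ITEM_COG_TERM, termOf(cc))))))
        if (runif(1) < cfg$ecProb)
          r <- rbind(r, annRow(sp, g, ITEM_EC,
                               paste(sample(6L, 1L), sample(20L, 1L),
                                     sample(20L, 1L), sample(99L, 1L),
                                     sep = ".")))
        rows[[i]] <- r
      }
      do.call(rbind, rows)
    }
    ann <- rbind(buildAnn(cfg$speciesA, idsA, catsA),
                 buildAnn(cfg$speciesB, idsB, catsB))

    # pathway memberships per species (+ pathway annotation rows)
    pw <- NULL
    for (sp in c(cfg$speciesA, cfg$speciesB)) {
      ids <- if (sp == cfg$speciesA) idsA else idsB
      for (p in seq_len(cfg$nPathways)) {
        sz <- sample(seq(cfg$pathwaySizeRange[1], cfg$pathwaySizeRange[2]),
                     1L)
        members <- sort(sample(ids, sz))
        pwid <- sprintf("pwy_%s_%02d", sp, p)
        pw <- rbind(pw, data.frame(species_id = sp, gene_id = members,
                                   pathway_id = pwid,
                                   stringsAsFactors = FALSE))
        ann <- rbind(ann, annRow(sp, members, ITEM_PATHWAY, pwid))
      }
    }

    # species-A network: disjoint planted modules + background
    sizes <- sample(seq(cfg$moduleSizeRange[1], cfg$moduleSizeRange[2]),
                    cfg$nModules, replace = TRUE)
    if (sum(sizes) > cfg$nGenesA)
      stop("infeasible config: planted modules exceed gene count",
           call. = FALSE)
    pool <- sample(idsA)
    modules <- vector("list", cfg$nModules)
    off <- 0L
    edges <- NULL
    for (m in seq_len(cfg$nModules)) {
      modules[[m]] <- sort(pool[(off + 1L):(off + sizes[m])])
      off <- off + sizes[m]
      prs <- combn(modules[[m]], 2L)
      need <- ceiling(cfg$moduleDensity * ncol(prs))
      pick <- sort(sample.int(ncol(prs), need))
      edges <- rbind(edges, data.frame(from = prs[1, pick],
                                       to = prs[2, pick],
                                       stringsAsFactors = FALSE))
    }
    if (cfg$backgroundEdgeProb > 0) {
      # background = the unassigned (non-module) proteome: noise edges
      # always involve at least one background gene, so the planted
      # modules and their separation remain the only dense truth
      allPairs <- combn(sort(idsA), 2L)
      inModule <- unlist(modules)
      bg <- !(allPairs[1, ] %in% inModule & allPairs[2, ] %in% inModule)
      allPairs <- allPairs[, bg, drop = FALSE]
      hit <- which(runif(ncol(allPairs)) < cfg$backgroundEdgeProb)
      if (length(hit))
        edges <- rbind(edges, data.frame(from = allPairs[1, hit],
                                         to = allPairs[2, hit],
                                         stringsAsFactors = FALSE))
    }
    edges$sources <- "string-like"
    edges$score <- sample(150:999, nrow(edges), replace = TRUE) / 1000

    seqs <- Biostrings::AAStringSet(setNames(c(seqA, seqB),
                                             c(idsA, idsB)))
    comm <- Community(
      genes = data.frame(species_id = rep(c(cfg$speciesA, cfg$speciesB),
                                          c(cfg$nGenesA, cfg$nGenesB)),
                         gene_id = c(idsA, idsB),
                         stringsAsFactors = FALSE),
      sequences = seqs, annotation = ann)
    net <- InteractionNetwork(nodes = idsA, edges = edges,
                              scope = cfg$speciesA, warnLoops = FALSE)

    annCounts <- do.call(rbind, lapply(
      split(comm@annotation, paste(comm@annotation$species_id,
                                   comm@annotation$item, sep = "\r")),
      function(d) data.frame(species_id = d$species_id[1],
                             item = d$item[1],
                             n_genes = length(unique(d$gene_id)),
                             stringsAsFactors = FALSE)))
    rownames(annCounts) <- NULL

    truth <- list(
      orthologPairs = data.frame(gene_a = unname(srcOf[orthoIdx]),
                                 gene_b = idsB[orthoIdx],
                                 stringsAsFactors = FALSE),
      modules = modules,
      annotationCounts = annCounts)

    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- writeCommunity(comm, dir)
      pwPath <- file.path(dir, "pathways.tsv")
      writeLines(c("species_id\tgene_id\tpathway_id",
                   paste(pw$species_id, pw$gene_id, pw$pathway_id,
                         sep = "\t")), pwPath)
      edgePath <- file.path(dir, "edges.tsv")
      writeEdgeList(net, edgePath)
      toPath <- file.path(dir, "truth_orthologs.tsv")
      writeLines(c("gene_a\tgene_b",
                   paste(truth$orthologPairs$gene_a,
                         truth$orthologPairs$gene_b, sep = "\t")), toPath)
      tmPath <- file.path(dir, "truth_modules.json")
      jsonlite::write_json(truth$modules, tmPath, pretty = TRUE)
      tcPath <- file.path(dir, "truth_annotation_counts.tsv")
      write.table(annCounts, tcPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      cfgPath <- file.path(dir, "config.json")
      jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, pretty = TRUE,
                           digits = 10)
      files <- c(files, list(pathways = pwPath, edges = edgePath,
                             truthOrthologs = toPath, truthModules = tmPath,
                             truthAnnotationCounts = tcPath,
                             config = cfgPath))
    }
    ouLog("simulate: %d+%d genes, %d planted orthologs, %d modules, %d edges",
          cfg$nGenesA, cfg$nGenesB, nOrtho, cfg$nModules, nrow(net@edges))
    list(community = comm, network = net, pathwayTable = pw,
         truth = truth, files = files, config = cfg)
  })
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Score pipeline outputs against generator ground truth
#'
#' Ortholog recall and precision of a mapping against the planted pairs,
#' and the best Jaccard similarity of each planted module against the
#' detected units. Metrics are label-invariant and deterministic.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{generateCommunity}} output.
#' @param map optional \linkS4class{OrthologMap}.
#' @param units optional list of \linkS4class{FunctionalUnit}.
#' @return List with \code{orthologRecall}, \code{orthologPrecision}
#'   (NA when no map given) and \code{moduleBestJaccard} (numeric per
#'   planted module; NULL when no units given).
#' @export
evaluateRecovery <- function(truth, map = NULL, units = NULL) {
  out <- list(orthologRecall = NA_real_, orthologPrecision = NA_real_,
              moduleBestJaccard = NULL)
  if (!is.null(map)) {
    planted <- paste(truth$orthologPairs$gene_a,
                     truth$orthologPairs$gene_b, sep = "\r")
    pred <- paste(map@pairs$gene_a, map@pairs$gene_b, sep = "\r")
    out$orthologRecall <- if (length(planted))
      sum(planted %in% pred) / length(planted) else NA_real_
    out$orthologPrecision <- if (length(pred))
      sum(pred %in% planted) / length(pred) else NA_real_
  }
  if (!is.null(units)) {
    memb <- lapply(units, unitMembers)
    out$moduleBestJaccard <- vapply(truth$modules, function(mod) {
      if (!length(memb)) return(0)
      max(vapply(memb, jaccard, 0, a = mod))
    }, 0)
  }
  out
}
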