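#' @include AllClasses.R community.R align.R network.R cog.R mcode.R
#'   processModel.R synth.R
NULL

# --key value argument parser; later occurrences win, flags win over
# entries of an optional key=value --config file.
parseArgs <- function(args) {
  flags <- list()
  sub <- NULL
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        flags[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      if (is.null(sub)) sub <- a
      else stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
      i <- i + 1L
    }
  }
  if (!is.null(flags$config)) {
    kv <- readLines(flags$config)
    kv <- kv[nzchar(kv) & !startsWith(trimws(kv), "#")]
    for (line in kv) {
      p <- strsplit(line, "=", fixed = TRUE)[[1]]
      key <- trimws(p[1])
      if (is.null(flags[[key]]))
        flags[[key]] <- trimws(paste(p[-1], collapse = "="))
    }
  }
  list(sub = sub, flags = flags)
}

flagNum <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) default else as.numeric(v)
}
flagChr <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) default else as.character(v)
}
needFile <- function(path, what) {
  if (is.null(path)) stop(sprintf("missing required flag for %s", what),
                          call. = FALSE)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path),
                               call. = FALSE)
  path
}

readFixtureCommunity <- function(dir, flags) {
  ann <- needFile(flagChr(flags, "annotation",
                          file.path(dir, "annotation.tsv")), "annotation")
  fastas <- Sys.glob(file.path(dir, "*.fasta"))
  names(fastas) <- sub("\\.fasta$", "", basename(fastas))
  readCommunity(ann, fastas)
}

stageSimulate <- function(flags) {
  outDir <- flagChr(flags, "out-dir")
  if (is.null(outDir)) stop("missing --out-dir", call. = FALSE)
  cfg <- synthConfig(
    seed = flagNum(flags, "seed", 1),
    nGenesA = flagNum(flags, "n-genes-a", 150),
    nGenesB = flagNum(flags, "n-genes-b", 150),
    orthologFraction = flagNum(flags, "ortholog-fraction", 0.6),
    substitutionRate = flagNum(flags, "substitution-rate", 0.05),
    nModules = flagNum(flags, "n-modules", 8),
    moduleDensity = flagNum(flags, "module-density", 0.9),
    backgroundEdgeProb = flagNum(flags, "background-edge-prob", 0.01))
  generateCommunity(cfg, outDir)
  0L
}

stageIngest <- function(flags) {
  outDir <- flagChr(flags, "out-dir")
  if (is.null(outDir)) stop("missing --out-dir", call. = FALSE)
  fastas <- c()
  if (!is.null(flags[["fasta-a"]]))
    fastas[flagChr(flags, "species-a", "spA")] <-
      needFile(flags[["fasta-a"]], "species-A FASTA")
  if (!is.null(flags[["fasta-b"]]))
    fastas[flagChr(flags, "species-b", "spB")] <-
      needFile(flags[["fasta-b"]], "species-B FASTA")
  comm <- readCommunity(needFile(flags$annotation, "annotation"), fastas)
  writeCommunity(comm, outDir)
  0L
}

stageCoverage <- function(flags) {
  dir <- flagChr(flags, "in-dir", ".")
  comm <- readFixtureCommunity(dir, flags)
  nets <- list()
  if (!is.null(flags$edges))
    nets$interactions <- readEdgeList(needFile(flags$edges, "edge list"),
                                      comm)
  cov <- coverageTable(comm, nets)
  writeCoverageTable(cov, flagChr(flags, "out", "coverage.tsv"))
  0L
}

stageOrthologs <- function(flags) {
  dir <- flagChr(flags, "in-dir", ".")
  comm <- readFixtureCommunity(dir, flags)
  sp <- speciesIds(comm)
  spA <- flagChr(flags, "species-a", sp[1])
  spB <- flagChr(flags, "species-b", sp[2])
  map <- mapOrthologs(comm, spA, spB,
                      mode = flagChr(flags, "mode", "one-way"),
                      minIdentity = flagNum(flags, "min-identity", NULL))
  writeOrthologMap(map, flagChr(flags, "out", "orthologs.tsv"))
  0L
}

stageImpute <- function(flags) {
  map <- readOrthologMap(needFile(flags$orthologs, "ortholog map"),
                         speciesA = flagChr(flags, "species-a", "spA"),
                         speciesB = flagChr(flags, "species-b", "spB"))
  net <- readEdgeList(needFile(flags$edges, "edge list"))
  out <- imputeInteractions(net, map)
  writeEdgeList(out, flagChr(flags, "out", "imputed_edges.tsv"))
  0L
}

stageCognet <- function(flags) {
  dir <- flagChr(flags, "in-dir", ".")
  comm <- readFixtureCommunity(dir, flags)
  sp <- speciesIds(comm)
  spA <- flagChr(flags, "species-a", sp[1])
  spB <- flagChr(flags, "species-b", sp[2])
  map <- readOrthologMap(needFile(flags$orthologs, "ortholog map"),
                         speciesA = spA, speciesB = spB)
  subset <- if (!is.null(flags[["gene-set"]]))
    unlist(readGeneSets(needFile(flags[["gene-set"]], "gene set")),
           use.names = FALSE) else NULL
  focal <- flagChr(flags, "focal-category")
  g <- if (is.null(focal))
    cogCategoryGraph(comm, map, geneSubset = subset)
  else
    crossCategoryMap(comm, map, focal,
                     flagChr(flags, "focal-species", spA),
                     geneSubset = subset)
  writeGraphML(g, flagChr(flags, "out", "cognet.graphml"))
  0L
}

stageSegment <- function(flags) {
  net <- readEdgeList(needFile(flags$edges, "edge list"),
                      minScore = flagNum(flags, "min-score", NULL))
  params <- mcodeParams(
    nodeScoreCutoff = flagNum(flags, "node-score-cutoff", 0.2),
    degreeCutoff = flagNum(flags, "degree-cutoff", 2),
    fluff = isTRUE(flags$fluff),
    haircut = !isTRUE(flags[["no-haircut"]]))
  units <- findComplexes(net, params)
  prefix <- flagChr(flags, "out-prefix", "units")
  writeUnits(units, paste0(prefix, ".tsv"))
  writeUnitsJSON(units, paste0(prefix, ".json"))
  0L
}

stageModel <- function(flags) {
  dir <- flagChr(flags, "in-dir")
  if (is.null(dir)) stop("missing --in-dir", call. = FALSE)
  outDir <- flagChr(flags, "out-dir", dir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  comm <- readFixtureCommunity(dir, flags)
  sp <- speciesIds(comm)
  spA <- flagChr(flags, "species-a", sp[1])
  spB <- flagChr(flags, "species-b", sp[2])
  netA <- readEdgeList(needFile(flagChr(flags, "edges",
                                        file.path(dir, "edges.tsv")),
                                "edge list"), comm,
                       minScore = flagNum(flags, "min-score", NULL))
  map <- mapOrthologs(comm, spA, spB,
                      mode = flagChr(flags, "mode", "one-way"),
                      minIdentity = flagNum(flags, "min-identity", NULL))
  writeOrthologMap(map, file.path(outDir, "orthologs.tsv"))
  netB <- imputeInteractions(netA, map)
  writeEdgeList(netB, file.path(outDir, "imputed_edges.tsv"))
  orthoA <- sort(unique(map@pairs$gene_a))
  orthoNet <- suppressWarnings(inducedSubgraph(netA, orthoA))
  if (length(orthoNet@nodes))
    ouLog("model: ortholog graph %d nodes, index of aggregation %.4f",
          length(orthoNet@nodes), indexOfAggregation(orthoNet))
  units <- findComplexes(orthoNet, mcodeParams(
    nodeScoreCutoff = flagNum(flags, "node-score-cutoff", 0.2),
    fluff = isTRUE(flags$fluff)))
  writeUnits(units, file.path(outDir, "units.tsv"))
  specific <- setdiff(geneIds(comm, spA), orthoA)
  model <- buildProcessModel(units, orthoNet, community = comm,
                             specificGenes = specific, netSpecific = netA,
                             minEdgeThreshold =
                               flagNum(flags, "min-edge-threshold", 1))
  writeProcessModel(model, file.path(outDir, "model.json"))
  writeGraphML(model, file.path(outDir, "model.graphml"))
  0L
}

#' Run a pipeline stage from command-line style arguments
#'
#' Subcommands mirror the analysis order: \code{simulate} (synthetic
#' fixture), \code{ingest}, \code{coverage}, \code{orthologs},
#' \code{impute}, \code{cognet}, \code{segment} and \code{model} (the
#' full chain from raw inputs to the serialized process model). Flags are
#' \code{--key value} pairs; an optional \code{--config} file with
#' \code{key = value} lines supplies defaults that explicit flags
#' override. Structured progress lines go to standard error; re-running a
#' stage on unchanged inputs rewrites identical bytes.
#'
#' @param args character vector, e.g. \code{commandArgs(trailingOnly =
#'   TRUE)}.
#' @return Integer exit status (0 on success), invisibly. On failure a
#'   one-line reason is printed to standard error and 1 is returned.
#' @examples
#' dir <- tempfile()
#' runPipeline(c("simulate", "--seed", "7", "--out-dir", dir,
#'               "--n-genes-a", "30", "--n-genes-b", "30",
#'               "--n-modules", "2"))
#' @export
runPipeline <- function(args) {
  status <- tryCatch({
    pa <- parseArgs(args)
    if (isTRUE(pa$flags$quiet)) {
      old <- options(OrthoUnits.quiet = TRUE)
      on.exit(options(old), add = TRUE)
    }
    stages <- list(simulate = stageSimulate, ingest = stageIngest,
                   coverage = stageCoverage, orthologs = stageOrthologs,
                   impute = stageImpute, cognet = stageCognet,
                   segment = stageSegment, model = stageModel)
    if (is.null(pa$sub) || !pa$sub %in% names(stages))
      stop(sprintf("unknown or missing subcommand; expected one of: %s",
                   paste(names(stages), collapse = ", ")), call. = FALSE)
    t0 <- Sys.time()
    st <- stages[[pa$sub]](pa$flags)
    ouLog("%s: done in %.1fs", pa$sub,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
    st
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    1L
  })
  invisible(status)
}
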