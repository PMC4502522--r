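#' @include AllClasses.R AllGenerics.R utils.R
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
NULL

#' Construct a Community
#'
#' Low-level constructor; most users will call \code{\link{readCommunity}}
#' or the synthetic generator instead. Tables are canonicalised (sorted,
#' de-duplicated) so that two communities with the same content compare
#' identical.
#'
#' @param genes data.frame with columns \code{species_id}, \code{gene_id}.
#' @param sequences named \linkS4class{AAStringSet} (names = gene ids).
#' @param annotation data.frame(species_id, gene_id, item, value).
#' @param itemCatalog named list species -> item names; defaults to the
#'   items observed per species.
#' @return A \linkS4class{Community}.
#' @export
Community <- function(genes,
                      sequences = Biostrings::AAStringSet(),
                      annotation = NULL,
                      itemCatalog = NULL) {
  genes <- data.frame(species_id = as.character(genes$species_id),
                      gene_id = as.character(genes$gene_id),
                      stringsAsFactors = FALSE)
  genes <- unique(genes)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop(sprintf("gene_id '%s' occurs in more than one species", dup[1]),
         call. = FALSE)
  genes <- genes[order(genes$species_id, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(annotation) || !nrow(annotation)) {
    annotation <- data.frame(species_id = character(0), gene_id = character(0),
                             item = character(0), value = character(0),
                             stringsAsFactors = FALSE)
  } else {
    annotation <- data.frame(species_id = as.character(annotation$species_id),
                             gene_id = as.character(annotation$gene_id),
                             item = as.character(annotation$item),
                             value = as.character(annotation$value),
                             stringsAsFactors = FALSE)
    annotation <- unique(annotation)
    annotation <- annotation[order(annotation$species_id, annotation$gene_id,
                                   annotation$item, annotation$value), ,
                             drop = FALSE]
    rownames(annotation) <- NULL
  }
  if (is.null(itemCatalog)) {
    itemCatalog <- lapply(
      setNames(nm = sort(unique(genes$species_id))),
      function(sp) sort(unique(annotation$item[annotation$species_id == sp])))
  }
  if (length(sequences)) {
    sequences <- sequences[order(names(sequences))]
    checkAminoAcid(as.character(sequences))
  }
  new("Community", genes = genes, sequences = sequences,
      annotation = annotation, itemCatalog = itemCatalog)
}

#' Load a community from an annotation table and FASTA files
#'
#' Ingests the single long-format annotation dialect used throughout the
#' package: a tab-separated file with header and columns
#' \code{species_id}, \code{gene_id}, \code{item}, \code{value}. Every
#' annotation source (database identifiers, COG categories and terms,
#' pathways, EC numbers, protein names, ...) is a value of the \code{item}
#' column; repeated (gene, item) rows accumulate into value sets. Protein
#' sequences come from per-species FASTA files whose record ids are gene
#' ids. Genes present only in a FASTA get an empty annotation; genes
#' present only in the table get no sequence.
#'
#' @param annotationFile path to the annotation TSV (header required).
#' @param fastaFiles named character vector, species id -> FASTA path.
#' @return A \linkS4class{Community}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("species_id\tgene_id\titem\tvalue",
#'              "sp1\tg1\tcog_category\tC",
#'              "sp1\tg1\tcog_category\tP"), tsv)
#' comm <- readCommunity(tsv)
#' cogCategories(comm)[["g1"]]
#' @export
readCommunity <- function(annotationFile, fastaFiles = character(0)) {
  lines <- readLines(annotationFile)
  if (length(lines) == 0L)
    stop("annotation file is empty (header row required)", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # count tab-separated columns without losing a trailing empty value
  nf <- lengths(strsplit(paste0(lines, "\tEND"), "\t", fixed = TRUE)) - 1L
  body <- which(seq_along(lines) > 1L & nzchar(lines))
  badrows <- body[nf[body] != 4L]
  if (length(badrows))
    stop(sprintf("malformed annotation row at line %d: expected 4 columns, got %d",
                 badrows[1], nf[badrows[1]]), call. = FALSE)
  header <- fields[[1]]
  if (!identical(header[1:2], c("species_id", "gene_id")))
    stop("annotation header must be: species_id gene_id item value",
         call. = FALSE)
  ann <- if (length(body)) {
    data.frame(
      species_id = vapply(fields[body], `[`, "", 1L),
      gene_id = vapply(fields[body], `[`, "", 2L),
      item = vapply(fields[body], `[`, "", 3L),
      value = vapply(fields[body], function(f)
        if (length(f) >= 4L) f[4L] else "", ""),
      stringsAsFactors = FALSE)
  } else NULL

  seqs <- Biostrings::AAStringSet()
  seqGenes <- NULL
  for (sp in names(fastaFiles)) {
    s <- Biostrings::readAAStringSet(fastaFiles[[sp]])
    names(s) <- sub("\\s.*$", "", names(s))
    seqGenes <- rbind(seqGenes, data.frame(species_id = sp,
                                           gene_id = names(s),
                                           stringsAsFactors = FALSE))
    seqs <- c(seqs, s)
  }
  genes <- unique(rbind(
    if (!is.null(ann)) ann[, c("species_id", "gene_id")] else NULL,
    seqGenes))
  if (is.null(genes) || !nrow(genes))
    stop("no genes found in annotation or FASTA input", call. = FALSE)
  comm <- Community(genes = genes, sequences = seqs, annotation = ann)
  ouLog("ingest: %d genes, %d species, %d annotation rows, %d sequences",
        nrow(comm@genes), length(unique(comm@genes$species_id)),
        nrow(comm@annotation), length(seqs))
  comm
}

#' Serialise a community back to its TSV + FASTA dialect
#'
#' Writes \code{annotation.tsv} plus one \code{<species>.fasta} per species
#' with sequences. \code{readCommunity} on the written files reproduces the
#' community exactly (load/serialise round trip).
#'
#' @param community a \linkS4class{Community}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
writeCommunity <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  annPath <- file.path(dir, "annotation.tsv")
  ann <- community@annotation
  hdr <- "species_id\tgene_id\titem\tvalue"
  writeLines(c(hdr, if (nrow(ann))
    paste(ann$species_id, ann$gene_id, ann$item, ann$value, sep = "\t")),
    annPath)
  paths <- list(annotation = annPath, fasta = character(0))
  for (sp in speciesIds(community)) {
    ids <- intersect(geneIds(community, sp), names(community@sequences))
    if (!length(ids)) next
    p <- file.path(dir, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(community@sequences[ids], p, width = 70L)
    paths$fasta[sp] <- p
  }
  invisible(paths)
}

## ---- accessors -----------------------------------------------------------

#' @describeIn Community species ids present in the community.
#' @param x a \linkS4class{Community}.
#' @export
setMethod("speciesIds", "Community", function(x)
  sort(unique(x@genes$species_id)))

#' @describeIn Community gene ids, optionally restricted to one species.
#' @param species optional species id filter.
#' @export
setMethod("geneIds", "Community", function(x, species = NULL) {
  if (is.null(species)) x@genes$gene_id
  else x@genes$gene_id[x@genes$species_id == species]
})

#' @describeIn Community number of (protein-coding) genes.
#' @export
setMethod("nGenes", "Community", function(x, species = NULL)
  length(geneIds(x, species)))

#' @describeIn Community named \code{AAStringSet} of protein sequences.
#' @export
setMethod("sequences", "Community", function(x) x@sequences)

#' @describeIn Community the long-format annotation table.
#' @export
setMethod("annotationTable", "Community", function(x) x@annotation)

#' @describeIn Community declared annotation items (per species, or the
#'   union across species).
#' @export
setMethod("itemCatalog", "Community", function(x, species = NULL) {
  if (is.null(species)) x@itemCatalog
  else x@itemCatalog[[species]]
})

#' @describeIn Community values of one annotation item as a named list
#'   gene id -> sorted character vector (genes without the item omitted).
#' @param item annotation item name.
#' @export
setMethod("annotationValues", "Community",
  function(x, item, species = NULL) {
    a <- x@annotation
    keep <- a$item == item & nzchar(a$value) & a$value != "NA"
    if (!is.null(species)) keep <- keep & a$species_id == species
    a <- a[keep, , drop = FALSE]
    if (!nrow(a)) return(setNames(list(), character(0)))
    lapply(split(a$value, a$gene_id), function(v) sort(unique(v)))
  })

setMethod("show", "Community", function(object) {
  sp <- speciesIds(object)
  cat(sprintf("Community with %d genes across %d species (%s)\n",
              nrow(object@genes), length(sp), paste(sp, collapse = ", ")))
  cat(sprintf("  sequences: %d; annotation rows: %d; items: %d\n",
              length(object@sequences), nrow(object@annotation),
              length(unique(object@annotation$item))))
})

#' COG category codes per gene
#' @param community a \linkS4class{Community}.
#' @param species optional species filter.
#' @return Named list gene id -> character vector of one-letter COG codes.
#' @export
cogCategories <- function(community, species = NULL)
  annotationValues(community, ITEM_COG_CATEGORY, species)

#' COG entry identifiers per gene
#' @inheritParams cogCategories
#' @export
cogTerms <- function(community, species = NULL)
  annotationValues(community, ITEM_COG_TERM, species)

#' Pathway identifiers per gene
#' @inheritParams cogCategories
#' @export
pathwayMembership <- function(community, species = NULL)
  annotationValues(community, ITEM_PATHWAY, species)

#' EC numbers per gene
#' @inheritParams cogCategories
#' @export
ecNumbers <- function(community, species = NULL)
  annotationValues(community, ITEM_EC, species)

#' Protein names per gene (first value where several are annotated)
#' @inheritParams cogCategories
#' @export
proteinNames <- function(community, species = NULL) {
  v <- annotationValues(community, ITEM_PROTEIN_NAME, species)
  vapply(v, `[`, "", 1L)
}

## ---- coverage ------------------------------------------------------------

#' Annotation (and interaction) coverage table
#'
#' For every species and annotation item, the percentage of the species'
#' protein-coding genes holding at least one valid entry for the item,
#' where valid means a non-empty value different from \code{"NA"}.
#' Percentages are rounded half-up to two decimals, the convention of
#' published coverage tables (a gene set fully covered prints 100.00).
#' Interaction sources are folded in by passing named
#' \linkS4class{InteractionNetwork}s: their coverage is the percentage of
#' genes with at least one interaction (degree >= 1), via
#' \code{\link{interactionCoverage}}.
#'
#' @param community a \linkS4class{Community}.
#' @param networks optional named list of \linkS4class{InteractionNetwork}s;
#'   names are used as item labels in the output.
#' @return data.frame(section, species_id, item, coverage) with section
#'   \code{"annotation"} or \code{"interaction"}.
#' @export
coverageTable <- function(community, networks = list()) {
  sp <- speciesIds(community)
  if (!length(sp)) stop("community has no species", call. = FALSE)
  out <- NULL
  for (s in sp) {
    n <- nGenes(community, s)
    if (n == 0L) stop(sprintf("species '%s' has zero genes", s),
                      call. = FALSE)
    for (it in itemCatalog(community, s)) {
      vals <- annotationValues(community, it, s)
      cov <- roundHalfUp(100 * length(vals) / n, 2)
      out <- rbind(out, data.frame(section = "annotation", species_id = s,
                                   item = it, coverage = cov,
                                   stringsAsFactors = FALSE))
    }
    for (nm in names(networks)) {
      cov <- interactionCoverage(networks[[nm]], community, s)
      out <- rbind(out, data.frame(section = "interaction", species_id = s,
                                   item = nm, coverage = cov,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a coverage table as TSV
#' @param coverage result of \code{\link{coverageTable}}.
#' @param file output path.
#' @export
writeCoverageTable <- function(coverage, file) {
  cov <- coverage
  cov$coverage <- sprintf("%.2f", cov$coverage)
  write.table(cov, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## ---- literature queries --------------------------------------------------

#' Default keyword catalog for literature screening
#'
#' Cooperative aspects (synergism, consortium, community, cooperation) and
#' specific utilisation in bioleaching contexts (bioleaching, biomining,
#' chalcopyrite): seven keywords in two groups.
#' @return Named list of character vectors.
#' @export
defaultKeywordCatalog <- function() {
  list(cooperation = c("synergism", "consortium", "community", "cooperation"),
       utilization = c("bioleaching", "biomining", "chalcopyrite"))
}

#' Build literature query strings
#'
#' One query per (gene, keyword) pair, formatted
#' \code{"<protein name>" AND <keyword>}, in deterministic order: genes by
#' gene id, keywords in catalog order. Genes without a protein name are
#' skipped with a warning. Query execution against any service is out of
#' scope; this only constructs the strings.
#'
#' @param community a \linkS4class{Community}.
#' @param species optional species filter.
#' @param catalog named list of keyword groups, flattened in order.
#' @return data.frame(gene_id, keyword, query).
#' @export
buildLiteratureQueries <- function(community, species = NULL,
                                   catalog = defaultKeywordCatalog()) {
  kw <- unlist(catalog, use.names = FALSE)
  ids <- sort(geneIds(community, species))
  nm <- proteinNames(community, species)
  out <- NULL
  for (g in ids) {
    pn <- if (g %in% names(nm)) nm[[g]] else ""
    if (!nzchar(pn)) {
      warning(sprintf("gene '%s' has no protein name; skipped", g),
              call. = FALSE)
      next
    }
    out <- rbind(out, data.frame(
      gene_id = g, keyword = kw,
      query = sprintf("\"%s\" AND %s", pn, kw),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(0), keyword = character(0),
                      query = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
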