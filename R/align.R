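#' @include AllClasses.R AllGenerics.R utils.R
#' @importFrom Biostrings pairwiseAlignment AAString AAStringSet nmatch
NULL

# BLOSUM62 etc. ship as data sets; load lazily into the package namespace.
substitutionMatrixByName <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop(sprintf("unknown substitution matrix '%s'", name), call. = FALSE)
  get(name, envir = e)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix files distributed with BLAST
#' (comment lines start with \code{#}, first row and column are residue
#' letters).
#'
#' @param file path to the matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(file) {
  lines <- grep("^\\s*#", readLines(file), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  m <- matrix(NA_real_, length(lines) - 1L, length(cols))
  rn <- character(length(lines) - 1L)
  for (i in seq_along(rn)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    rn[i] <- f[1]
    m[i, ] <- as.numeric(f[-1])
  }
  dimnames(m) <- list(rn, cols)
  m
}

resolveMatrix <- function(substitutionMatrix) {
  if (is.character(substitutionMatrix) && length(substitutionMatrix) == 1L) {
    if (file.exists(substitutionMatrix))
      readSubstitutionMatrix(substitutionMatrix)
    else substitutionMatrixByName(substitutionMatrix)
  } else as.matrix(substitutionMatrix)
}

#' Global (Needleman-Wunsch) alignment of two protein sequences
#'
#' Optimal global alignment under an affine gap model in which a gap of
#' length L costs \code{gapOpen + L * gapExtend}. Defaults follow the
#' EMBOSS Needle protein defaults: BLOSUM62, gap open 10, gap extend 0.5.
#' Percent identity is the number of identical aligned positions divided
#' by the alignment length (gaps included).
#'
#' @param seqA,seqB non-empty amino-acid strings (20 standard letters
#'   plus X).
#' @param substitutionMatrix matrix, matrix name (e.g. \code{"BLOSUM62"})
#'   or path to an NCBI-format matrix file.
#' @param gapOpen,gapExtend affine gap parameters (positive costs).
#' @return list(score, identity, alignedLength).
#' @examples
#' globalAlign("ACDE", "ACDE")$score  # 24 under BLOSUM62
#' @export
globalAlign <- function(seqA, seqB, substitutionMatrix = "BLOSUM62",
                        gapOpen = 10, gapExtend = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("empty sequence in global alignment", call. = FALSE)
  checkAminoAcid(c(a = seqA, b = seqB))
  mat <- resolveMatrix(substitutionMatrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = mat, gapOpening = gapOpen,
    gapExtension = gapExtend, type = "global")
  al <- Biostrings::nchar(pa)
  list(score = Biostrings::score(pa),
       identity = 100 * Biostrings::nmatch(pa) / al,
       alignedLength = al)
}

#' Map orthologs between two species by top-scoring global alignment
#'
#' Aligns every species-B protein against every species-A protein
#' (all-vs-all, no pre-filtering) and assigns orthologs by top score. In
#' \code{"one-way"} mode (default) each B gene is paired with its
#' top-scoring A gene, so several B genes may share one A partner
#' (multiple assignment); in \code{"rbh"} mode a pair is kept only if each
#' gene is the other's top hit. Score ties break by higher percent
#' identity, then by lexicographically smaller partner gene id, making
#' the mapping deterministic and invariant to input order. Pairs below
#' \code{minIdentity} are dropped.
#'
#' @param community a \linkS4class{Community} with sequences for both
#'   species.
#' @param speciesA,speciesB species ids (imputation direction is A to B).
#' @param mode \code{"one-way"} or \code{"rbh"}.
#' @param minIdentity optional percent-identity cutoff applied to the
#'   selected pairs (default none).
#' @param substitutionMatrix,gapOpen,gapExtend see
#'   \code{\link{globalAlign}}.
#' @return An \linkS4class{OrthologMap}.
#' @export
mapOrthologs <- function(community, speciesA, speciesB,
                         mode = c("one-way", "rbh"), minIdentity = NULL,
                         substitutionMatrix = "BLOSUM62", gapOpen = 10,
                         gapExtend = 0.5) {
  mode <- match.arg(mode)
  mat <- resolveMatrix(substitutionMatrix)
  seqs <- sequences(community)
  idsA <- sort(intersect(geneIds(community, speciesA), names(seqs)))
  idsB <- sort(intersect(geneIds(community, speciesB), names(seqs)))
  if (!length(idsA))
    stop(sprintf("species '%s' has no sequences", speciesA), call. = FALSE)
  if (!length(idsB))
    stop(sprintf("species '%s' has no sequences", speciesB), call. = FALSE)
  setA <- seqs[idsA]

  scoreMat <- matrix(NA_real_, nrow = length(idsB), ncol = length(idsA),
                     dimnames = list(idsB, idsA))
  for (j in seq_along(idsB)) {
    pa <- Biostrings::pairwiseAlignment(
      setA, seqs[[idsB[j]]], substitutionMatrix = mat,
      gapOpening = gapOpen, gapExtension = gapExtend, type = "global",
      scoreOnly = TRUE)
    scoreMat[j, ] <- pa
  }

  # top-scoring A partner per B gene, ties by identity then gene id
  pickTop <- function(scoresRow, bSeq) {
    best <- max(scoresRow)
    cand <- which(scoresRow == best)
    if (length(cand) > 1L) {
      pids <- vapply(cand, function(k) {
        pa <- Biostrings::pairwiseAlignment(
          setA[[k]], bSeq, substitutionMatrix = mat, gapOpening = gapOpen,
          gapExtension = gapExtend, type = "global")
        100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      }, 0)
      cand <- cand[pids == max(pids)]
      # idsA sorted, so the first candidate is lexicographically smallest
    }
    cand[1]
  }

  topA <- integer(length(idsB))
  for (j in seq_along(idsB)) topA[j] <- pickTop(scoreMat[j, ], seqs[[idsB[j]]])

  keep <- seq_along(idsB)
  if (mode == "rbh") {
    topB <- integer(length(idsA))
    for (i in seq_along(idsA)) {
      col <- scoreMat[, i]
      best <- max(col)
      cand <- which(col == best)
      if (length(cand) > 1L) {
        pids <- vapply(cand, function(j) {
          pa <- Biostrings::pairwiseAlignment(
            setA[[i]], seqs[[idsB[j]]], substitutionMatrix = mat,
            gapOpening = gapOpen, gapExtension = gapExtend, type = "global")
          100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
        }, 0)
        cand <- cand[pids == max(pids)]
      }
      topB[i] <- cand[1]
    }
    keep <- which(topB[topA] == seq_along(idsB))
  }

  rows <- lapply(keep, function(j) {
    i <- topA[j]
    pa <- Biostrings::pairwiseAlignment(
      setA[[i]], seqs[[idsB[j]]], substitutionMatrix = mat,
      gapOpening = gapOpen, gapExtension = gapExtend, type = "global")
    data.frame(gene_a = idsA[i], gene_b = idsB[j],
               score = Biostrings::score(pa),
               identity = 100 * Biostrings::nmatch(pa) /
                 Biostrings::nchar(pa),
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               score = numeric(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(minIdentity))
    pairs <- pairs[pairs$identity >= minIdentity, , drop = FALSE]
  pairs <- pairs[order(pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  ouLog("orthologs: %d pairs (%s, %s -> %s)", nrow(pairs), mode,
        speciesA, speciesB)
  new("OrthologMap", speciesA = speciesA, speciesB = speciesB,
      mode = mode, pairs = pairs)
}

#' Write an ortholog map as TSV
#' @param map an \linkS4class{OrthologMap}.
#' @param file output path.
#' @export
writeOrthologMap <- function(map, file) {
  p <- map@pairs
  lines <- c("gene_a\tgene_b\tscore\tidentity",
             if (nrow(p)) paste(p$gene_a, p$gene_b,
                                format(p$score, trim = TRUE),
                                sprintf("%.4f", p$identity), sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Read an ortholog map from TSV
#' @param file path written by \code{\link{writeOrthologMap}}.
#' @param speciesA,speciesB species ids of the two sides.
#' @param mode pairing mode recorded in the object.
#' @export
readOrthologMap <- function(file, speciesA = "A", speciesB = "B",
                            mode = "one-way") {
  p <- read.delim(file, stringsAsFactors = FALSE)
  new("OrthologMap", speciesA = speciesA, speciesB = speciesB, mode = mode,
      pairs = data.frame(gene_a = as.character(p$gene_a),
                         gene_b = as.character(p$gene_b),
                         score = as.numeric(p$score),
                         identity = as.numeric(p$identity),
                         stringsAsFactors = FALSE))
}
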