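#' @importFrom utils read.delim write.table head combn
#' @importFrom stats setNames
NULL

# Round half-up to `digits` decimals. base::round() rounds half-to-even,
# which would print 0.125 as 0.12; annotation-coverage tables follow the
# conventional half-up rule instead (0.125 -> 0.13).
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stage logging to stderr; silenced with options(OrthoUnits.quiet = TRUE).
ouLog <- function(fmt, ...) {
  if (isTRUE(getOption("OrthoUnits.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(fmt, ...))
}

# Canonical unordered pair keys: lexicographically smaller id first.
pairKey <- function(a, b) {
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  list(a = lo, b = hi, key = paste(lo, hi, sep = "\r"))
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. All stochastic code in the package goes
# through this so that a single integer seed fixes every draw.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

emptyEdgeFrame <- function() {
  data.frame(from = character(0), to = character(0),
             score = numeric(0), sources = character(0),
             stringsAsFactors = FALSE)
}

AA_ALPHABET20X <- c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y","X")

checkAminoAcid <- function(seqs, where = "sequence") {
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(s %in% AA_ALPHABET20X))
    if (length(bad) > 0L) {
      stop(sprintf("illegal character '%s' at position %d of %s '%s'",
                   s[bad[1]], bad[1], where,
                   if (!is.null(names(seqs))) names(seqs)[i] else i),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
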