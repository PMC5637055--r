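## Internal helpers: alphabet handling and seeded evaluation.

.toRNA <- function(x) chartr("Tt", "Uu", toupper(x))
.toDNA <- function(x) chartr("Uu", "Tt", toupper(x))

## reverse complement of DNA strings (character in, character out)
.revcompDNA <- function(x) {
  comp <- chartr("ACGT", "TGCA", .toDNA(x))
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

.revcompRNA <- function(x) .toRNA(.revcompDNA(x))

## RNA Watson-Crick complement of a single base vector
.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

.checkAlphabet <- function(seqs, extra = "N", what = "sequence") {
  pat <- paste0("[^ACGTU", extra, "]")
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    id <- if (!is.null(names(seqs))) names(seqs)[bad][1L] else which(bad)[1L]
    stop("non-IUPAC character in ", what, " '", id, "'")
  }
  invisible(TRUE)
}

## Evaluate `code` under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  env <- globalenv()
  has <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

## Derive a child seed that stays inside 32-bit integer range.
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347) %% 2147483647)
}

.randSeq <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

## empty exon GRanges with the TranscriptSet metadata columns
.emptyExonGR <- function() {
  gr <- GRanges()
  mcols(gr)$transcript_id <- character(0)
  mcols(gr)$gene_id <- character(0)
  mcols(gr)$biotype <- character(0)
  gr
}

## substitute a substring (same length) at position `at` (1-based)
.replaceAt <- function(seq, at, repl) {
  paste0(substr(seq, 1L, at - 1L), repl,
         substr(seq, at + nchar(repl), nchar(seq)))
}
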