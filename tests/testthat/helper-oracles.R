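# Brute-force oracles and small shared fixtures. Oracles are written
# directly from the definitions and stay independent of the package
# code paths they check.

# step-up FDR adjustment by its definition: padj_(i) = min_{j>=i} m p_(j)/j
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# all target windows reverse-complementary to miRNA positions 2-7,
# found by checking every window base by base
bruteAnchors <- function(mirna, target) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  tg <- strsplit(chartr("T", "U", toupper(target)), "")[[1]]
  hits <- integer(0)
  if (length(tg) < 6) return(hits)
  for (s in 1:(length(tg) - 5)) {
    ok <- TRUE
    for (k in 2:7) {
      if (is.na(comp[m[k]]) || tg[s + 7 - k] != comp[[m[k]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# O(n*m) scan for spans within `window` bp (coordinate-difference gap)
bruteCisPairs <- function(lnc, gene, window) {
  out <- character(0)
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(gene))) {
      if (lnc$chrom[i] != gene$chrom[j]) next
      gap <- if (gene$start[j] > lnc$end[i]) gene$start[j] - lnc$end[i]
      else if (lnc$start[i] > gene$end[j]) lnc$start[i] - gene$end[j]
      else 0
      if (gap <= window)
        out <- c(out, paste(lnc$id[i], gene$id[j]))
    }
  }
  out
}

# strict same-strand containment of precursor loci in lncRNA spans
bruteContained <- function(prec, spans) {
  out <- character(0)
  for (i in seq_len(nrow(prec))) {
    for (j in seq_len(nrow(spans))) {
      if (prec$chrom[i] == spans$chrom[j] &&
          prec$strand[i] == spans$strand[j] &&
          prec$start[i] >= spans$start[j] &&
          prec$end[i] <= spans$end[j])
        out <- c(out, paste(spans$id[j], prec$id[i]))
    }
  }
  out
}

# 1 bp of exonic overlap between interval sets, by exhaustive pairs
bruteExonOverlap <- function(ex1, ex2) {
  for (i in seq_len(nrow(ex1))) {
    for (j in seq_len(nrow(ex2))) {
      if (ex1$chrom[i] == ex2$chrom[j] &&
          ex1$start[i] <= ex2$end[j] && ex1$end[i] >= ex2$start[j])
        return(TRUE)
    }
  }
  FALSE
}

# tiny TranscriptSet builder used across test files
makeTx <- function(...) {
  rows <- list(...)
  grs <- lapply(rows, function(r)
    GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$starts, r$ends),
                           strand = r$strand, transcript_id = r$id,
                           gene_id = ifelse(is.null(r$gene), r$id, r$gene),
                           biotype = ifelse(is.null(r$biotype), "unknown",
                                            r$biotype)))
  TranscriptSet(suppressWarnings(do.call(c, grs)))
}

# one shared default synthetic study (built once per test session)
sharedStudy <- local({
  bundle <- NULL
  function() {
    if (is.null(bundle)) bundle <<- simulateStudy(synthConfig(seed = 7))
    bundle
  }
})

# a tiny hexamer model shared by filter tests
sharedHexamers <- local({
  hex <- NULL
  function() {
    if (is.null(hex)) {
      set.seed(404)
      hex <<- ceRNAcycle:::.synthHexamers(n_train = 20L, train_len = 600L)
    }
    hex
  }
})

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
randomRNA <- function(n) chartr("T", "U", randomSeq(n))
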