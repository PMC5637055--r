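## Synthetic transcript sequences: codon-biased coding sequences and
## ORF/hexamer-constrained noncoding sequences, plus the hexamer
## training sets used by the coding-potential stand-in.

## biased codon table: GC-leaning usage, no stops
.codonTable <- function() {
  b <- c("A", "C", "G", "T")
  cods <- do.call(paste0, expand.grid(b, b, b))
  cods <- setdiff(cods, c("TAA", "TAG", "TGA"))
  w <- ifelse(substr(cods, 3L, 3L) %in% c("G", "C"), 3, 1) *
    ifelse(substr(cods, 1L, 1L) %in% c("G", "C"), 2, 1)
  list(codons = cods, weights = w / sum(w))
}

## coding-style sequence of exactly `len` nt: short 5' UTR, a long ORF
## (ATG..stop) covering ~70% of the transcript, 3' UTR remainder
.codingSeq <- function(len, tab = .codonTable()) {
  stopifnot(len >= 200L)
  utr5 <- max(10L, round(0.12 * len))
  cds_nt <- round(0.7 * len)
  cds_nt <- cds_nt - (cds_nt %% 3L)
  n_cod <- cds_nt / 3L - 2L          # minus start and stop
  cds <- paste0("ATG",
                paste(sample(tab$codons, n_cod, replace = TRUE,
                             prob = tab$weights), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  utr3 <- len - utr5 - nchar(cds)
  paste0(.randSeq(utr5), cds, .randSeq(max(0L, utr3)))
}

## longest ORF with its location: list(len, start) in nt coordinates
.orfScan <- function(seq) {
  n <- nchar(seq)
  best <- list(len = 0L, start = 0L)
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    if (!length(starts)) next
    cods <- substring(seq, starts, starts + 2L)
    open <- NA_integer_
    for (i in seq_along(cods)) {
      if (is.na(open) && cods[i] == "ATG") open <- i
      if (!is.na(open) && cods[i] %in% c("TAA", "TAG", "TGA")) {
        l <- (i - open + 1L) * 3L
        if (l > best$len) best <- list(len = l, start = starts[open])
        open <- NA_integer_
      }
    }
    if (!is.na(open)) {
      l <- (length(cods) - open + 1L) * 3L
      if (l > best$len) best <- list(len = l, start = starts[open])
    }
  }
  best
}

## noncoding sequence of `len` nt: longest ORF capped (both below the
## ORF-fraction and ORF-length detector thresholds) and clearly
## negative hexamer log-likelihood ratio under `model` (NULL skips the
## check; the margin keeps the call stable under later local edits)
.noncodingSeq <- function(len, model = NULL, margin = 5) {
  limit <- min(floor(0.33 * len), 288L)
  for (try in 1:50) {
    s <- .randSeq(len)
    for (it in 1:200) {
      orf <- .orfScan(s)
      if (orf$len <= limit) break
      ## knock a stop codon into the middle of the offending ORF
      mid <- orf$start + 3L * (orf$len %/% 6L)
      s <- .replaceAt(s, mid, "TAA")
    }
    if (.orfScan(s)$len > limit) next
    if (is.null(model) || .hexamerLLR(s, model) < -margin) return(s)
  }
  stop("failed to generate a noncoding sequence of length ", len)
}

## re-establish the noncoding fate of a sequence after site planting /
## anchor scrubbing, editing only outside `protect` intervals, and keep
## it anchor-free for the given miRNA set
.polishNoncoding <- function(seq, model, mirnas, protect = NULL) {
  limit <- min(floor(0.33 * nchar(seq)), 288L)
  clash <- function(s, e) {
    !is.null(protect) && nrow(protect) &&
      any(s <= protect$end & e >= protect$start)
  }
  for (it in 1:100) {
    orf <- .orfScan(seq)
    if (orf$len > limit) {
      cands <- orf$start + 3L * seq.int(1L, orf$len %/% 3L - 2L)
      cands <- cands[!vapply(cands, function(p) clash(p, p + 2L),
                             logical(1))]
      if (!length(cands)) stop("cannot patch ORF outside planted sites")
      seq <- .replaceAt(seq, cands[ceiling(length(cands) / 2)], "TAA")
      next
    }
    if (!is.null(model) && .hexamerLLR(seq, model) >= 0) {
      repeat {
        p <- sample.int(nchar(seq), 1L)
        if (!clash(p, p)) break
      }
      seq <- .replaceAt(seq, p, sample(c("A", "T"), 1L))
      next
    }
    seq2 <- .scrubAnchors(seq, mirnas, protect)
    if (identical(seq2, seq)) return(seq)
    seq <- seq2
  }
  stop("failed to polish a noncoding sequence")
}

## hexamer training sets + model
.synthHexamers <- function(n_train = 40L, train_len = 900L) {
  tab <- .codonTable()
  coding <- vapply(seq_len(n_train), function(i)
    .codingSeq(train_len, tab), "")
  noncoding <- vapply(seq_len(n_train), function(i)
    .randSeq(train_len), "")
  model <- hexamerModel(coding, noncoding)
  list(model = model, coding_train = coding, noncoding_train = noncoding)
}

## sequences for every candidate and coding gene, honoring designed
## coding/noncoding fates; returns a named character vector
.synthSequences <- function(ann, hex) {
  lens_cand <- txLengths(ann$candidates)
  lens_gene <- setNames(txLengths(ann$coding_genes),
                        geneIds(ann$coding_genes)[transcriptIds(ann$coding_genes)])
  fate <- setNames(ann$fates$class, ann$fates$transcript_id)
  tab <- .codonTable()
  seqs <- character(0)
  for (id in names(lens_cand)) {
    cls <- fate[[id]]
    seqs[[id]] <- if (cls %in% c("assembled_coding", "coding_orf"))
      .codingSeq(max(200L, lens_cand[[id]]), tab)
    else if (lens_cand[[id]] < 200L) .randSeq(lens_cand[[id]])
    else .noncodingSeq(lens_cand[[id]], hex$model)
  }
  ## mRNA sequences keyed by gene id (used for miRNA target scanning)
  for (g in names(lens_gene))
    seqs[[g]] <- .codingSeq(max(200L, lens_gene[[g]]), tab)
  ## truncate coding-style sequences back to the exact transcript length
  want <- c(lens_cand, lens_gene)
  for (id in names(seqs))
    seqs[[id]] <- substr(seqs[[id]], 1L, want[[id]])
  seqs
}
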