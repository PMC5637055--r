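## Five-step lncRNA identification pipeline with an audit trail, plus
## lincRNA/antisense classification. Boundary semantics follow the
## printed inequalities strictly: transcripts with length < 200, exon
## number < 2 or FPKM < 0.5 are removed; equality survives.

.audit <- function(step, ids_in, ids_out) {
  list(audit = data.frame(step = step, n_in = length(ids_in),
                          n_out = length(ids_out),
                          stringsAsFactors = FALSE),
       removed = setNames(list(setdiff(ids_in, ids_out)), step))
}

.bindAudit <- function(...) {
  parts <- list(...)
  list(audit = do.call(rbind, lapply(parts, `[[`, "audit")),
       removed = do.call(c, lapply(parts, `[[`, "removed")))
}

#' Structural filter: minimum length and exon number
#'
#' Removes transcripts shorter than `min_length` nt (step 1), then
#' single-exon transcripts (step 2, `min_exons`). Both sub-steps are
#' audited separately.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param min_length Minimum summed exon length (default 200; a 200-nt
#'   transcript is kept).
#' @param min_exons Minimum exon count (default 2).
#' @return List with `survivors` ([TranscriptSet-class]), `audit`
#'   (data.frame `step`, `n_in`, `n_out`) and `removed` (ids per step).
#' @export
structuralFilter <- function(transcripts, min_length = 200L,
                             min_exons = 2L) {
  ids <- transcriptIds(transcripts)
  len <- txLengths(transcripts)
  keep1 <- ids[len[ids] >= min_length]
  nex <- table(mcols(exonRanges(transcripts))$transcript_id)
  keep2 <- keep1[as.numeric(nex[keep1]) >= min_exons]
  a <- .bindAudit(.audit("min_length", ids, keep1),
                  .audit("min_exons", keep1, keep2))
  surv <- if (length(keep2)) transcripts[keep2] else
    TranscriptSet(exonRanges(transcripts)[0L])
  c(list(survivors = surv), a)
}

## exon-chain signature: chrom|strand|start-end,start-end,...
.chainSig <- function(ts) {
  ex <- exonRanges(ts)
  tx <- mcols(ex)$transcript_id
  sig <- tapply(seq_along(ex), tx, function(i) {
    i <- i[order(start(ex)[i])]
    paste0(as.character(seqnames(ex))[i[1L]], "|",
           as.character(strand(ex))[i[1L]], "|",
           paste(start(ex)[i], end(ex)[i], sep = "-", collapse = ","))
  })
  setNames(as.character(sig[transcriptIds(ts)]), transcriptIds(ts))
}

.NCRNA_TYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "pre_miRNA")

#' Remove candidates matching known annotation
#'
#' Operationalizes the "same or similar transcript" comparison against
#' known annotation. A candidate is removed when (a) its exon chain is
#' identical to a known transcript on the same strand, (b) it has
#' same-strand exonic overlap with a known mRNA covering at least
#' `coverage` of the candidate's exonic bases, or (c) it has any-strand
#' exonic overlap with an rRNA, tRNA, snRNA, snoRNA or pre-miRNA locus.
#'
#' @param transcripts Candidate [TranscriptSet-class].
#' @param known Known-annotation [TranscriptSet-class] with biotypes in
#'   `{coding, rRNA, tRNA, snRNA, snoRNA, pre_miRNA}`. An empty set
#'   raises a warning and removes nothing.
#' @param coverage Fraction of candidate exonic bases that a known mRNA
#'   must cover under rule (b) (default 0.5).
#' @return List `survivors`, `audit`, `removed` as in
#'   [structuralFilter()].
#' @export
knownOverlapFilter <- function(transcripts, known, coverage = 0.5) {
  ids <- transcriptIds(transcripts)
  if (length(known) == 0L) {
    warning("known annotation is empty; nothing removed")
    return(c(list(survivors = transcripts),
             .audit("known_overlap", ids, ids)))
  }
  ex <- exonRanges(transcripts)
  kx <- exonRanges(known)
  kbt <- mcols(kx)$biotype
  drop <- character(0)

  ## (a) identical exon chain, same strand
  csig <- .chainSig(transcripts)
  ksig <- .chainSig(known)
  drop <- c(drop, names(csig)[csig %in% ksig])

  ## (b) same-strand exonic overlap with known mRNA, >= coverage
  kc <- kx[kbt == "coding"]
  if (length(kc)) {
    red <- reduce(granges(kc))                 # strand-aware, disjoint
    hits <- findOverlaps(granges(ex), red, ignore.strand = FALSE)
    if (length(hits)) {
      q <- queryHits(hits); s <- subjectHits(hits)
      w <- pmin(end(ex)[q], end(red)[s]) - pmax(start(ex)[q], start(red)[s]) + 1L
      covered <- tapply(w, mcols(ex)$transcript_id[q], sum)
      len <- txLengths(transcripts)
      frac <- as.numeric(covered[names(len)]) / len
      frac[is.na(frac)] <- 0
      drop <- c(drop, names(len)[frac >= coverage])
    }
  }

  ## (c) any-strand exonic overlap with known structural/small RNA
  kn <- kx[kbt %in% .NCRNA_TYPES]
  if (length(kn)) {
    hits <- findOverlaps(granges(ex), granges(kn), ignore.strand = TRUE)
    drop <- c(drop, unique(mcols(ex)$transcript_id[queryHits(hits)]))
  }

  keep <- setdiff(ids, drop)
  surv <- if (length(keep)) transcripts[keep] else
    TranscriptSet(exonRanges(transcripts)[0L])
  c(list(survivors = surv), .audit("known_overlap", ids, keep))
}

#' Expression filter on FPKM
#'
#' A transcript is kept when its aggregated FPKM is at least
#' `threshold` (default 0.5; exactly 0.5 survives). The aggregation rule
#' is configurable because only the threshold is fixed by convention:
#' `max` across samples (default, the most permissive reading), `mean`,
#' or `all` (every sample must reach the threshold).
#'
#' @param transcripts A [TranscriptSet-class].
#' @param fpkm [ExpressionMatrix-class] with unit `FPKM`, covering every
#'   transcript (a missing transcript is an error naming it).
#' @param threshold FPKM threshold (default 0.5).
#' @param aggregate `"max"`, `"mean"` or `"all"`.
#' @return List `survivors`, `audit`, `removed`.
#' @export
expressionFilter <- function(transcripts, fpkm, threshold = 0.5,
                             aggregate = c("max", "mean", "all")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(fpkm, "ExpressionMatrix"))
  if (exprUnit(fpkm) != "FPKM") stop("expression matrix must be FPKM")
  ids <- transcriptIds(transcripts)
  v <- exprValues(fpkm)
  miss <- setdiff(ids, rownames(v))
  if (length(miss))
    stop("transcript(s) missing from the FPKM matrix: ",
         paste(head(miss), collapse = ", "))
  agg <- switch(aggregate,
                max = apply(v[ids, , drop = FALSE], 1L, max),
                mean = rowMeans(v[ids, , drop = FALSE]),
                all = apply(v[ids, , drop = FALSE], 1L, min))
  keep <- ids[agg >= threshold]
  surv <- if (length(keep)) transcripts[keep] else
    TranscriptSet(exonRanges(transcripts)[0L])
  c(list(survivors = surv), .audit("min_expression", ids, keep))
}

## longest open reading frame (ATG..stop, stop included; an ATG without
## a downstream in-frame stop counts up to the sequence end)
.longestOrf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    if (!length(starts)) next
    cods <- substring(seq, starts, starts + 2L)
    open <- NA_integer_
    for (i in seq_along(cods)) {
      if (is.na(open) && cods[i] == "ATG") open <- i
      if (!is.na(open) && cods[i] %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (i - open + 1L) * 3L)
        open <- NA_integer_
      }
    }
    if (!is.na(open)) best <- max(best, (length(cods) - open + 1L) * 3L)
  }
  best
}

#' Train a hexamer log-likelihood model
#'
#' Overlapping hexamer frequencies are tabulated separately on coding
#' and noncoding training sequences (with a pseudocount over the full
#' 4096-hexamer space); the model stores the per-hexamer log ratio
#' `log(p_coding / p_noncoding)`.
#'
#' @param coding_seqs,noncoding_seqs Character vectors of DNA training
#'   sequences.
#' @param pseudocount Added to every hexamer count (default 1).
#' @return List with element `logratio` (named numeric over hexamers).
#' @seealso [codingPotentialScore()]
#' @export
hexamerModel <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  all_hex <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6)))
  countHex <- function(seqs) {
    cnt <- setNames(rep(pseudocount, length(all_hex)), all_hex)
    for (s in seqs) {
      s <- .toDNA(s)
      n <- nchar(s)
      if (n < 6L) next
      h <- substring(s, 1:(n - 5L), 6:n)
      tab <- table(h)
      tab <- tab[names(tab) %in% all_hex]
      cnt[names(tab)] <- cnt[names(tab)] + as.numeric(tab)
    }
    cnt / sum(cnt)
  }
  pc <- countHex(coding_seqs)
  pn <- countHex(noncoding_seqs)
  list(logratio = log(pc / pn))
}

## summed hexamer log-likelihood ratio of a sequence under the model
.hexamerLLR <- function(seq, model) {
  seq <- .toDNA(seq)
  n <- nchar(seq)
  if (n < 6L) return(0)
  h <- substring(seq, 1:(n - 5L), 6:n)
  lr <- model$logratio[h]
  sum(lr, na.rm = TRUE)
}

#' Coding-potential consensus score
#'
#' A stand-in for external coding-potential tools, combining three
#' detectors on the transcript sequence: (d1) longest-ORF fraction of
#' the transcript above `orf_fraction_max`; (d2) positive hexamer
#' log-likelihood ratio under a caller-supplied [hexamerModel()]; (d3)
#' longest ORF of at least `orf_codons_max` codons. The consensus is
#' `noncoding` only when all three detectors say noncoding, mirroring
#' the intersection of independent tools. This scorer does not claim
#' equivalence to any external tool.
#'
#' @param sequence DNA sequence of length >= 200 (shorter input is an
#'   error: it belongs to the structural filter).
#' @param hexamer_model Model from [hexamerModel()].
#' @param orf_fraction_max d1 threshold (default 0.35).
#' @param orf_codons_max d3 threshold in codons, stop excluded
#'   (default 100).
#' @return List with `orf_fraction`, `hexamer_llr`, `detector_calls`
#'   (named character) and `consensus` (`coding`/`noncoding`).
#' @export
codingPotentialScore <- function(sequence, hexamer_model,
                                 orf_fraction_max = 0.35,
                                 orf_codons_max = 100L) {
  sequence <- .toDNA(sequence)
  if (nchar(sequence) < 200L)
    stop("sequence shorter than 200 nt; apply the structural filter first")
  .checkAlphabet(setNames(sequence, "input"), what = "transcript")
  orf_nt <- .longestOrf(sequence)
  orf_fraction <- orf_nt / nchar(sequence)
  codons <- max(0L, orf_nt %/% 3L - 1L)
  llr <- .hexamerLLR(sequence, hexamer_model)
  calls <- c(
    orf_fraction = ifelse(orf_fraction > orf_fraction_max, "coding", "noncoding"),
    hexamer = ifelse(llr > 0, "coding", "noncoding"),
    orf_length = ifelse(codons >= orf_codons_max, "coding", "noncoding"))
  list(orf_fraction = orf_fraction, hexamer_llr = llr,
       detector_calls = calls,
       consensus = ifelse(all(calls == "noncoding"), "noncoding", "coding"))
}

#' Classify surviving lncRNAs as lincRNA or antisense
#'
#' `antisense` means at least 1 bp of exonic overlap with a coding
#' transcript on the opposite strand; everything else is `lincRNA`.
#' Same-strand exonic overlap with a coding transcript is a
#' contradiction (such candidates are removed by the known-overlap
#' filter) and raises an error.
#'
#' @param lncrnas Surviving lncRNA [TranscriptSet-class].
#' @param coding_annotation [TranscriptSet-class] of coding transcripts.
#' @return Named character vector (`lincRNA`/`antisense`) over the
#'   lncRNA transcript ids.
#' @export
classifyLncRNA <- function(lncrnas, coding_annotation) {
  ids <- transcriptIds(lncrnas)
  if (!length(ids)) return(setNames(character(0), character(0)))
  ex <- exonRanges(lncrnas)
  cod <- exonRanges(coding_annotation)
  cod <- cod[mcols(cod)$biotype %in% c("coding", "unknown")]
  same <- findOverlaps(granges(ex), granges(cod), ignore.strand = FALSE)
  if (length(same))
    stop("same-strand exonic overlap with coding transcript(s) for: ",
         paste(unique(mcols(ex)$transcript_id[queryHits(same)]),
               collapse = ", "),
         " (should have been removed by the known-overlap filter)")
  flip <- granges(cod)
  strand(flip) <- ifelse(as.character(strand(flip)) == "+", "-", "+")
  anti <- findOverlaps(granges(ex), flip, ignore.strand = FALSE)
  anti_ids <- unique(mcols(ex)$transcript_id[queryHits(anti)])
  setNames(ifelse(ids %in% anti_ids, "antisense", "lincRNA"), ids)
}

#' Run the full five-step lncRNA identification pipeline
#'
#' Applies, in order: minimum length, minimum exon number, known-overlap
#' removal, expression filter, coding-potential filter; then classifies
#' survivors as lincRNA or antisense. All five predicates are pure
#' per-transcript tests, so the surviving set is invariant under filter
#' order (the coding-potential step passes sub-200-nt transcripts
#' through untouched — removing them is the length filter's job — which
#' keeps arbitrary orders well defined).
#'
#' @param transcripts Candidate [TranscriptSet-class].
#' @param known Known-annotation [TranscriptSet-class].
#' @param fpkm [ExpressionMatrix-class] (unit `FPKM`) covering all
#'   candidates.
#' @param sequences Named character vector of candidate DNA sequences.
#' @param hexamer_model From [hexamerModel()].
#' @param coding_annotation Coding transcripts used for classification;
#'   defaults to the coding subset of `known`.
#' @param threshold,aggregate Passed to [expressionFilter()].
#' @param coverage Passed to [knownOverlapFilter()].
#' @param orf_fraction_max,orf_codons_max Passed to
#'   [codingPotentialScore()].
#' @return List with `lncrnas` (surviving [TranscriptSet-class]),
#'   `classes` (named `lincRNA`/`antisense`), `audit` (5 filter rows),
#'   `removed` (ids per step) and `class_tally`.
#' @export
runLncRNAPipeline <- function(transcripts, known, fpkm, sequences,
                              hexamer_model, coding_annotation = NULL,
                              threshold = 0.5, aggregate = "max",
                              coverage = 0.5, orf_fraction_max = 0.35,
                              orf_codons_max = 100L) {
  s1 <- structuralFilter(transcripts)
  s3 <- knownOverlapFilter(s1$survivors, known, coverage = coverage)
  s4 <- expressionFilter(s3$survivors, fpkm, threshold = threshold,
                         aggregate = aggregate)
  ids <- transcriptIds(s4$survivors)
  miss <- setdiff(ids, names(sequences))
  if (length(miss))
    stop("missing sequence(s) for: ", paste(head(miss), collapse = ", "))
  noncoding <- vapply(ids, function(id) {
    if (nchar(sequences[[id]]) < 200L) return(TRUE)  # length filter's job
    codingPotentialScore(sequences[[id]], hexamer_model,
                         orf_fraction_max = orf_fraction_max,
                         orf_codons_max = orf_codons_max)$consensus ==
      "noncoding"
  }, logical(1))
  keep <- ids[noncoding]
  surv <- if (length(keep)) s4$survivors[keep] else
    TranscriptSet(exonRanges(transcripts)[0L])
  a <- .bindAudit(s1[c("audit", "removed")], s3[c("audit", "removed")],
                  s4[c("audit", "removed")],
                  .audit("coding_potential", ids, keep))
  if (is.null(coding_annotation)) {
    kx <- exonRanges(known)
    coding_annotation <- TranscriptSet(kx[mcols(kx)$biotype == "coding"])
  }
  classes <- classifyLncRNA(surv, coding_annotation)
  list(lncrnas = surv, classes = classes, audit = a$audit,
       removed = a$removed,
       class_tally = table(factor(classes, c("lincRNA", "antisense"))))
}
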