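## Cis-window and trans-correlation lncRNA target inference, and the
## intersection of both kinds of evidence.

.asSpans <- function(x, what = "input") {
  if (is(x, "TranscriptSet")) return(txSpans(x))
  if (is(x, "GRanges")) {
    if (!all(c("transcript_id", "gene_id") %in% colnames(mcols(x))))
      stop(what, " GRanges needs transcript_id and gene_id metadata")
    return(x)
  }
  stop(what, " must be a TranscriptSet or GRanges")
}

#' Coding genes within a cis window of lncRNA loci
#'
#' A pair is emitted when the genomic spans of the lncRNA and the gene
#' lie on the same chromosome with a gap of at most `window` bp between
#' their closest edges (0 for overlapping spans). The signed distance is
#' oriented by the lncRNA strand: positive downstream of the lncRNA,
#' negative upstream, 0 when the spans overlap.
#'
#' @param lncrnas,coding_genes [TranscriptSet-class] objects (or span
#'   `GRanges` with `transcript_id`/`gene_id` metadata).
#' @param window Maximum gap in bp (default 100000, i.e. 100 kb up- and
#'   downstream).
#' @return Data.frame `lncrna_id`, `gene_id`, `distance`, `side`
#'   (`upstream`, `downstream` or `overlapping`).
#' @export
cisTargets <- function(lncrnas, coding_genes, window = 100000) {
  ln <- .asSpans(lncrnas, "lncrnas")
  gn <- .asSpans(coding_genes, "coding_genes")
  if (!length(ln) || !length(gn))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance = numeric(), side = character(),
                      stringsAsFactors = FALSE))
  hits <- findOverlaps(ln, gn, maxgap = window, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance = numeric(), side = character(),
                      stringsAsFactors = FALSE))
  q <- queryHits(hits); s <- subjectHits(hits)
  ls <- start(ln)[q]; le <- end(ln)[q]
  gs <- start(gn)[s]; ge <- end(gn)[s]
  ## gap between closest span edges, measured as coordinate difference
  gap <- ifelse(gs > le, gs - le, ifelse(ls > ge, ls - ge, 0))
  keep <- gap <= window
  q <- q[keep]; s <- s[keep]; gap <- gap[keep]
  gs <- gs[keep]; le <- le[keep]
  ## gene right of lncRNA is downstream for '+' lncRNAs, upstream for '-'
  right <- gs > le
  plus <- as.character(strand(ln))[q] == "+"
  side <- ifelse(gap == 0, "overlapping",
                 ifelse(right == plus, "downstream", "upstream"))
  dist <- ifelse(side == "downstream", gap,
                 ifelse(side == "upstream", -gap, 0))
  out <- data.frame(lncrna_id = mcols(ln)$transcript_id[q],
                    gene_id = mcols(gn)$gene_id[s],
                    distance = dist, side = side,
                    stringsAsFactors = FALSE)
  ## one row per (lncRNA, gene): keep the closest transcript of the gene
  out <- out[order(out$lncrna_id, out$gene_id, abs(out$distance)), ]
  out <- out[!duplicated(out[, c("lncrna_id", "gene_id")]), ]
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation with strict input checks
#'
#' @param x,y Numeric vectors of equal length >= 3; constant vectors are
#'   an error (the correlation is undefined and the caller should
#'   exclude the feature).
#' @return The correlation coefficient.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined for a constant vector")
  cor(x, y)
}

#' Co-expression (trans) lncRNA-gene edges
#'
#' Computes all pairwise Pearson correlations between lncRNA and mRNA
#' expression profiles over the same samples and keeps pairs with
#' `r >= r_min` or (in `two_sided` mode) `r <= -r_min`, both inclusive.
#' The `positive` mode is the variant the ceRNA screen's rule (iii)
#' uses. Constant features are skipped with a message.
#'
#' @param lncrna_expr,mrna_expr [ExpressionMatrix-class] objects over an
#'   identical sample set and order (typically FPKM).
#' @param r_min Correlation threshold (default 0.95).
#' @param mode `"two_sided"` (default) or `"positive"`.
#' @return Data.frame `lncrna_id`, `gene_id`, `r`, `n_samples`.
#' @export
transTargets <- function(lncrna_expr, mrna_expr, r_min = 0.95,
                         mode = c("two_sided", "positive")) {
  mode <- match.arg(mode)
  stopifnot(is(lncrna_expr, "ExpressionMatrix"),
            is(mrna_expr, "ExpressionMatrix"))
  if (!identical(colnames(lncrna_expr), colnames(mrna_expr)))
    stop("sample sets/order differ between the two matrices")
  lv <- exprValues(lncrna_expr); mv <- exprValues(mrna_expr)
  n <- ncol(lv)
  if (n < 3L) stop("need at least 3 samples")
  lconst <- apply(lv, 1L, var) == 0
  mconst <- apply(mv, 1L, var) == 0
  if (any(lconst) || any(mconst))
    message("skipping constant features: ", sum(lconst), " lncRNA(s), ",
            sum(mconst), " gene(s)")
  lv <- lv[!lconst, , drop = FALSE]; mv <- mv[!mconst, , drop = FALSE]
  if (!nrow(lv) || !nrow(mv))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      r = numeric(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  R <- cor(t(lv), t(mv))
  hit <- if (mode == "two_sided") abs(R) >= r_min else R >= r_min
  idx <- which(hit, arr.ind = TRUE)
  data.frame(lncrna_id = rownames(R)[idx[, 1L]],
             gene_id = colnames(R)[idx[, 2L]],
             r = R[idx], n_samples = n,
             stringsAsFactors = FALSE)
}

#' Pairs supported by both co-localization and co-expression
#'
#' Intersection of [cisTargets()] and [transTargets()] output on
#' `(lncrna_id, gene_id)`, carrying both the genomic distance and the
#' correlation coefficient.
#'
#' @param cis Data.frame from [cisTargets()].
#' @param trans Data.frame from [transTargets()].
#' @return Merged data.frame, one row per pair present in both inputs.
#' @export
colocalizedCorrelatedPairs <- function(cis, trans) {
  out <- merge(cis, trans, by = c("lncrna_id", "gene_id"))
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' lncRNA loci hosting miRNA precursors
#'
#' A pair is reported when a precursor locus lies entirely within the
#' genomic span of an lncRNA on the same strand.
#'
#' @param lncrnas [TranscriptSet-class] (or span `GRanges`).
#' @param precursor_loci `GRanges` with a `precursor_id` metadata column.
#' @return Data.frame `lncrna_id`, `precursor_id`.
#' @export
precursorOverlap <- function(lncrnas, precursor_loci) {
  spans <- if (is(lncrnas, "TranscriptSet")) txSpans(lncrnas) else lncrnas
  if (!is(precursor_loci, "GRanges") ||
      !"precursor_id" %in% colnames(mcols(precursor_loci)))
    stop("precursor_loci must be a GRanges with a precursor_id column")
  if (!length(spans) || !length(precursor_loci))
    return(data.frame(lncrna_id = character(), precursor_id = character(),
                      stringsAsFactors = FALSE))
  hits <- findOverlaps(precursor_loci, spans, type = "within",
                       ignore.strand = FALSE)
  data.frame(lncrna_id = mcols(spans)$transcript_id[subjectHits(hits)],
             precursor_id = mcols(precursor_loci)$precursor_id[queryHits(hits)],
             stringsAsFactors = FALSE)
}
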