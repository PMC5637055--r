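#' Accessors for TranscriptSet objects
#'
#' @param x A [TranscriptSet-class].
#' @return `transcriptIds` gives the transcript ids in order of first
#'   appearance; `txLengths` the summed exon widths (named by transcript);
#'   `txSpans` a `GRanges` with one genomic span per transcript (metadata
#'   `transcript_id`, `gene_id`, `biotype`); `exonRanges` the underlying
#'   exon `GRanges`; `biotypes` and `geneIds` named character vectors.
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x)
  unique(mcols(x@exons)$transcript_id))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txLengths", "TranscriptSet", function(x) {
  ids <- transcriptIds(x)
  w <- tapply(width(x@exons), mcols(x@exons)$transcript_id, sum)
  setNames(as.numeric(w[ids]), ids)
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txSpans", "TranscriptSet", function(x) {
  ids <- transcriptIds(x)
  if (!length(ids)) return(.emptyExonGR())
  tx <- mcols(x@exons)$transcript_id
  first <- match(ids, tx)
  s <- tapply(start(x@exons), tx, min)[ids]
  e <- tapply(end(x@exons), tx, max)[ids]
  gr <- GRanges(as.character(seqnames(x@exons))[first],
                IRanges(as.numeric(s), as.numeric(e)),
                strand = as.character(strand(x@exons))[first])
  mcols(gr)$transcript_id <- ids
  mcols(gr)$gene_id <- mcols(x@exons)$gene_id[first]
  mcols(gr)$biotype <- mcols(x@exons)$biotype[first]
  names(gr) <- ids
  gr
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("exonRanges", "TranscriptSet", function(x) x@exons)

#' @rdname TranscriptSet-accessors
#' @export
setMethod("biotypes", "TranscriptSet", function(x) {
  ids <- transcriptIds(x)
  first <- match(ids, mcols(x@exons)$transcript_id)
  setNames(mcols(x@exons)$biotype[first], ids)
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("geneIds", "TranscriptSet", function(x) {
  ids <- transcriptIds(x)
  first <- match(ids, mcols(x@exons)$transcript_id)
  setNames(mcols(x@exons)$gene_id[first], ids)
})

#' Accessors for ExpressionMatrix objects
#'
#' @param x An [ExpressionMatrix-class].
#' @return `exprValues` the numeric feature x sample matrix; `exprUnit`
#'   the unit string; `sampleGroups` a named character vector of stage
#'   labels.
#' @name ExpressionMatrix-accessors
NULL

#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "values"))

#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("exprUnit", "ExpressionMatrix", function(x) x@unit)

#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("sampleGroups", "ExpressionMatrix", function(x)
  setNames(as.character(colData(x)$group), colnames(x)))

#' Accessors for NBModel objects
#'
#' @param x An [NBModel-class].
#' @name NBModel-accessors
NULL

#' @rdname NBModel-accessors
#' @export
setMethod("dispersions", "NBModel", function(x) x@dispersion)

#' @rdname NBModel-accessors
#' @export
setMethod("sizeFactors", "NBModel", function(x) x@sizeFactors)
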