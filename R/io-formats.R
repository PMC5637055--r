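## Readers and writers for the standard formats the pipeline touches.
## All readers validate and reject rather than repair; write/read is an
## identity on valid inputs (coordinate-exact for GTF).

#' Read transcript models from a GTF file
#'
#' Parses `exon` records, groups them per transcript and returns a
#' validated [TranscriptSet-class]. Attributes `transcript_id` and
#' `gene_id` are required; a `biotype` attribute is used when present and
#' defaults to `"unknown"`. Unstranded (`.`) exon records are rejected
#' because downstream antisense classification is strand-dependent.
#'
#' @param path Path to a GTF file (plain text or gzip).
#' @return A [TranscriptSet-class]; empty input gives an empty set.
#' @seealso [writeTranscripts()]
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GTF record at line ", i, " (", length(f), " fields)")
    s <- suppressWarnings(as.numeric(f[4L]))
    e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF record at line ", i, " (non-numeric coordinates)")
    if (s > e)
      stop("validation error at line ", i, ": exon start > end")
    if (tolower(f[3L]) == "exon" && !f[7L] %in% c("+", "-"))
      stop("validation error at line ", i,
           ": unstranded exon ('.') is not allowed")
  }
  if (!any(keep)) return(TranscriptSet(.emptyExonGR()))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[tolower(as.character(mcols(gr)$type)) == "exon"]
  mc <- mcols(gr)
  if (!all(c("transcript_id", "gene_id") %in% colnames(mc)) ||
      any(is.na(mc$transcript_id)) || any(is.na(mc$gene_id)))
    stop("every exon record needs transcript_id and gene_id attributes")
  bt <- if ("biotype" %in% colnames(mc)) as.character(mc$biotype) else
    rep(NA_character_, length(gr))
  bt[is.na(bt)] <- "unknown"
  out <- granges(gr)
  mcols(out)$transcript_id <- as.character(mc$transcript_id)
  mcols(out)$gene_id <- as.character(mc$gene_id)
  mcols(out)$biotype <- bt
  TranscriptSet(out)
}

#' Write transcript models to GTF
#'
#' One `exon` record per exon, with `transcript_id`, `gene_id` and
#' `biotype` attributes. `readTranscripts(writeTranscripts(x))` returns a
#' coordinate-identical set.
#'
#' @param ts A [TranscriptSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTranscripts <- function(ts, path) {
  stopifnot(is(ts, "TranscriptSet"))
  gr <- exonRanges(ts)
  out <- granges(gr)
  mcols(out)$source <- rep("ceRNAcycle", length(out))
  mcols(out)$type <- rep("exon", length(out))
  mcols(out)$transcript_id <- mcols(gr)$transcript_id
  mcols(out)$gene_id <- mcols(gr)$gene_id
  mcols(out)$biotype <- mcols(gr)$biotype
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param rna If `TRUE`, normalize `T` to `U` (mature miRNA files are
#'   stored in the RNA alphabet, genomic/transcript FASTA in DNA).
#' @return Named character vector of upper-case sequences; ids are the
#'   first whitespace-delimited token of each header. Duplicate ids and
#'   non-IUPAC characters are errors.
#' @seealso [writeFastaSeqs()]
#' @export
readFastaSeqs <- function(path, rna = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- setNames(toupper(as.character(ss)), ids)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id '", ids[nchar(seqs) == 0L][1L], "'")
  .checkAlphabet(seqs, what = "FASTA record")
  if (rna) seqs <- .toRNA(seqs)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  writeXStringSet(BStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read an expression table (TSV)
#'
#' Expects a header row of sample ids and feature ids in the first
#' column. Values must be non-negative; every sample needs a stage label.
#'
#' @param path Path to a tab-separated table.
#' @param unit One of `"count"`, `"FPKM"`, `"CPM"`.
#' @param groups Named character vector sample id -> `anagen`/`telogen`.
#' @return An [ExpressionMatrix-class].
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(path, unit, groups) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected feature ids plus at least one sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in expression table")
  rownames(m) <- ids
  ExpressionMatrix(m, unit = unit, groups = groups)
}

#' Write an expression table (TSV)
#'
#' @param em An [ExpressionMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(em, path) {
  stopifnot(is(em, "ExpressionMatrix"))
  v <- exprValues(em)
  df <- data.frame(feature_id = rownames(v),
                   format(v, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   member gene ids, tab-separated).
#' @return Named list of character vectors; empty sets are an error.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty))
    stop("gene set(s) without members: ",
         paste(names(sets)[empty], collapse = ", "))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(sets, path) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

.NODE_TYPES <- c("lncRNA", "miRNA", "mRNA")
.EDGE_HEADER <- c("source", "source_type", "target", "target_type",
                  "sign", "evidence")

#' Write a typed network edge list (TSV)
#'
#' Fixed header `source, source_type, target, target_type, sign,
#' evidence`; node types must be `lncRNA`, `miRNA` or `mRNA` and the sign
#' `+` or `-`. The file is directly loadable in graph tools such as
#' Cytoscape.
#'
#' @param edges Data.frame with the six columns above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [readNetworkEdges()], [buildCernaNetwork()]
#' @export
writeNetworkEdges <- function(edges, path) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  miss <- setdiff(.EDGE_HEADER, colnames(edges))
  if (length(miss)) stop("missing edge column(s): ", paste(miss, collapse = ", "))
  edges <- edges[, .EDGE_HEADER, drop = FALSE]
  badt <- setdiff(unique(c(edges$source_type, edges$target_type)), .NODE_TYPES)
  if (nrow(edges) && length(badt))
    stop("unknown node type(s): ", paste(badt, collapse = ", "))
  if (nrow(edges) && !all(edges$sign %in% c("+", "-")))
    stop("edge sign must be '+' or '-'")
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typed network edge list written by [writeNetworkEdges()]
#'
#' @param path Path to the TSV edge list.
#' @return Data.frame with the fixed six-column header.
#' @export
readNetworkEdges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!identical(colnames(df), .EDGE_HEADER))
    stop("unexpected edge-list header")
  df
}
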