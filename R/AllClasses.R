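## Central S4 containers. Coordinates are GTF convention throughout:
## 1-based, inclusive on both ends.

.BIOTYPES <- c("coding", "lncRNA_candidate", "lincRNA", "antisense",
               "rRNA", "tRNA", "snRNA", "snoRNA", "pre_miRNA", "unknown")
.GROUPS <- c("anagen", "telogen")
.UNITS <- c("count", "FPKM", "CPM")

#' Set of exon-structured, stranded transcript models
#'
#' A `TranscriptSet` holds the exons of one or more transcripts as a
#' [GenomicRanges::GRanges] with metadata columns `transcript_id`,
#' `gene_id` and `biotype`. Exons of a transcript must lie on a single
#' chromosome and strand, be sorted in ascending order and be
#' non-overlapping; every transcript has at least one exon and strand
#' `+` or `-` (unstranded transcripts are rejected because the
#' antisense/lincRNA classification is strand-dependent).
#'
#' @slot exons A `GRanges` of exons carrying `transcript_id`, `gene_id`
#'   and `biotype` metadata columns.
#' @seealso [TranscriptSet()], [readTranscripts()], [txSpans()]
#' @export
setClass("TranscriptSet", slots = c(exons = "GRanges"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  need <- c("transcript_id", "gene_id", "biotype")
  miss <- setdiff(need, colnames(mcols(ex)))
  if (length(miss))
    return(paste("missing exon metadata column(s):", paste(miss, collapse = ", ")))
  if (length(ex) == 0L) return(TRUE)
  if (any(is.na(mcols(ex)$transcript_id)) || any(is.na(mcols(ex)$gene_id)))
    return("transcript_id and gene_id must not be NA")
  if (!all(mcols(ex)$biotype %in% .BIOTYPES))
    return(paste("invalid biotype(s):",
                 paste(unique(setdiff(mcols(ex)$biotype, .BIOTYPES)), collapse = ", ")))
  st <- as.character(strand(ex))
  if (!all(st %in% c("+", "-")))
    return("all exons must be stranded ('+' or '-')")
  tx <- mcols(ex)$transcript_id
  for (id in unique(tx)) {
    i <- which(tx == id)
    if (length(unique(as.character(seqnames(ex)[i]))) != 1L)
      return(paste0("transcript ", id, " spans multiple chromosomes"))
    if (length(unique(st[i])) != 1L)
      return(paste0("transcript ", id, " mixes strands"))
    if (length(unique(mcols(ex)$gene_id[i])) != 1L)
      return(paste0("transcript ", id, " has multiple gene_ids"))
    if (length(unique(mcols(ex)$biotype[i])) != 1L)
      return(paste0("transcript ", id, " has multiple biotypes"))
    s <- start(ex)[i]; e <- end(ex)[i]
    o <- order(s)
    if (length(i) > 1L && any(s[o][-1L] <= e[o][-length(o)]))
      return(paste0("transcript ", id, " has overlapping exons"))
  }
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons `GRanges` of exons with metadata columns `transcript_id`,
#'   `gene_id` and `biotype` (`biotype` defaults to `"unknown"` when
#'   absent). Exons are sorted per transcript; transcript order follows
#'   first appearance.
#' @return A [TranscriptSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 300), c(200, 400)),
#'   strand = "+", transcript_id = "t1", gene_id = "g1", biotype = "unknown")
#' ts <- TranscriptSet(gr)
#' txLengths(ts)
#' @export
TranscriptSet <- function(exons) {
  if (!"biotype" %in% colnames(mcols(exons)))
    mcols(exons)$biotype <- rep("unknown", length(exons))
  if (length(exons)) {
    tx <- mcols(exons)$transcript_id
    ord <- order(match(tx, unique(tx)), start(exons))
    exons <- exons[ord]
  }
  new("TranscriptSet", exons = exons)
}

#' @describeIn TranscriptSet-class number of transcripts
#' @param x,object A `TranscriptSet`.
#' @export
setMethod("length", "TranscriptSet", function(x)
  length(unique(mcols(x@exons)$transcript_id)))

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object)
  bt <- biotypes(object)
  cat("TranscriptSet with", n, "transcript(s),",
      length(object@exons), "exon(s)\n")
  if (n) {
    tab <- table(bt)
    cat("  biotypes:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  }
})

#' Extract transcripts by id, index or logical mask
#' @param x A `TranscriptSet`.
#' @param i Character transcript ids, integer indices or logical vector
#'   over transcripts.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  ids <- transcriptIds(x)
  keep <- if (is.character(i)) {
    if (!all(i %in% ids)) stop("unknown transcript id(s): ",
                               paste(setdiff(i, ids), collapse = ", "))
    i
  } else ids[i]
  TranscriptSet(x@exons[mcols(x@exons)$transcript_id %in% keep])
})

#' Expression matrix with unit and stage labels
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one non-negative assay (`values`), a measurement `unit` (`count`,
#' `FPKM` or `CPM`) and a hair-follicle stage label (`anagen` or
#' `telogen`) for every sample in `colData(x)$group`.
#'
#' @slot unit Character scalar, one of `count`, `FPKM`, `CPM`.
#' @seealso [ExpressionMatrix()], [exprValues()], [sampleGroups()]
#' @export
setClass("ExpressionMatrix",
         contains = "SummarizedExperiment",
         slots = c(unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  if (length(object@unit) != 1L || !object@unit %in% .UNITS)
    return(paste("unit must be one of:", paste(.UNITS, collapse = ", ")))
  v <- assay(object, "values")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("feature ids must be present and unique")
  if (any(!is.finite(v)) || any(v < 0))
    return("values must be finite and non-negative")
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    return("colData must contain a 'group' column")
  g <- as.character(cd$group)
  if (any(is.na(g)) || !all(g %in% .GROUPS))
    return(paste("every sample needs a group label in:",
                 paste(.GROUPS, collapse = ", ")))
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values Numeric matrix, features x samples, with dimnames.
#' @param unit One of `"count"`, `"FPKM"`, `"CPM"`.
#' @param groups Named character vector mapping every sample id to
#'   `"anagen"` or `"telogen"`.
#' @return An [ExpressionMatrix-class].
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' em <- ExpressionMatrix(m, "count",
#'   c(s1 = "anagen", s2 = "anagen", s3 = "telogen"))
#' exprUnit(em)
#' @export
ExpressionMatrix <- function(values, unit, groups) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("sample ids (column names) are required")
  if (!all(colnames(values) %in% names(groups)))
    stop("sample(s) without a group label: ",
         paste(setdiff(colnames(values), names(groups)), collapse = ", "))
  se <- SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(group = unname(groups[colnames(values)]),
                        row.names = colnames(values)))
  new("ExpressionMatrix", se, unit = unit)
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object), "feature(s) x", ncol(object),
      "sample(s), unit =", object@unit, "\n")
  g <- sampleGroups(object)
  cat("  groups:", paste(names(table(g)), table(g), sep = ":", collapse = ", "), "\n")
})

#' Negative-binomial model fit used by the Wald test
#'
#' Per-feature method-of-moments dispersion estimates together with
#' median-of-ratios size factors. The dispersion parameterization is
#' `variance = mu + phi * mu^2`.
#'
#' @slot dispersion Named numeric, per-feature `phi >= 0`.
#' @slot sizeFactors Named numeric, per-sample positive size factors.
#' @slot flagged Character vector of feature ids with all-zero counts
#'   (their dispersion is reported as 0).
#' @seealso [estimateDispersion()], [nbWaldTest()]
#' @export
setClass("NBModel",
         slots = c(dispersion = "numeric", sizeFactors = "numeric",
                   flagged = "character"))

setValidity("NBModel", function(object) {
  if (any(!is.finite(object@dispersion)) || any(object@dispersion < 0))
    return("dispersions must be finite and >= 0")
  if (any(!is.finite(object@sizeFactors)) || any(object@sizeFactors <= 0))
    return("size factors must be finite and positive")
  TRUE
})

setMethod("show", "NBModel", function(object) {
  cat("NBModel:", length(object@dispersion), "feature(s),",
      length(object@sizeFactors), "sample(s)\n")
  cat("  median dispersion:", signif(median(object@dispersion), 3),
      "| size factors:", paste(signif(object@sizeFactors, 3), collapse = ", "), "\n")
})

#' Configuration of the synthetic hair-follicle study
#'
#' Mirrors the study design emulated by the generator: 3 anagen + 3
#' telogen RNA libraries and 2 pooled small-RNA libraries per stage,
#' negative-binomial counts, a planted fraction of differentially
#' expressed features, planted lncRNA-mRNA co-expression and planted
#' miRNA binding sites forming known ceRNA triplets. See the package
#' vignette for the rationale behind each default.
#'
#' @slot seed Integer seed; the full bundle is a deterministic function
#'   of the configuration.
#' @slot n_anagen,n_telogen RNA library count per stage (default 3 + 3).
#' @slot n_srna_libs_per_group Pooled small-RNA libraries per stage (2).
#' @slot n_coding,n_lncrna,n_mirna Feature counts.
#' @slot mean_expression Log-normal location of per-feature mean counts.
#' @slot dispersion NB dispersion `phi` (`variance = mu + phi mu^2`).
#' @slot de_fraction Fraction of features with planted differential
#'   expression.
#' @slot planted_log2fc Magnitude of the planted log2 fold change
#'   (anagen over telogen; signs alternate).
#' @slot n_correlated_pairs Planted co-expressed lncRNA-mRNA pairs.
#' @slot n_cerna_triplets Planted (lncRNA, miRNA, mRNA) ceRNA triplets.
#' @slot decoy_fraction Fraction of lncRNA candidates designed to fail
#'   exactly one identification filter.
#' @slot library_size Total mapped fragments per RNA library (FPKM
#'   denominator).
#' @seealso [synthConfig()], [simulateStudy()]
#' @export
setClass("SynthConfig",
  slots = c(seed = "integer", n_anagen = "integer", n_telogen = "integer",
            n_srna_libs_per_group = "integer", n_coding = "integer",
            n_lncrna = "integer", n_mirna = "integer",
            mean_expression = "numeric", dispersion = "numeric",
            de_fraction = "numeric", planted_log2fc = "numeric",
            n_correlated_pairs = "integer", n_cerna_triplets = "integer",
            decoy_fraction = "numeric", library_size = "numeric"))

setValidity("SynthConfig", function(object) {
  cnt <- c(object@n_anagen, object@n_telogen, object@n_srna_libs_per_group,
           object@n_coding, object@n_lncrna, object@n_mirna,
           object@n_correlated_pairs, object@n_cerna_triplets)
  if (any(is.na(cnt)) || any(cnt < 0L)) return("all counts must be >= 0")
  if (object@dispersion < 0) return("dispersion must be >= 0")
  if (object@de_fraction < 0 || object@de_fraction > 1)
    return("de_fraction must be in [0, 1]")
  if (object@decoy_fraction < 0 || object@decoy_fraction > 1)
    return("decoy_fraction must be in [0, 1]")
  if (object@mean_expression <= 0) return("mean_expression must be > 0")
  if (object@library_size <= 0) return("library_size must be > 0")
  TRUE
})

#' Create a synthetic-study configuration
#'
#' Defaults reproduce the emulated study design: 6 skin RNA libraries
#' (3 anagen, 3 telogen), 4 pooled small-RNA libraries (2 per stage),
#' negative-binomial counts, planted |log2FC| = 2 on 15% of features,
#' 20 co-expressed lncRNA-mRNA pairs and 10 planted ceRNA triplets.
#'
#' @param seed Integer seed.
#' @param n_anagen,n_telogen,n_srna_libs_per_group,n_coding,n_lncrna,n_mirna
#'   Design sizes; see [SynthConfig-class].
#' @param mean_expression,dispersion,de_fraction,planted_log2fc Expression
#'   model parameters.
#' @param n_correlated_pairs,n_cerna_triplets,decoy_fraction Planted-truth
#'   sizes.
#' @param library_size Total mapped fragments per RNA library.
#' @return A validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(seed = 1)
#' cfg
#' @export
synthConfig <- function(seed = 1L, n_anagen = 3L, n_telogen = 3L,
                        n_srna_libs_per_group = 2L, n_coding = 150L,
                        n_lncrna = 120L, n_mirna = 30L,
                        mean_expression = 300, dispersion = 0.05,
                        de_fraction = 0.15, planted_log2fc = 2,
                        n_correlated_pairs = 15L, n_cerna_triplets = 10L,
                        decoy_fraction = 0.35, library_size = 1e7) {
  new("SynthConfig", seed = as.integer(seed),
      n_anagen = as.integer(n_anagen), n_telogen = as.integer(n_telogen),
      n_srna_libs_per_group = as.integer(n_srna_libs_per_group),
      n_coding = as.integer(n_coding), n_lncrna = as.integer(n_lncrna),
      n_mirna = as.integer(n_mirna), mean_expression = mean_expression,
      dispersion = dispersion, de_fraction = de_fraction,
      planted_log2fc = planted_log2fc,
      n_correlated_pairs = as.integer(n_correlated_pairs),
      n_cerna_triplets = as.integer(n_cerna_triplets),
      decoy_fraction = decoy_fraction, library_size = library_size)
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig (seed", object@seed, "):",
      object@n_anagen, "anagen +", object@n_telogen, "telogen libraries;",
      object@n_coding, "coding genes,", object@n_lncrna, "lncRNA candidates,",
      object@n_mirna, "miRNAs\n")
  cat("  de_fraction", object@de_fraction, "| planted log2FC",
      object@planted_log2fc, "| triplets", object@n_cerna_triplets, "\n")
})

#' Complete in-silico study with planted ground truth
#'
#' Produced by [simulateStudy()]. Bundles annotation (candidates, known
#' transcripts, coding genes), transcript sequences, count matrices,
#' small-RNA tag libraries, miRNA records, pathway gene sets and the
#' planted truth tables that the test suite checks recovery against.
#'
#' @slot config The generating [SynthConfig-class].
#' @slot candidates,known,codingGenes [TranscriptSet-class] objects.
#' @slot sequences Named character vector of transcript DNA sequences.
#' @slot mrnaCounts,lncrnaCounts [ExpressionMatrix-class] (unit `count`).
#' @slot librarySizes Named numeric, total mapped fragments per library.
#' @slot srnaTags List per small-RNA library of data.frames
#'   (`seq`, `count`).
#' @slot mirna Data.frame of mature miRNA records (name, mature_seq,
#'   precursor_id).
#' @slot precursorSeqs Named character (precursor RNA sequences).
#' @slot precursorLoci `GRanges` of precursor genomic loci.
#' @slot geneSets Named list of gene-id vectors (pathway collections).
#' @slot hexamers Hexamer model (see [hexamerModel()]).
#' @slot chromLengths Named numeric chromosome lengths.
#' @slot truth List of planted-truth tables.
#' @export
setClass("StudyBundle",
  slots = c(config = "SynthConfig", candidates = "TranscriptSet",
            known = "TranscriptSet", codingGenes = "TranscriptSet",
            sequences = "character", mrnaCounts = "ExpressionMatrix",
            lncrnaCounts = "ExpressionMatrix", librarySizes = "numeric",
            srnaTags = "list", mirna = "data.frame",
            precursorSeqs = "character", precursorLoci = "GRanges",
            geneSets = "list", hexamers = "list",
            chromLengths = "numeric", truth = "list"))

setValidity("StudyBundle", function(object) {
  tr <- object@truth$triplets
  if (!is.null(tr) && nrow(tr)) {
    if (!all(tr$lncrna_id %in% names(object@sequences)))
      return("triplet lncRNA id(s) missing from sequences")
    if (!all(tr$mrna_id %in% names(object@sequences)))
      return("triplet mRNA id(s) missing from sequences")
    if (!all(tr$mirna %in% object@mirna$name))
      return("triplet miRNA(s) missing from mirna records")
  }
  TRUE
})

setMethod("show", "StudyBundle", function(object) {
  cat("StudyBundle (seed", object@config@seed, ")\n")
  cat("  candidates:", length(object@candidates),
      "| known:", length(object@known),
      "| coding genes:", length(object@codingGenes), "\n")
  cat("  mRNA counts:", nrow(object@mrnaCounts), "x", ncol(object@mrnaCounts),
      "| lncRNA counts:", nrow(object@lncrnaCounts), "x",
      ncol(object@lncrnaCounts), "\n")
  cat("  sRNA libraries:", length(object@srnaTags),
      "| miRNAs:", nrow(object@mirna),
      "| planted triplets:", nrow(object@truth$triplets), "\n")
})
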