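## Synthetic genome annotation with designed per-filter fates.
##
## Two 5-Mb chromosomes. chr1 carries most coding genes with intergenic
## gaps that host clean lncRNA candidates (within 100 kb of genes, i.e.
## cis cases); chr2 carries the remaining genes, the known structural/
## small-RNA loci, and a gene desert (> 100 kb from any coding gene)
## for intergenic lncRNAs. Every decoy candidate class is engineered to
## fail exactly one identification filter.

.CHROMS <- c(chr1 = 5e6, chr2 = 5e6)

## exon rows as a plain data.frame (one GRanges is built per set at the
## end; constructing hundreds of small S4 objects is too slow)
.txExons <- function(chrom, strand, starts, ends, tx, gene, biotype) {
  data.frame(chrom = chrom, strand = strand, start = starts, end = ends,
             transcript_id = tx, gene_id = gene, biotype = biotype,
             stringsAsFactors = FALSE)
}

.grFromRows <- function(rows) {
  df <- do.call(rbind, rows)
  gr <- GRanges(factor(df$chrom, levels = names(.CHROMS)),
                IRanges(df$start, df$end), strand = df$strand,
                transcript_id = df$transcript_id, gene_id = df$gene_id,
                biotype = df$biotype)
  GenomeInfoDb::seqlengths(gr) <- .CHROMS
  gr
}

## exon chain from a start coordinate and exon/intron widths
.chainFrom <- function(start, exon_lens, intron_lens) {
  s <- integer(length(exon_lens)); e <- integer(length(exon_lens))
  cur <- start
  for (i in seq_along(exon_lens)) {
    s[i] <- cur
    e[i] <- cur + exon_lens[i] - 1L
    cur <- e[i] + 1L + if (i < length(exon_lens)) intron_lens[i] else 0L
  }
  list(starts = s, ends = e)
}

## split a target total length into `k` exon widths (each >= min_w, sum
## exactly `total`)
.splitLen <- function(total, k, min_w = 30L) {
  if (k == 1L) return(total)
  stopifnot(total >= k * min_w)
  repeat {
    cuts <- sort(sample(seq_len(total - 1L), k - 1L))
    parts <- diff(c(0L, cuts, total))
    if (all(parts >= min_w)) return(parts)
  }
}

.FAIL_CLASSES <- c("too_short", "single_exon", "known_dup", "mrna_overlap",
                   "ncrna_overlap", "low_expr", "coding_orf")
.STEP_OF_CLASS <- c(too_short = "min_length", single_exon = "min_exons",
                    known_dup = "known_overlap",
                    mrna_overlap = "known_overlap",
                    ncrna_overlap = "known_overlap",
                    low_expr = "min_expression",
                    coding_orf = "coding_potential",
                    cis_linc = "survivor", desert_linc = "survivor",
                    antisense = "survivor")

## core builder shared by simulateAnnotation() and the filter fixture
.synthAnnotation <- function(n_coding, class_counts,
                             include_assembled_coding = TRUE) {
  ## ---- coding genes --------------------------------------------------
  genes <- list(); gaps <- list()
  nc1 <- ceiling(0.6 * n_coding); nc2 <- n_coding - nc1
  place_genes <- function(chrom, n, start, limit, gap_range) {
    out <- list(); gp <- list(); cursor <- start
    for (i in seq_len(n)) {
      nex <- sample(3:7, 1L)
      exl <- sample(120:400, nex, replace = TRUE)
      inl <- sample(800:2500, max(0L, nex - 1L), replace = TRUE)
      ch <- .chainFrom(cursor, exl, inl)
      if (max(ch$ends) > limit)
        stop("chromosome capacity insufficient for requested features")
      out[[i]] <- list(chrom = chrom, strand = sample(c("+", "-"), 1L),
                       starts = ch$starts, ends = ch$ends)
      gap <- sample(gap_range[1L]:gap_range[2L], 1L)
      gp[[i]] <- c(max(ch$ends) + 2000L, max(ch$ends) + gap - 2000L)
      cursor <- max(ch$ends) + gap
    }
    list(genes = out, gaps = gp)
  }
  p1 <- place_genes("chr1", nc1, 20000L, .CHROMS[["chr1"]] - 100000L,
                    c(15000L, 30000L))
  p2 <- place_genes("chr2", nc2, 100000L, 1900000L, c(8000L, 15000L))
  genes <- c(p1$genes, p2$genes)
  gene_ids <- sprintf("GENE_%03d", seq_len(n_coding))
  names(genes) <- gene_ids

  ## each intergenic chr1 gap offers two candidate slots
  slot_list <- list()
  for (i in seq_along(p1$gaps)) {
    g <- p1$gaps[[i]]
    half <- floor((g[2L] - g[1L]) / 2)
    slot_list[[length(slot_list) + 1L]] <-
      list(start = g[1L], width = half - 500L,
           flank_gene = gene_ids[min(i + 1L, nc1)])
    slot_list[[length(slot_list) + 1L]] <-
      list(start = g[1L] + half, width = half - 500L,
           flank_gene = gene_ids[i])
  }
  slot_cursor <- 0L
  take_slot <- function() {
    slot_cursor <<- slot_cursor + 1L
    if (slot_cursor > length(slot_list))
      stop("chromosome capacity insufficient for requested features")
    slot_list[[slot_cursor]]
  }

  ## ---- known structural/small RNA loci on chr2 -----------------------
  nc_loci <- list(); cursor <- 1950000L
  for (bt in .NCRNA_TYPES) {
    lens <- c(rRNA = 1500L, tRNA = 80L, snRNA = 150L, snoRNA = 120L,
              pre_miRNA = 80L)[[bt]]
    for (j in 1:4) {
      nc_loci[[length(nc_loci) + 1L]] <-
        list(biotype = bt, chrom = "chr2", strand = sample(c("+", "-"), 1L),
             start = cursor, end = cursor + lens - 1L)
      cursor <- cursor + lens + 20000L
    }
  }
  if (cursor > 2450000L)
    stop("chromosome capacity insufficient for requested features")

  ## ---- lncRNA candidates --------------------------------------------
  cand <- list(); fates <- list()
  lnc_i <- 0L
  add_cand <- function(class, chrom, strand, starts, ends, flank = NA) {
    lnc_i <<- lnc_i + 1L
    id <- sprintf("LNC_%03d", lnc_i)
    cand[[id]] <<- list(chrom = chrom, strand = strand, starts = starts,
                        ends = ends)
    fates[[id]] <<- data.frame(transcript_id = id, class = class,
                               step = .STEP_OF_CLASS[[class]],
                               flank_gene = flank,
                               stringsAsFactors = FALSE)
    id
  }
  clean_in_slot <- function(class, total_len, nex) {
    sl <- take_slot()
    exl <- .splitLen(total_len, nex)
    inl <- if (nex > 1L) sample(500:1500, nex - 1L, replace = TRUE) else integer(0)
    ch <- .chainFrom(sl$start + sample(0:200, 1L), exl, inl)
    if (max(ch$ends) > sl$start + sl$width)
      stop("chromosome capacity insufficient for requested features")
    add_cand(class, "chr1", sample(c("+", "-"), 1L), ch$starts, ch$ends,
             flank = sl$flank_gene)
  }

  cc <- class_counts
  for (k in seq_len(cc[["too_short"]]))
    clean_in_slot("too_short", sample(150:199, 1L), 2L)
  for (k in seq_len(cc[["single_exon"]]))
    clean_in_slot("single_exon", sample(400:700, 1L), 1L)
  used_genes <- character(0)
  for (k in seq_len(cc[["known_dup"]])) {
    gid <- sample(setdiff(gene_ids[seq_len(nc1)], used_genes), 1L)
    used_genes <- c(used_genes, gid)
    g <- genes[[gid]]
    add_cand("known_dup", g$chrom, g$strand, g$starts, g$ends)
  }
  for (k in seq_len(cc[["mrna_overlap"]])) {
    gid <- sample(setdiff(gene_ids[seq_len(nc1)], used_genes), 1L)
    used_genes <- c(used_genes, gid)
    g <- genes[[gid]]
    j <- sample(seq_len(length(g$starts) - 1L), 1L)
    add_cand("mrna_overlap", g$chrom, g$strand,
             g$starts[j:(j + 1L)], g$ends[j:(j + 1L)])
  }
  nc_avail <- which(vapply(nc_loci, function(x)
    x$biotype %in% c("tRNA", "rRNA"), logical(1)))
  for (k in seq_len(cc[["ncrna_overlap"]])) {
    loc <- nc_loci[[nc_avail[((k - 1L) %% length(nc_avail)) + 1L]]]
    opp <- ifelse(loc$strand == "+", "-", "+")
    s1 <- loc$start - 60L; e1 <- loc$end + 60L
    add_cand("ncrna_overlap", loc$chrom, opp,
             c(s1, e1 + 700L), c(e1, e1 + 900L))
  }
  for (k in seq_len(cc[["low_expr"]]))
    clean_in_slot("low_expr", sample(300:800, 1L), sample(2:3, 1L))
  for (k in seq_len(cc[["coding_orf"]]))
    clean_in_slot("coding_orf", sample(1200:1500, 1L), 2L)
  for (k in seq_len(cc[["cis_linc"]]))
    clean_in_slot("cis_linc", sample(600:2000, 1L), sample(2:3, 1L))
  ## desert lincs: far side of chr2, > 100 kb from every coding gene
  cursor <- 2700000L
  for (k in seq_len(cc[["desert_linc"]])) {
    nex <- sample(2:3, 1L)
    exl <- .splitLen(sample(800:2000, 1L), nex, min_w = 50L)
    inl <- sample(500:1500, nex - 1L, replace = TRUE)
    ch <- .chainFrom(cursor, exl, inl)
    if (max(ch$ends) > .CHROMS[["chr2"]] - 100000L)
      stop("chromosome capacity insufficient for requested features")
    add_cand("desert_linc", "chr2", sample(c("+", "-"), 1L),
             ch$starts, ch$ends)
    cursor <- max(ch$ends) + 150000L
  }
  anti_genes <- setdiff(gene_ids[seq_len(nc1)], used_genes)
  for (k in seq_len(cc[["antisense"]])) {
    gid <- anti_genes[k]
    if (is.na(gid)) stop("not enough genes for antisense placements")
    used_genes <- c(used_genes, gid)
    g <- genes[[gid]]
    j <- length(g$starts)                   # last exon of the gene
    a_start <- g$starts[j] + floor((g$ends[j] - g$starts[j]) / 3)
    a_end <- g$ends[j] + 200L
    opp <- ifelse(g$strand == "+", "-", "+")
    add_cand("antisense", g$chrom, opp,
             c(a_start, max(g$ends) + 2500L),
             c(a_end, max(g$ends) + 2500L + 299L))
  }

  ## ---- assemble TranscriptSets ---------------------------------------
  gene_rows <- lapply(gene_ids, function(gid) {
    g <- genes[[gid]]
    .txExons(g$chrom, g$strand, g$starts, g$ends,
             sub("GENE", "GTX", gid), gid, "coding")
  })
  known_rows <- c(
    lapply(gene_ids, function(gid) {
      g <- genes[[gid]]
      .txExons(g$chrom, g$strand, g$starts, g$ends,
               sub("GENE", "KNM", gid), gid, "coding")
    }),
    lapply(seq_along(nc_loci), function(i) {
      x <- nc_loci[[i]]
      .txExons(x$chrom, x$strand, x$start, x$end,
               sprintf("KNC_%03d", i), sprintf("KNCG_%03d", i), x$biotype)
    }))
  cand_rows <- lapply(names(cand), function(id) {
    x <- cand[[id]]
    .txExons(x$chrom, x$strand, x$starts, x$ends, id,
             sub("LNC", "LNCG", id), "unknown")
  })
  fate_df <- do.call(rbind, fates)
  if (include_assembled_coding) {
    tc_rows <- lapply(gene_ids, function(gid) {
      g <- genes[[gid]]
      .txExons(g$chrom, g$strand, g$starts, g$ends,
               sub("GENE", "TCONS_C", gid), gid, "unknown")
    })
    cand_rows <- c(tc_rows, cand_rows)
    fate_df <- rbind(
      data.frame(transcript_id = sub("GENE", "TCONS_C", gene_ids),
                 class = "assembled_coding", step = "known_overlap",
                 flank_gene = NA, stringsAsFactors = FALSE),
      fate_df)
  }
  rownames(fate_df) <- NULL
  list(candidates = TranscriptSet(.grFromRows(cand_rows)),
       known = TranscriptSet(.grFromRows(known_rows)),
       coding_genes = TranscriptSet(.grFromRows(gene_rows)),
       chrom_lengths = .CHROMS,
       fates = fate_df)
}

## class sizes implied by a SynthConfig
.classCounts <- function(cfg) {
  n_fail <- round(cfg@n_lncrna * cfg@decoy_fraction)
  base <- n_fail %/% length(.FAIL_CLASSES)
  extra <- n_fail %% length(.FAIL_CLASSES)
  fail <- setNames(rep(base, length(.FAIL_CLASSES)), .FAIL_CLASSES)
  if (extra) fail[seq_len(extra)] <- fail[seq_len(extra)] + 1L
  n_surv <- cfg@n_lncrna - n_fail
  if (n_surv < 4L) stop("too few surviving lncRNAs; lower decoy_fraction")
  n_anti <- max(2L, round(0.15 * n_surv))
  n_desert <- min(12L, max(2L, floor((n_surv - n_anti) / 2)))
  n_cis <- n_surv - n_anti - n_desert
  c(fail, cis_linc = n_cis, desert_linc = n_desert, antisense = n_anti)
}

#' Simulate the study annotation
#'
#' Generates the synthetic genome annotation: multi-exon coding genes on
#' two 5-Mb chromosomes, known structural/small-RNA loci, and lncRNA
#' candidates engineered to exercise every identification filter
#' (too-short, single-exon, known-duplicate, mRNA-overlapping,
#' ncRNA-overlapping, under-expressed and ORF-containing decoys;
#' antisense survivors overlapping coding exons on the opposite strand;
#' intergenic survivors both within 100 kb of genes and in a gene
#' desert). Deterministic given the configuration.
#'
#' @param cfg A [SynthConfig-class].
#' @return List with `candidates`, `known`, `coding_genes`
#'   ([TranscriptSet-class]), `chrom_lengths`, and `fates` (data.frame
#'   `transcript_id`, `class`, `step`: the designed per-filter fate of
#'   every candidate).
#' @export
simulateAnnotation <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  .withSeed(.childSeed(cfg@seed, 1L),
            .synthAnnotation(cfg@n_coding, .classCounts(cfg)))
}
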