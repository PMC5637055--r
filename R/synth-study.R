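## Composition of the full synthetic study and its serialization.

## mature miRNAs: the 17 whitelist names (22 nt, 5' U, mutually free of
## each other's seed anchors) plus synthetic extras
.synthMatures <- function(n_mirna) {
  wl <- hfMirnaWhitelist()
  n_extra <- max(0L, n_mirna - length(wl))
  nms <- c(wl, sprintf("syn-miR-%02d", seq_len(n_extra)))
  seqs <- character(0)
  for (i in seq_along(nms)) {
    len <- if (i <= length(wl)) 22L else sample(20:24, 1L)
    first <- if (i <= length(wl) || runif(1) < 0.7) "U" else
      sample(c("A", "C", "G"), 1L)
    repeat {
      m <- paste0(first, .toRNA(.randSeq(len - 1L)))
      ## no miRNA may carry a seed anchor for another one in its
      ## reverse complement (keeps planted sites specific)
      site <- .revcompDNA(.toDNA(m))
      clash <- any(vapply(seqs, function(o)
        length(seedAnchors(o, site)) > 0 ||
          length(seedAnchors(m, .revcompDNA(.toDNA(o)))) > 0, logical(1)))
      if (!clash && !m %in% seqs) break
    }
    seqs[[nms[i]]] <- m
  }
  seqs
}

## small-RNA tag libraries: exact matures, 3' isomiR trims, junk tags
.synthSrna <- function(matures, cfg) {
  n_lib <- cfg@n_srna_libs_per_group
  libs <- c(sprintf("srna_anagen_%d", seq_len(n_lib)),
            sprintf("srna_telogen_%d", seq_len(n_lib)))
  grp <- rep(c("anagen", "telogen"), each = n_lib)
  mu <- pmin(pmax(stats::rlnorm(length(matures), log(400), 1), 50), 5000)
  n_de <- round(cfg@de_fraction * length(matures))
  de_idx <- if (n_de) sample(seq_along(matures), n_de) else integer(0)
  de_sign <- rep_len(c(1, -1), n_de)
  lfc <- numeric(length(matures))
  lfc[de_idx] <- de_sign * cfg@planted_log2fc
  tags <- list()
  for (l in seq_along(libs)) {
    m <- mu * if (grp[l] == "anagen") 2^lfc else 1
    cnt <- rnbinom(length(matures), mu = m, size = 1 / 0.05)
    rows <- list()
    for (i in seq_along(matures)) {
      if (cnt[i] >= 1)
        rows[[length(rows) + 1L]] <- data.frame(
          seq = matures[[i]], count = cnt[i], stringsAsFactors = FALSE)
      if (cnt[i] >= 7) {
        tr <- substr(matures[[i]], 1L, nchar(matures[[i]]) - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          seq = tr, count = max(1, round(0.15 * cnt[i])),
          stringsAsFactors = FALSE)
      }
    }
    ## unassignable background tags, length mode at 22 nt
    for (k in 1:30) {
      repeat {
        len <- sample(18:30, 1L, prob = stats::dnorm(18:30, 22, 2.2))
        s <- .toRNA(.randSeq(len))
        if (!s %in% matures &&
            !s %in% substr(matures, 1L, nchar(matures) - 1L)) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq = s, count = rpois(1L, 15) + 1, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    agg <- tapply(df$count, df$seq, sum)
    tags[[libs[l]]] <- data.frame(seq = names(agg),
                                  count = as.numeric(agg),
                                  stringsAsFactors = FALSE)
  }
  list(tags = tags, groups = setNames(grp, libs),
       de = data.frame(name = names(matures)[de_idx],
                       log2fc = de_sign * cfg@planted_log2fc,
                       stringsAsFactors = FALSE),
       counts_mu = mu)
}

#' Simulate a complete in-silico hair-follicle study
#'
#' Composes the annotation, sequence, expression, target-site and
#' small-RNA generators into a [StudyBundle-class] with planted ground
#' truth: designed per-filter candidate fates, differentially expressed
#' genes/lncRNAs/miRNAs at the configured fold change, co-expressed
#' lncRNA-mRNA pairs (some placed within 100 kb of each other, giving
#' co-localized and correlated pairs), ceRNA triplets with planted
#' binding sites, miRNA precursor loci nested inside lncRNAs, and a
#' pathway collection containing one gene set enriched for the planted
#' DE genes. Identical configurations give identical bundles.
#'
#' @param cfg A [SynthConfig-class].
#' @return A [StudyBundle-class].
#' @examples
#' \dontrun{
#' bundle <- simulateStudy(synthConfig(seed = 1))
#' bundle
#' }
#' @export
simulateStudy <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  ann <- simulateAnnotation(cfg)
  fate <- setNames(ann$fates$class, ann$fates$transcript_id)
  surv_ids <- ann$fates$transcript_id[ann$fates$step == "survivor"]
  cis_ids <- ann$fates$transcript_id[ann$fates$class == "cis_linc"]
  desert_ids <- ann$fates$transcript_id[ann$fates$class == "desert_linc"]
  anti_ids <- ann$fates$transcript_id[ann$fates$class == "antisense"]
  gene_ids <- unique(geneIds(ann$coding_genes))

  hex <- .withSeed(.childSeed(cfg@seed, 2L), .synthHexamers())
  seqs <- .withSeed(.childSeed(cfg@seed, 2L) + 1L,
                    .synthSequences(ann, hex))

  matures <- .withSeed(.childSeed(cfg@seed, 3L),
                       .synthMatures(cfg@n_mirna))

  ## ---- planted-truth design -----------------------------------------
  if (cfg@n_cerna_triplets > length(desert_ids) + length(anti_ids))
    stop("not enough surviving lncRNAs for the requested triplets")
  trip_lnc <- c(desert_ids, anti_ids)[seq_len(cfg@n_cerna_triplets)]
  wl <- intersect(hfMirnaWhitelist(), names(matures))
  trip_mir <- rep_len(wl, cfg@n_cerna_triplets)
  trip_gene <- gene_ids[seq_len(cfg@n_cerna_triplets)]
  triplets <- data.frame(lncrna_id = trip_lnc, mirna = trip_mir,
                         mrna_id = trip_gene, stringsAsFactors = FALSE)
  ## co-expressed pairs: cis lincs pair with a flanking gene (these
  ## become co-localized AND correlated), remaining pairs use desert
  ## lincs and arbitrary free genes
  flank <- setNames(ann$fates$flank_gene, ann$fates$transcript_id)
  free_lnc <- setdiff(surv_ids, trip_lnc)
  pair_lnc <- head(c(cis_ids, setdiff(free_lnc, cis_ids)),
                   cfg@n_correlated_pairs)
  free_genes <- setdiff(gene_ids, trip_gene)
  pair_gene <- character(length(pair_lnc))
  for (i in seq_along(pair_lnc)) {
    fg <- flank[[pair_lnc[i]]]
    pair_gene[i] <- if (!is.na(fg) && fg %in% free_genes) fg else
      free_genes[1L]
    free_genes <- setdiff(free_genes, pair_gene[i])
  }
  pairs <- data.frame(lncrna_id = pair_lnc, gene_id = pair_gene,
                      cis = !is.na(flank[pair_lnc]) &
                        flank[pair_lnc] == pair_gene,
                      stringsAsFactors = FALSE)

  ## ---- expression ----------------------------------------------------
  lnc_lens <- txLengths(ann$candidates)
  cand_ids <- names(lnc_lens)
  low_ids <- ann$fates$transcript_id[ann$fates$class == "low_expr"]
  n_de_g <- round(cfg@de_fraction * length(gene_ids))
  de_g <- unique(c(trip_gene,
                   head(setdiff(free_genes, pair_gene), max(0L, n_de_g -
                          length(trip_gene)))))
  n_de_l <- round(cfg@de_fraction * length(surv_ids))
  de_l <- unique(c(trip_lnc,
                   head(setdiff(free_lnc, c(pair_lnc, low_ids)),
                        max(0L, n_de_l - length(trip_lnc)))))
  signs_g <- setNames(rep_len(c(1, -1), length(de_g)), de_g)
  signs_g[trip_gene] <- 1
  signs_l <- setNames(rep_len(c(1, -1), length(de_l)), de_l)
  signs_l[trip_lnc] <- 1

  mkFeatures <- function(ids, kind) {
    mean <- pmin(pmax(stats::rlnorm(length(ids),
                                    log(cfg@mean_expression), 1), 50), 5000)
    df <- data.frame(id = ids, mean = mean,
                     dispersion = cfg@dispersion, log2fc = 0,
                     factor_group = NA_character_, factor_sd = 0,
                     stringsAsFactors = FALSE)
    rownames(df) <- ids
    de <- if (kind == "gene") de_g else de_l
    sg <- if (kind == "gene") signs_g else signs_l
    hit <- intersect(ids, de)
    df[hit, "log2fc"] <- sg[hit] * cfg@planted_log2fc
    ## triplet features: high, tight, group-coupled
    for (i in seq_len(nrow(triplets))) {
      tid <- if (kind == "gene") triplets$mrna_id[i] else
        triplets$lncrna_id[i]
      if (tid %in% ids) {
        df[tid, c("mean", "dispersion")] <- list(1000, 0.002)
        df[tid, "factor_group"] <- sprintf("trip_%02d", i)
        df[tid, "factor_sd"] <- 0.2
      }
    }
    ## pure co-expressed pairs: strong shared latent factor
    for (i in seq_len(nrow(pairs))) {
      tid <- if (kind == "gene") pairs$gene_id[i] else pairs$lncrna_id[i]
      if (tid %in% ids) {
        df[tid, c("mean", "dispersion")] <- list(1000, 0.01)
        df[tid, "factor_group"] <- sprintf("pair_%02d", i)
        df[tid, "factor_sd"] <- 2.0
      }
    }
    df
  }
  feats <- .withSeed(.childSeed(cfg@seed, 9L),
                     rbind(mkFeatures(gene_ids, "gene"),
                           mkFeatures(cand_ids, "cand")))
  sim <- simulateExpression(feats, cfg@n_anagen, cfg@n_telogen,
                            seed = .childSeed(cfg@seed, 4L))
  v <- exprValues(sim$counts)
  groups <- sampleGroups(sim$counts)
  lib_sizes <- .withSeed(.childSeed(cfg@seed, 4L) + 1L,
                         setNames(round(runif(ncol(v), 0.95, 1.05) *
                                          cfg@library_size), colnames(v)))
  ## designed sub-threshold candidates: cap counts below the FPKM cutoff
  .withSeed(.childSeed(cfg@seed, 4L) + 2L, {
    for (id in low_ids) {
      cap <- floor(0.5 * lnc_lens[[id]] * lib_sizes / 1e9 - 1e-9)
      v[id, ] <- pmin(rpois(ncol(v), 0.8), pmax(cap, 0))
    }
  })
  mrna_counts <- ExpressionMatrix(v[gene_ids, , drop = FALSE], "count",
                                  groups)
  lnc_counts <- ExpressionMatrix(v[cand_ids, , drop = FALSE], "count",
                                 groups)

  planted <- plantTargetSites(matures, seqs, triplets,
                              seed = .childSeed(cfg@seed, 5L))
  ## planting and scrubbing edit sequences locally; re-assert the
  ## designed noncoding fate of every noncoding-fated candidate
  planted$sequences <- .withSeed(.childSeed(cfg@seed, 5L) + 1L, {
    sq <- planted$sequences
    nonc <- ann$fates$transcript_id[
      !ann$fates$class %in% c("assembled_coding", "coding_orf", "too_short")]
    for (id in nonc) {
      pr <- planted$sites[planted$sites$target_id == id, , drop = FALSE]
      pr <- if (nrow(pr)) data.frame(start = pr$offset,
                                     end = pr$offset +
                                       nchar(matures[pr$mirna]) - 1L)
      else NULL
      sq[[id]] <- .polishNoncoding(sq[[id]], hex$model, matures, pr)
    }
    sq
  })

  srna <- .withSeed(.childSeed(cfg@seed, 6L), .synthSrna(matures, cfg))

  ## ---- miRNA precursors (some nested in surviving lncRNA loci) ------
  prec <- .withSeed(.childSeed(cfg@seed, 7L), {
    spans <- txSpans(ann$candidates)
    host_ids <- head(c(desert_ids, cis_ids), 5L)
    loci <- list(); prec_seq <- character(0); host_map <- list()
    mrec <- data.frame(name = names(matures),
                       mature_seq = unname(matures),
                       precursor_id = sprintf("PRE_%03d",
                                              seq_along(matures)),
                       stringsAsFactors = FALSE)
    cursor <- 2480000L
    for (i in seq_along(matures)) {
      m <- matures[[i]]
      pseq <- paste0(.toRNA(.randSeq(25L)), m, .toRNA(.randSeq(25L)))
      prec_seq[[mrec$precursor_id[i]]] <- pseq
      w <- nchar(pseq)
      if (i <= length(host_ids)) {
        sp <- spans[host_ids[i]]
        st <- start(sp) + 100L
        loci[[i]] <- GRanges(factor(as.character(seqnames(sp)),
                                    levels = names(.CHROMS)),
                             IRanges(st, st + w - 1L),
                             strand = as.character(strand(sp)),
                             precursor_id = mrec$precursor_id[i])
        host_map[[length(host_map) + 1L]] <-
          data.frame(lncrna_id = host_ids[i],
                     precursor_id = mrec$precursor_id[i],
                     stringsAsFactors = FALSE)
      } else {
        loci[[i]] <- GRanges(factor("chr2", levels = names(.CHROMS)),
                             IRanges(cursor, cursor + w - 1L),
                             strand = sample(c("+", "-"), 1L),
                             precursor_id = mrec$precursor_id[i])
        cursor <- cursor + w + 400L
      }
    }
    list(records = mrec, seqs = prec_seq,
         loci = suppressWarnings(do.call(c, loci)),
         hosts = do.call(rbind, host_map))
  })

  ## ---- pathway gene sets ---------------------------------------------
  gsets <- .withSeed(.childSeed(cfg@seed, 8L), {
    sets <- list()
    for (i in 1:19)
      sets[[sprintf("SYN_PATH_%02d", i)]] <-
        sample(gene_ids, sample(15:40, 1L))
    k_de <- min(24L, length(de_g))
    sets[["HF_CYCLING_SYNTHETIC"]] <-
      unique(c(sample(de_g, k_de),
               sample(setdiff(gene_ids, de_g), 30L - k_de)))
    sets
  })

  truth <- list(
    fates = ann$fates,
    survivors = surv_ids,
    classes = setNames(ifelse(surv_ids %in% anti_ids, "antisense",
                              "lincRNA"), surv_ids),
    low_expr = low_ids,
    de_mrna = data.frame(id = de_g, log2fc = signs_g[de_g] *
                           cfg@planted_log2fc, stringsAsFactors = FALSE),
    de_lncrna = data.frame(id = de_l, log2fc = signs_l[de_l] *
                             cfg@planted_log2fc, stringsAsFactors = FALSE),
    de_mirna = srna$de,
    correlated_pairs = pairs,
    triplets = triplets,
    planted_sites = planted$sites,
    lnc_precursors = prec$hosts,
    enriched_set = "HF_CYCLING_SYNTHETIC")

  new("StudyBundle", config = cfg, candidates = ann$candidates,
      known = ann$known, codingGenes = ann$coding_genes,
      sequences = planted$sequences, mrnaCounts = mrna_counts,
      lncrnaCounts = lnc_counts, librarySizes = lib_sizes,
      srnaTags = srna$tags, mirna = prec$records,
      precursorSeqs = prec$seqs, precursorLoci = prec$loci,
      geneSets = gsets, hexamers = hex, chromLengths = ann$chrom_lengths,
      truth = truth)
}

#' Write a study bundle to standard-format files
#'
#' GTF for annotation, FASTA for sequences, TSV for count matrices,
#' groups, library sizes, small-RNA tags and truth tables, GMT for the
#' pathway collection and YAML for the configuration.
#'
#' @param bundle A [StudyBundle-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "StudyBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  writeTranscripts(bundle@candidates, p("candidates.gtf"))
  writeTranscripts(bundle@known, p("known.gtf"))
  writeTranscripts(bundle@codingGenes, p("coding_genes.gtf"))
  writeFastaSeqs(bundle@sequences, p("transcripts.fa"))
  writeFastaSeqs(setNames(bundle@mirna$mature_seq, bundle@mirna$name),
                 p("mirna_mature.fa"))
  writeFastaSeqs(bundle@precursorSeqs, p("mirna_precursors.fa"))
  writeExpressionTable(bundle@mrnaCounts, p("mrna_counts.tsv"))
  writeExpressionTable(bundle@lncrnaCounts, p("lncrna_counts.tsv"))
  g <- sampleGroups(bundle@mrnaCounts)
  write.table(data.frame(sample = names(g), group = unname(g)),
              p("groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = names(bundle@librarySizes),
                         total_fragments = unname(bundle@librarySizes)),
              p("library_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (lib in names(bundle@srnaTags))
    write.table(bundle@srnaTags[[lib]], p(paste0(lib, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  loci <- bundle@precursorLoci
  write.table(data.frame(precursor_id = mcols(loci)$precursor_id,
                         chrom = as.character(seqnames(loci)),
                         start = start(loci), end = end(loci),
                         strand = as.character(strand(loci))),
              p("precursor_loci.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeGeneSets(bundle@geneSets, p("gene_sets.gmt"))
  for (nm in c("fates", "de_mrna", "de_lncrna", "de_mirna",
               "correlated_pairs", "triplets", "planted_sites"))
    write.table(bundle@truth[[nm]], p(paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bundle@config
  cfg_list <- lapply(setNames(slotNames(cfg), slotNames(cfg)),
                     function(s) methods::slot(cfg, s))
  writeLines(yaml::as.yaml(cfg_list), p("config.yaml"))
  invisible(dir)
}

#' Fixed 50-transcript filter fixture with designed per-filter fates
#'
#' A compact instance of the annotation/sequence generators: exactly 50
#' lncRNA candidates of which 5 fail the length filter, 5 the exon
#' filter, 9 the known-overlap filter (3 exon-chain duplicates, 3
#' mRNA-overlapping, 3 ncRNA-overlapping), 6 the expression filter and
#' 5 the coding-potential filter; the 20 designed survivors split into
#' 15 lincRNAs and 5 antisense lncRNAs. The expected audit table is
#' included.
#'
#' @param seed Integer seed.
#' @return List with `candidates`, `known`, `coding_genes`, `fpkm`,
#'   `sequences`, `hexamers` and `truth` (with `fates`, `survivors`,
#'   `classes` and `expected_audit`).
#' @export
simulateFilterFixture <- function(seed = 2024L) {
  counts <- c(too_short = 5L, single_exon = 5L, known_dup = 3L,
              mrna_overlap = 3L, ncrna_overlap = 3L, low_expr = 6L,
              coding_orf = 5L, cis_linc = 8L, desert_linc = 7L,
              antisense = 5L)
  ann <- .withSeed(.childSeed(seed, 1L),
                   .synthAnnotation(30L, counts,
                                    include_assembled_coding = FALSE))
  hex <- .withSeed(.childSeed(seed, 2L), .synthHexamers())
  seqs <- .withSeed(.childSeed(seed, 2L) + 1L, .synthSequences(ann, hex))
  ids <- transcriptIds(ann$candidates)
  low <- ann$fates$transcript_id[ann$fates$class == "low_expr"]
  fpkm <- .withSeed(.childSeed(seed, 3L), {
    m <- matrix(runif(length(ids) * 6L, 2, 80), length(ids), 6L,
                dimnames = list(ids, c(sprintf("anagen_%d", 1:3),
                                       sprintf("telogen_%d", 1:3))))
    m[low, ] <- runif(length(low) * 6L, 0.05, 0.45)
    m
  })
  groups <- setNames(rep(c("anagen", "telogen"), each = 3L),
                     colnames(fpkm))
  surv <- ann$fates$transcript_id[ann$fates$step == "survivor"]
  anti <- ann$fates$transcript_id[ann$fates$class == "antisense"]
  n <- length(ids)
  audit <- data.frame(
    step = c("min_length", "min_exons", "known_overlap",
             "min_expression", "coding_potential"),
    n_in = c(n, n - 5L, n - 10L, n - 19L, n - 25L),
    n_out = c(n - 5L, n - 10L, n - 19L, n - 25L, n - 30L),
    stringsAsFactors = FALSE)
  list(candidates = ann$candidates, known = ann$known,
       coding_genes = ann$coding_genes,
       fpkm = ExpressionMatrix(fpkm, "FPKM", groups),
       sequences = seqs[ids], hexamers = hex,
       truth = list(fates = ann$fates, survivors = surv,
                    classes = setNames(ifelse(surv %in% anti, "antisense",
                                              "lincRNA"), surv),
                    expected_audit = audit))
}
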