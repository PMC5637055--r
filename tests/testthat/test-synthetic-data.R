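test_that("identical configurations give byte-identical bundles", {
  cfg <- synthConfig(seed = 5, n_coding = 40L, n_lncrna = 30L,
                     n_mirna = 20L, n_correlated_pairs = 4L,
                     n_cerna_triplets = 3L)
  b1 <- simulateStudy(cfg)
  b2 <- simulateStudy(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudyBundle(b1, d1)
  writeStudyBundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("designed filter-failure classes have the sizes they were dealt", {
  fx <- simulateFilterFixture(seed = 77)
  tab <- table(fx$truth$fates$class)
  expect_equal(tab[["too_short"]], 5L)
  expect_equal(tab[["single_exon"]], 5L)
  expect_equal(tab[["low_expr"]], 6L)
  expect_equal(tab[["coding_orf"]], 5L)
  short_ids <- fx$truth$fates$transcript_id[
    fx$truth$fates$class == "too_short"]
  expect_true(all(txLengths(fx$candidates)[short_ids] < 200))
})

test_that("each designed decoy fails exactly its intended filter", {
  fx <- simulateFilterFixture(seed = 78)
  fates <- fx$truth$fates
  len <- txLengths(fx$candidates)
  nex <- table(S4Vectors::mcols(exonRanges(fx$candidates))$transcript_id)
  known_surv <- transcriptIds(
    suppressWarnings(knownOverlapFilter(fx$candidates, fx$known)$survivors))
  expr_surv <- transcriptIds(
    expressionFilter(fx$candidates, fx$fpkm)$survivors)
  passes <- function(id, step) {
    switch(step,
      min_length = len[[id]] >= 200,
      min_exons = as.numeric(nex[[id]]) >= 2,
      known_overlap = id %in% known_surv,
      min_expression = id %in% expr_surv,
      coding_potential = nchar(fx$sequences[[id]]) < 200 ||
        codingPotentialScore(fx$sequences[[id]],
                             fx$hexamers$model)$consensus == "noncoding")
  }
  steps <- c("min_length", "min_exons", "known_overlap",
             "min_expression", "coding_potential")
  for (i in seq_len(nrow(fates))) {
    id <- fates$transcript_id[i]
    for (s in steps) {
      ## coding potential is undefined below 200 nt
      if (s == "coding_potential" && len[[id]] < 200) next
      expected <- if (fates$step[i] == "survivor") TRUE else
        s != fates$step[i]
      expect_equal(passes(id, s), expected,
                   label = paste(id, fates$class[i], s))
    }
  }
})

test_that("antisense placements overlap coding exons on the opposite strand", {
  fx <- simulateFilterFixture(seed = 79)
  anti <- fx$truth$fates$transcript_id[
    fx$truth$fates$class == "antisense"]
  cod <- exonRanges(fx$coding_genes)
  cod_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cod)),
                       strand = as.character(GenomicRanges::strand(cod)),
                       start = IRanges::start(cod),
                       end = IRanges::end(cod))
  for (id in anti) {
    ex <- exonRanges(fx$candidates[id])
    ex_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                        start = IRanges::start(ex),
                        end = IRanges::end(ex))
    strand <- as.character(GenomicRanges::strand(ex))[1]
    expect_true(bruteExonOverlap(
      ex_df, cod_df[cod_df$strand != strand &
                      cod_df$chrom == ex_df$chrom[1], , drop = FALSE]),
      label = id)
  }
})

test_that("zero dispersion degenerates to Poisson counts", {
  feats <- data.frame(id = sprintf("f%04d", 1:5000), mean = 100,
                      dispersion = 0)
  sim <- simulateExpression(feats, seed = 81)
  v <- exprValues(sim$counts)
  ratio <- mean(apply(v, 1, var) / rowMeans(v))
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
  expect_equal(nrow(sim$truth$de), 0L)
})

test_that("null p-values from the DE pipeline are approximately uniform", {
  feats <- data.frame(id = sprintf("f%04d", 1:5000), mean = 200,
                      dispersion = 0.05)
  sim <- simulateExpression(feats, seed = 82)
  model <- new("NBModel",
               dispersion = setNames(rep(0.05, 5000), feats$id),
               sizeFactors = sizeFactorsMedianRatio(exprValues(sim$counts)),
               flagged = character(0))
  res <- nbWaldTest(sim$counts, model, moderate = FALSE)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("planted 8mer sites pass the scanner and decoys carry none", {
  b <- sharedStudy()
  mat <- setNames(b@mirna$mature_seq, b@mirna$name)
  sites <- b@truth$planted_sites
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    expect_equal(seedClass(mat[[s$mirna]],
                           b@sequences[[s$target_id]], s$seed_start),
                 "8mer", label = paste(s$mirna, s$target_id))
    hits <- scanMirnaSites(mat[[s$mirna]], b@sequences[[s$target_id]],
                           mirna = s$mirna, target_id = s$target_id)
    expect_true(any(hits$seed_start == s$seed_start))
  }
  ## decoys: survivors and DE genes without a planted site have no
  ## passing site for any whitelist miRNA
  wl <- intersect(hfMirnaWhitelist(), names(mat))
  decoy_ids <- setdiff(c(b@truth$survivors, b@truth$de_mrna$id),
                       unique(sites$target_id))
  set.seed(83)
  for (id in sample(decoy_ids, 12)) {
    for (m in sample(wl, 6))
      expect_equal(nrow(scanMirnaSites(mat[[m]], b@sequences[[id]])), 0L,
                   label = paste(m, id))
  }
})

test_that("the default bundle matches the emulated study design", {
  b <- sharedStudy()
  expect_equal(ncol(b@mrnaCounts), 6L)
  expect_equal(unname(table(sampleGroups(b@mrnaCounts))[c("anagen", "telogen")]),
               c(3L, 3L), ignore_attr = TRUE)
  expect_length(b@srnaTags, 4L)
  expect_equal(nrow(b@truth$triplets), 10L)
  expect_true(all(b@truth$triplets$lncrna_id %in% b@truth$survivors))
})

test_that("a written bundle loads back through the io module cleanly", {
  b <- sharedStudy()
  d <- withr::local_tempdir()
  writeStudyBundle(b, d)
  cand <- readTranscripts(file.path(d, "candidates.gtf"))
  expect_equal(length(cand), length(b@candidates))
  expect_equal(sort(unname(txLengths(cand))),
               sort(unname(txLengths(b@candidates))))
  known <- readTranscripts(file.path(d, "known.gtf"))
  expect_setequal(unique(biotypes(known)),
                  unique(biotypes(b@known)))
  seqs <- readFastaSeqs(file.path(d, "transcripts.fa"))
  expect_identical(seqs[sort(names(seqs))],
                   b@sequences[sort(names(b@sequences))])
  mat <- readFastaSeqs(file.path(d, "mirna_mature.fa"), rna = TRUE)
  expect_identical(unname(mat[b@mirna$name]), b@mirna$mature_seq)
  g <- sampleGroups(b@mrnaCounts)
  cm <- readExpressionTable(file.path(d, "mrna_counts.tsv"), "count", g)
  expect_equal(exprValues(cm), exprValues(b@mrnaCounts))
  sets <- readGeneSets(file.path(d, "gene_sets.gmt"))
  expect_identical(sets, b@geneSets)
})

test_that("precursor loci nested in lncRNAs are recovered", {
  b <- sharedStudy()
  surv <- b@candidates[b@truth$survivors]
  got <- precursorOverlap(surv, b@precursorLoci)
  want <- b@truth$lnc_precursors
  expect_setequal(paste(got$lncrna_id, got$precursor_id),
                  paste(want$lncrna_id, want$precursor_id))
  ## matures are substrings of their precursors
  for (i in seq_len(nrow(b@mirna)))
    expect_true(grepl(b@mirna$mature_seq[i],
                      b@precursorSeqs[[b@mirna$precursor_id[i]]],
                      fixed = TRUE))
})

test_that("small-RNA libraries carry the planted length mode and base bias", {
  b <- sharedStudy()
  all_tags <- do.call(rbind, b@srnaTags)
  ld <- lengthDistribution(all_tags)
  expect_equal(names(ld)[which.max(ld)], "22")
  rec <- mirnaRecords(b@mirna$name, b@mirna$mature_seq)
  asg <- assignTags(b@srnaTags[[1]], rec)
  expect_equal(sum(asg$counts) +
                 sum(asg$assignments$count[
                   is.na(asg$assignments$assigned_mirna)]),
               sum(b@srnaTags[[1]]$count))
  assigned <- asg$assignments[!is.na(asg$assignments$assigned_mirna), ]
  bias <- firstBaseBias(assigned)
  expect_gt(bias["22", "U"], 0.5)
})
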