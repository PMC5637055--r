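test_that("structural filter applies the printed boundary semantics", {
  ts <- makeTx(
    list(chrom = "chr1", strand = "+", starts = c(100, 300),
         ends = c(170, 378), id = "short2ex"),        # 150 nt, 2 exons
    list(chrom = "chr1", strand = "+", starts = 1000,
         ends = 5999, id = "long1ex"),                # 5000 nt, 1 exon
    list(chrom = "chr1", strand = "+", starts = c(10000, 11000),
         ends = c(10099, 11099), id = "exactly200"))  # 200 nt, 2 exons
  out <- structuralFilter(ts)
  expect_equal(transcriptIds(out$survivors), "exactly200")
  expect_equal(out$removed$min_length, "short2ex")
  expect_equal(out$removed$min_exons, "long1ex")
  expect_equal(out$audit$n_in, c(3, 2))
  expect_equal(out$audit$n_out, c(2, 1))
})

test_that("known-overlap filter implements the three removal rules", {
  known <- makeTx(
    list(chrom = "chr1", strand = "+", starts = c(1000, 3000),
         ends = c(1400, 3400), id = "KNM1", gene = "kg1",
         biotype = "coding"),
    list(chrom = "chr1", strand = "-", starts = 50000,
         ends = 50080, id = "KNT1", gene = "kg2", biotype = "tRNA"))
  cand <- makeTx(
    ## (a) identical exon chain, same strand
    list(chrom = "chr1", strand = "+", starts = c(1000, 3000),
         ends = c(1400, 3400), id = "dup"),
    ## (b) fully covered by the known mRNA, same strand
    list(chrom = "chr1", strand = "+", starts = c(1100, 3100),
         ends = c(1300, 3300), id = "covered"),
    ## (b counter-case) same strand but only ~25% covered
    list(chrom = "chr1", strand = "+", starts = c(1200, 9000),
         ends = c(1400, 9600), id = "quarter"),
    ## (c) opposite-strand overlap with a tRNA locus
    list(chrom = "chr1", strand = "+", starts = c(50040, 51000),
         ends = c(50120, 51200), id = "trna_hit"),
    ## clean
    list(chrom = "chr1", strand = "+", starts = c(80000, 81000),
         ends = c(80200, 81200), id = "clean"))
  out <- knownOverlapFilter(cand, known)
  expect_setequal(transcriptIds(out$survivors), c("quarter", "clean"))
  expect_setequal(out$removed$known_overlap,
                  c("dup", "covered", "trna_hit"))
  empty <- makeTx(list(chrom = "chr1", strand = "+", starts = 1,
                       ends = 100, id = "nothing"))[0]
  expect_warning(out2 <- knownOverlapFilter(cand, empty), "empty")
  expect_equal(length(out2$survivors), length(cand))
})

test_that("expression filter keeps max-FPKM >= 0.5 with exact boundary", {
  ts <- makeTx(
    list(chrom = "chr1", strand = "+", starts = c(1, 300),
         ends = c(150, 500), id = "low"),
    list(chrom = "chr1", strand = "+", starts = c(1000, 1300),
         ends = c(1150, 1500), id = "spike"),
    list(chrom = "chr1", strand = "+", starts = c(2000, 2300),
         ends = c(2150, 2500), id = "boundary"))
  g <- c(s1 = "anagen", s2 = "anagen", s3 = "telogen")
  m <- rbind(low = c(0.1, 0.2, 0.3), spike = c(0.6, 0, 0),
             boundary = c(0.5, 0.1, 0.1))
  colnames(m) <- names(g)
  fpkm <- ExpressionMatrix(m, "FPKM", g)
  out <- expressionFilter(ts, fpkm)
  expect_setequal(transcriptIds(out$survivors), c("spike", "boundary"))
  strict <- expressionFilter(ts, fpkm, aggregate = "all")
  expect_equal(length(strict$survivors), 0L)
  expect_error(expressionFilter(makeTx(
    list(chrom = "chr1", strand = "+", starts = 1, ends = 300,
         id = "missing")), fpkm), "missing")
})

test_that("coding-potential consensus combines the three detectors", {
  hex <- sharedHexamers()
  set.seed(41)
  coding <- ceRNAcycle:::.codingSeq(600)     # ORF spans ~70%
  res <- codingPotentialScore(coding, hex$model)
  expect_equal(res$consensus, "coding")
  expect_gt(res$orf_fraction, 0.35)
  nc <- ceRNAcycle:::.noncodingSeq(600, hex$model)
  res2 <- codingPotentialScore(nc, hex$model)
  expect_equal(res2$consensus, "noncoding")
  expect_true(all(res2$detector_calls == "noncoding"))
  expect_lt(res2$hexamer_llr, 0)
  expect_error(codingPotentialScore(ceRNAcycle:::.randSeq(150),
                                    hex$model), "200")
})

test_that("classification separates lincRNA from antisense", {
  coding <- makeTx(list(chrom = "chr1", strand = "+",
                        starts = c(1000, 2000), ends = c(1500, 2400),
                        id = "cod1", gene = "g1", biotype = "coding"))
  lnc <- makeTx(
    list(chrom = "chr1", strand = "-", starts = c(1200, 3000),
         ends = c(1400, 3300), id = "anti"),
    list(chrom = "chr1", strand = "-", starts = c(900000, 901000),
         ends = c(900300, 901400), id = "desert"))
  cls <- classifyLncRNA(lnc, coding)
  expect_equal(cls[["anti"]], "antisense")
  expect_equal(cls[["desert"]], "lincRNA")
  bad <- makeTx(list(chrom = "chr1", strand = "+",
                     starts = c(1200, 3000), ends = c(1400, 3300),
                     id = "same_strand"))
  expect_error(classifyLncRNA(bad, coding), "same-strand")
})

test_that("classification agrees with a brute-force strand-overlap oracle", {
  set.seed(43)
  g <- 30
  gene_ex <- data.frame(chrom = sample(c("chr1", "chr2"), g, TRUE),
                        strand = sample(c("+", "-"), g, TRUE),
                        start = sample(1:2000000, g))
  gene_ex$end <- gene_ex$start + sample(200:2000, g, TRUE)
  coding <- do.call(makeTx, lapply(seq_len(g), function(i)
    list(chrom = gene_ex$chrom[i], strand = gene_ex$strand[i],
         starts = gene_ex$start[i], ends = gene_ex$end[i],
         id = sprintf("cod%02d", i), gene = sprintf("cg%02d", i),
         biotype = "coding")))
  n_ok <- 0
  for (i in 1:300) {
    chrom <- sample(c("chr1", "chr2"), 1)
    strand <- sample(c("+", "-"), 1)
    st <- sample(1:2000000, 1)
    en <- st + sample(200:3000, 1)
    same <- bruteExonOverlap(
      data.frame(chrom = chrom, start = st, end = en),
      gene_ex[gene_ex$strand == strand & gene_ex$chrom == chrom, ,
              drop = FALSE])
    if (same) next  # contradiction case, covered above
    opp <- bruteExonOverlap(
      data.frame(chrom = chrom, start = st, end = en),
      gene_ex[gene_ex$strand != strand & gene_ex$chrom == chrom, ,
              drop = FALSE])
    lnc <- makeTx(list(chrom = chrom, strand = strand, starts = st,
                       ends = en, id = "q"))
    got <- classifyLncRNA(lnc, coding)[["q"]]
    expect_equal(got, if (opp) "antisense" else "lincRNA")
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 200)
})

test_that("the full pipeline matches designed fates and is order-invariant", {
  fx <- simulateFilterFixture(seed = 515)
  res <- runLncRNAPipeline(fx$candidates, fx$known, fx$fpkm,
                           fx$sequences, fx$hexamers$model)
  expect_setequal(transcriptIds(res$lncrnas), fx$truth$survivors)
  expect_equal(res$audit[, c("step", "n_in", "n_out")],
               fx$truth$expected_audit, ignore_attr = TRUE)
  expect_equal(res$classes[names(fx$truth$classes)], fx$truth$classes)
  ## classification partitions survivors
  expect_true(all(res$classes %in% c("lincRNA", "antisense")))
  expect_setequal(names(res$classes), transcriptIds(res$lncrnas))

  ## order-invariance: filters are pure per-transcript predicates
  passStructural <- function(ts) {
    s <- structuralFilter(ts)
    transcriptIds(s$survivors)
  }
  ids <- transcriptIds(fx$candidates)
  len <- txLengths(fx$candidates)
  nex <- table(S4Vectors::mcols(exonRanges(fx$candidates))$transcript_id)
  p_len <- ids[len[ids] >= 200]
  p_ex <- ids[as.numeric(nex[ids]) >= 2]
  p_known <- transcriptIds(
    knownOverlapFilter(fx$candidates, fx$known)$survivors)
  p_expr <- transcriptIds(expressionFilter(fx$candidates, fx$fpkm)$survivors)
  p_cp <- ids[vapply(ids, function(id) {
    s <- fx$sequences[[id]]
    nchar(s) < 200 ||
      codingPotentialScore(s, fx$hexamers$model)$consensus == "noncoding"
  }, logical(1))]
  ref <- Reduce(intersect, list(p_len, p_ex, p_known, p_expr, p_cp))
  expect_setequal(ref, fx$truth$survivors)
  ## monotonicity: survivors are a subset of every prefix's survivors
  expect_true(all(fx$truth$survivors %in% p_len))
  expect_true(all(fx$truth$survivors %in% p_known))
})

test_that("an all-coding candidate set yields no lncRNAs", {
  fx <- simulateFilterFixture(seed = 516)
  known_ids <- transcriptIds(fx$known)
  coding_known <- fx$known[known_ids[startsWith(known_ids, "KNM")]]
  ex <- exonRanges(coding_known)
  S4Vectors::mcols(ex)$transcript_id <-
    sub("KNM", "CAND", S4Vectors::mcols(ex)$transcript_id)
  S4Vectors::mcols(ex)$biotype <- "unknown"
  cands <- TranscriptSet(ex)
  g <- sampleGroups(fx$fpkm)
  fpkm <- ExpressionMatrix(
    matrix(10, length(cands), 6,
           dimnames = list(transcriptIds(cands), names(g))), "FPKM", g)
  seqs <- setNames(vapply(txLengths(cands), function(l)
    ceRNAcycle:::.codingSeq(max(200, l)), ""), transcriptIds(cands))
  res <- runLncRNAPipeline(cands, fx$known, fpkm, seqs,
                           fx$hexamers$model)
  expect_equal(length(res$lncrnas), 0L)
})
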