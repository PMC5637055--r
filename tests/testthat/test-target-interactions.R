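spanTx <- function(id, chrom, start, end, strand = "+", gene = id)
  list(chrom = chrom, strand = strand, starts = start, ends = end,
       id = id, gene = gene, biotype = "unknown")

test_that("cis window arithmetic follows the coordinate-gap rule", {
  lnc <- makeTx(spanTx("lnc1", "chr1", 200000, 210000))
  genes <- makeTx(spanTx("g1", "chr1", 105000, 110000, gene = "geneA"),
                  spanTx("g2", "chr1", 90000, 95000, gene = "geneB"),
                  spanTx("g3", "chr2", 200000, 210000, gene = "geneC"))
  out <- cisTargets(lnc, genes)
  expect_equal(out$gene_id, "geneA")       # gap 90 kb in; 105 kb out
  expect_equal(abs(out$distance), 90000)
  expect_equal(out$side, "upstream")       # gene left of a + lncRNA
})

test_that("flipping the lncRNA strand flips distance sign, not membership", {
  genes <- makeTx(spanTx("g1", "chr1", 50000, 55000, gene = "gA"),
                  spanTx("g2", "chr1", 300000, 310000, gene = "gB"))
  plus <- cisTargets(makeTx(spanTx("L", "chr1", 150000, 160000, "+")), genes)
  minus <- cisTargets(makeTx(spanTx("L", "chr1", 150000, 160000, "-")), genes)
  expect_setequal(plus$gene_id, minus$gene_id)
  m <- merge(plus, minus, by = "gene_id")
  expect_equal(m$distance.x, -m$distance.y)
})

test_that("cis pairs agree with a brute-force scan on random placements", {
  set.seed(9)
  n <- 400
  lnc_df <- data.frame(id = sprintf("L%03d", 1:n),
                       chrom = sample(c("chr1", "chr2"), n, TRUE),
                       start = sample(1:4800000, n))
  lnc_df$end <- lnc_df$start + sample(500:20000, n, TRUE)
  g <- 50
  gene_df <- data.frame(id = sprintf("G%02d", 1:g),
                        chrom = sample(c("chr1", "chr2"), g, TRUE),
                        start = sample(1:4800000, g))
  gene_df$end <- gene_df$start + sample(2000:30000, g, TRUE)
  lnc <- do.call(makeTx, lapply(seq_len(n), function(i)
    spanTx(lnc_df$id[i], lnc_df$chrom[i], lnc_df$start[i], lnc_df$end[i])))
  genes <- do.call(makeTx, lapply(seq_len(g), function(i)
    spanTx(gene_df$id[i], gene_df$chrom[i], gene_df$start[i],
           gene_df$end[i], gene = gene_df$id[i])))
  got <- cisTargets(lnc, genes)
  expect_setequal(paste(got$lncrna_id, got$gene_id),
                  bruteCisPairs(lnc_df, gene_df, 100000))
})

test_that("pearsonCor matches closed-form values and rejects bad input", {
  expect_equal(pearsonCor(1:3, c(2, 4, 6)), 1)
  expect_equal(pearsonCor(1:3, c(6, 4, 2)), -1)
  expect_equal(pearsonCor(1:3, c(1, 3, 2)), 0.5)
  expect_error(pearsonCor(1:3, c(2, 2, 2)), "constant")
  expect_error(pearsonCor(1:2, 1:2), "3 observations")
})

test_that("trans edges use inclusive thresholds and survive permutation", {
  g <- setNames(rep(c("anagen", "telogen"), each = 3),
                c(sprintf("a%d", 1:3), sprintf("t%d", 1:3)))
  x <- c(1, 2, 3, 4, 5, 6)
  ## y has cor(x, y) exactly 1; scale to engineer r = 1 >= 0.95
  lnc <- ExpressionMatrix(matrix(x, 1, 6,
                                 dimnames = list("L", names(g))), "FPKM", g)
  mr <- ExpressionMatrix(matrix(c(2 * x, rev(x)), 2, 6, byrow = TRUE,
                                dimnames = list(c("up", "down"), names(g))),
                         "FPKM", g)
  two <- transTargets(lnc, mr)
  expect_setequal(two$gene_id, c("up", "down"))
  pos <- transTargets(lnc, mr, mode = "positive")
  expect_equal(pos$gene_id, "up")
  perm <- sample(names(g))
  two_p <- transTargets(
    ExpressionMatrix(exprValues(lnc)[, perm, drop = FALSE], "FPKM", g),
    ExpressionMatrix(exprValues(mr)[, perm, drop = FALSE], "FPKM", g))
  expect_equal(two_p[order(two_p$gene_id), c("gene_id", "r")],
               two[order(two$gene_id), c("gene_id", "r")],
               ignore_attr = TRUE)
})

test_that("null feature pairs rarely reach the correlation threshold", {
  set.seed(12)
  g <- setNames(rep(c("anagen", "telogen"), each = 3),
                c(sprintf("a%d", 1:3), sprintf("t%d", 1:3)))
  lv <- matrix(rnbinom(100 * 6, mu = 300, size = 20), 100, 6,
               dimnames = list(sprintf("L%d", 1:100), names(g)))
  mv <- matrix(rnbinom(100 * 6, mu = 300, size = 20), 100, 6,
               dimnames = list(sprintf("G%d", 1:100), names(g)))
  ed <- transTargets(ExpressionMatrix(lv, "FPKM", g),
                     ExpressionMatrix(mv, "FPKM", g))
  expect_lt(nrow(ed) / 10000, 0.02)
})

test_that("planted co-expressed pairs reach r >= 0.95 in most replicates", {
  n_rep <- 400
  feats <- do.call(rbind, lapply(seq_len(n_rep), function(i)
    data.frame(id = sprintf(c("L%03d", "G%03d"), i), mean = 1000,
               dispersion = 0.01, log2fc = 0,
               factor_group = sprintf("fg%03d", i), factor_sd = 2.0)))
  sim <- simulateExpression(feats, seed = 31)
  v <- exprValues(sim$counts)
  rs <- vapply(seq_len(n_rep), function(i)
    suppressWarnings(cor(v[2 * i - 1, ], v[2 * i, ])), numeric(1))
  expect_gte(median(rs, na.rm = TRUE), 0.95)
  expect_gte(mean(rs >= 0.95, na.rm = TRUE), 0.95)
})

test_that("co-localized + correlated pairs are the exact set intersection", {
  cis <- data.frame(lncrna_id = c("a", "b", "c"),
                    gene_id = c("g1", "g2", "g3"),
                    distance = c(0, 100, -5), side = "overlapping")
  tr <- data.frame(lncrna_id = c("b", "c", "d"),
                   gene_id = c("g2", "gX", "g4"),
                   r = c(0.99, 0.97, 0.96), n_samples = 6)
  both <- colocalizedCorrelatedPairs(cis, tr)
  expect_equal(nrow(both), 1L)
  expect_equal(both$lncrna_id, "b")
  expect_true(all(c("distance", "r") %in% colnames(both)))
  set.seed(13)
  c2 <- data.frame(lncrna_id = sample(letters, 200, TRUE),
                   gene_id = sample(LETTERS, 200, TRUE),
                   distance = 1, side = "upstream")
  t2 <- data.frame(lncrna_id = sample(letters, 200, TRUE),
                   gene_id = sample(LETTERS, 200, TRUE),
                   r = 0.99, n_samples = 6)
  c2 <- c2[!duplicated(c2[1:2]), ]; t2 <- t2[!duplicated(t2[1:2]), ]
  got <- colocalizedCorrelatedPairs(c2, t2)
  want <- intersect(paste(c2$lncrna_id, c2$gene_id),
                    paste(t2$lncrna_id, t2$gene_id))
  expect_setequal(paste(got$lncrna_id, got$gene_id), want)
})

test_that("precursor containment agrees with a brute-force oracle", {
  lnc <- makeTx(spanTx("L1", "chr1", 5000, 7000, "+"))
  prec <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(5100, 5100), c(5180, 5180)),
    strand = c("+", "-"), precursor_id = c("p_same", "p_opp"))
  out <- precursorOverlap(lnc, prec)
  expect_equal(out$precursor_id, "p_same")

  set.seed(14)
  n <- 1000
  pd <- data.frame(id = sprintf("p%04d", 1:n),
                   chrom = sample(c("chr1", "chr2"), n, TRUE),
                   strand = sample(c("+", "-"), n, TRUE),
                   start = sample(1:99000, n, TRUE))
  pd$end <- pd$start + 80
  sp <- data.frame(id = sprintf("L%03d", 1:80),
                   chrom = sample(c("chr1", "chr2"), 80, TRUE),
                   strand = sample(c("+", "-"), 80, TRUE),
                   start = sample(1:95000, 80, TRUE))
  sp$end <- sp$start + sample(500:5000, 80, TRUE)
  lncs <- do.call(makeTx, lapply(seq_len(nrow(sp)), function(i)
    spanTx(sp$id[i], sp$chrom[i], sp$start[i], sp$end[i], sp$strand[i])))
  pg <- GenomicRanges::GRanges(pd$chrom, IRanges::IRanges(pd$start, pd$end),
                               strand = pd$strand, precursor_id = pd$id)
  got <- precursorOverlap(lncs, pg)
  expect_setequal(paste(got$lncrna_id, got$precursor_id),
                  bruteContained(pd, sp))
})

test_that("scanner reports a maximal passing site on a perfect duplex", {
  set.seed(15)
  mir <- paste0("U", randomRNA(21))
  site <- ceRNAcycle:::.revcompDNA(chartr("U", "T", mir))
  target <- paste0(randomSeq(40), site, randomSeq(40))
  hits <- scanMirnaSites(mir, target)
  expect_equal(nrow(hits), 1L)
  ## 6 doubled seed pairs + doubled position 8 + position 1 + 14 matches
  expect_equal(hits$align_score, 6 * 10 + 10 + 5 + 14 * 5)
  expect_equal(hits$seed, "8mer")
  expect_lt(hits$energy_kcal_mol, -1)
  expect_equal(hits$target_start, 41L)
  expect_equal(hits$target_end, 62L)
})

test_that("targets without a seed-complementary window yield no sites", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_equal(nrow(scanMirnaSites(mir, strrep("A", 100))), 0L)
  expect_error(scanMirnaSites(mir, "ACGTXXACGT"), "non-IUPAC")
  expect_error(scanMirnaSites("UGAG", strrep("A", 50)), "\\[18, 26\\]")
})

test_that("phase-1 anchors match exhaustive window enumeration", {
  set.seed(16)
  for (i in 1:200) {
    mir <- randomRNA(sample(18:26, 1))
    target <- randomSeq(sample(60:400, 1))
    expect_identical(seedAnchors(mir, target), bruteAnchors(mir, target))
  }
})

test_that("mutating a Watson-Crick pair never increases the site score", {
  set.seed(17)
  mir <- paste0("U", randomRNA(21))
  site <- ceRNAcycle:::.revcompDNA(chartr("U", "T", mir))
  target <- paste0(randomSeq(30), site, randomSeq(30))
  base <- scanMirnaSites(mir, target,
                         params = scanParams(score_min = 0,
                                             energy_max = 100))
  full <- base$align_score[1]
  for (k in c(31, 35, 40, 45, 52)) {   # positions inside the site
    old <- substr(target, k, k)
    for (repl in setdiff(c("A", "C", "G", "T"), old)) {
      mut <- paste0(substr(target, 1, k - 1), repl,
                    substr(target, k + 1, nchar(target)))
      hits <- scanMirnaSites(mir, mut,
                             params = scanParams(score_min = 0,
                                                 energy_max = 100))
      if (nrow(hits)) expect_lte(max(hits$align_score), full)
    }
  }
})

test_that("seed classes follow the canonical TargetScan taxonomy", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  seed7 <- ceRNAcycle:::.revcompDNA(chartr("U", "T", substr(mir, 2, 8)))
  ## target layout: [pad 10] [m8'] [m7'..m2'] [base opposite pos 1] [pad]
  ## so the 6-mer opposite positions 2-7 starts at index 12
  t8 <- paste0(randomSeq(10), seed7, "A", randomSeq(10))
  expect_equal(seedClass(mir, t8, 12), "8mer")
  t7m8 <- paste0(randomSeq(10), seed7, "C", randomSeq(10))
  expect_equal(seedClass(mir, t7m8, 12), "7mer-m8")
  seed6 <- substr(seed7, 2, 7)
  t7a1 <- paste0(randomSeq(10), "G", seed6, "A", randomSeq(10))
  expect_equal(seedClass(mir, t7a1, 12), "7mer-A1")
  t6 <- paste0(randomSeq(10), "G", seed6, "C", randomSeq(10))
  expect_equal(seedClass(mir, t6, 12), "6mer")
  ## a G:U wobble inside the seed disqualifies every canonical class:
  ## miRNA position 4 is G; put U (T) on the target instead of C
  tgu <- t8
  substr(tgu, 15, 15) <- "T"              # index 12 + (7 - 4)
  expect_equal(seedClass(mir, tgu, 12), "none")
})
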