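# Coverage comparison: bedGraph I/O, binned log2 ratios against a per-base
# oracle, midpoint aggregation, the pooled-variance t test, and the planted
# gene-body depletion.

trackFromDf <- function(df, genome) {
  SignalTrack(gr0(df$chrom, df$s0, df$e0, score = df$v), genome)
}

test_that("readBedgraph validates and round-trips", {
  genome <- smallGenome()
  p <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t100\t2.0", p)
  tr <- readBedgraph(p, genome)
  expect_s4_class(tr, "SignalTrack")
  expect_equal(mcols(tr)$score, 2)
  expect_equal(c(start(tr) - 1, end(tr)), c(0, 100))

  writeLines(c("chr1\t0\t100\t2.0", "chr1\t50\t150\t3.0"), p)
  expect_error(readBedgraph(p, genome), "overlapping")

  writeLines("chr1\t0\t100\t-1", p)
  expect_error(readBedgraph(p, genome), "negative")

  writeLines(c("chr1\t0\t100\t2.5", "chr2\t10\t30\t0.25"), p)
  tr <- readBedgraph(p, genome)
  p2 <- tempfile()
  writeBedgraph(tr, p2)
  tr2 <- readBedgraph(p2, genome)
  expect_equal(mcols(tr2)$score, mcols(tr)$score)
  expect_identical(as.data.frame(granges(tr2)), as.data.frame(granges(tr)))
})

test_that("binLog2Ratio computes per-bin log2 with pseudocount", {
  genome <- genomeSpec("chr1", 1000)
  A <- trackFromDf(data.frame(chrom = "chr1", s0 = 0, e0 = 1000, v = 4),
                   genome)
  B <- trackFromDf(data.frame(chrom = "chr1", s0 = 0, e0 = 1000, v = 2),
                   genome)
  r <- binLog2Ratio(A, B, binSize = 50, pseudocount = 0)
  expect_equal(length(r), 20)
  expect_true(all(mcols(r)$score == 1))

  expect_true(all(mcols(binLog2Ratio(A, A, 50, 1))$score == 0))
  # swapping the tracks negates every bin exactly
  r1 <- binLog2Ratio(A, B, 50, 1)
  r2 <- binLog2Ratio(B, A, 50, 1)
  expect_equal(mcols(r1)$score, -mcols(r2)$score)

  # zero pseudocount with an uncovered bin is an error
  Az <- trackFromDf(data.frame(chrom = "chr1", s0 = 0, e0 = 500, v = 4),
                    genome)
  expect_error(binLog2Ratio(Az, B, 50, 0), "pseudocount 0")
})

test_that("binLog2Ratio agrees with a per-base averaging oracle", {
  genome <- genomeSpec("chr1", 2000)
  set.seed(91)
  mkTrack <- function() {
    e <- sort(sample(50:1950, 8))
    s <- c(0, e[-8])
    keep <- s < e
    trackFromDf(data.frame(chrom = "chr1", s0 = s[keep], e0 = e[keep],
                           v = round(runif(sum(keep), 0, 10), 2)), genome)
  }
  for (i in 1:10) {
    A <- mkTrack(); B <- mkTrack()
    r <- binLog2Ratio(A, B, binSize = 50, pseudocount = 1)
    baseVec <- function(tr) {
      v <- numeric(2000)
      for (j in seq_along(tr))
        v[start(tr)[j]:end(tr)[j]] <- mcols(tr)$score[j]
      v
    }
    va <- baseVec(A); vb <- baseVec(B)
    want <- vapply(seq_len(40), function(k) {
      idx <- ((k - 1) * 50 + 1):(k * 50)
      log2((mean(va[idx]) + 1) / (mean(vb[idx]) + 1))
    }, numeric(1))
    expect_equal(mcols(r)$score, want, tolerance = 1e-12)
  }
})

test_that("meanOverIntervals averages bins by midpoint containment", {
  genome <- genomeSpec("chr1", 1000)
  A <- trackFromDf(data.frame(chrom = "chr1", s0 = 0, e0 = 100, v = 3),
                   genome)
  B <- trackFromDf(data.frame(chrom = "chr1", s0 = 0, e0 = 100, v = 1),
                   genome)
  r <- binLog2Ratio(A, B, binSize = 50, pseudocount = 1)
  # bins valued {1,1,0,...}: region over the first three bins
  m <- meanOverIntervals(r, gr0("chr1", 0, 150))
  expect_equal(unname(m), 2 / 3)
  # a region shorter than one bin containing one midpoint takes that value
  m2 <- meanOverIntervals(r, gr0("chr1", 20, 30))
  expect_equal(unname(m2), 1)
  # a region containing no bin midpoint is NA
  m3 <- meanOverIntervals(r, gr0("chr1", 30, 40))
  expect_true(is.na(m3))
  # random regions match direct recomputation
  set.seed(92)
  regions <- randomIntervalSet(15, genome, maxLen = 200)
  got <- meanOverIntervals(r, regions)
  mids0 <- (start(r) - 1 + end(r)) %/% 2
  for (j in seq_along(regions)) {
    sel <- mids0 >= start(regions)[j] - 1 & mids0 < end(regions)[j]
    if (any(sel)) expect_equal(unname(got[j]), mean(mcols(r)$score[sel]))
    else expect_true(is.na(got[j]))
  }
})

test_that("twoSampleTTest matches the pooled-variance formula", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  got <- twoSampleTTest(x, y)
  # hand pooled computation as the oracle
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tHand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, tHand, tolerance = 1e-12)
  expect_equal(got$t, -1.224745, tolerance = 1e-6)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(tHand, 4), tolerance = 1e-12)
  expect_equal(got$p, 0.288, tolerance = 1e-3)

  same <- twoSampleTTest(c(5, 5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(zv <- twoSampleTTest(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(zv$p, 0)

  # scale invariance and welch/student agreement for balanced groups
  g1 <- twoSampleTTest(x, y)
  g2 <- twoSampleTTest(10 * x, 10 * y)
  expect_equal(g1$t, g2$t)
  expect_equal(g1$p, g2$p)
  w <- twoSampleTTest(x, y, variant = "welch")
  expect_equal(w$t, g1$t, tolerance = 1e-9)
  expect_equal(w$p, g1$p, tolerance = 1e-9)
})

test_that("gene-body comparison recovers a planted depletion", {
  genome <- genomeSpec(c("chr1", "chr2"), c(200000, 200000))
  set.seed(93)
  n <- 40
  s0 <- rep(seq(0, 190000, by = 5000), 2)[1:n]
  chrom <- rep(c("chr1", "chr2"), each = n / 2)
  gr <- gr0(chrom, s0, s0 + 3000, strand = "+")
  mcols(gr)$gene_id <- sprintf("g%02d", 1:n)
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
  GenomeInfoDb::seqinfo(gr) <- genome
  genes <- GeneTable(gr)
  classes <- setNames(rep("unchanged", n), geneIds(genes))
  classes[1:10] <- "down"
  # WT constant 40; KO = 20 over down-gene bodies, 40 elsewhere, plus noise
  mkBins <- function(lam) {
    w <- tileWindows(genome, 50)
    mcols(w)$score <- rpois(length(w), lam)
    w
  }
  wt <- SignalTrack(mkBins(40), genome)
  koGR <- mkBins(40)
  downBodies <- geneBodies(genes)[classes == "down"]
  mid0 <- (start(koGR) - 1 + end(koGR)) %/% 2
  inDown <- overlapsAny(GRanges(seqnames(koGR), IRanges(mid0 + 1, width = 1)),
                        downBodies)
  mcols(koGR)$score[inDown] <- rpois(sum(inDown), 20)
  ko <- SignalTrack(koGR, genome)

  res <- geneBodyRatioComparison(ko, wt, genes, classes)
  means <- tapply(res$perGene$mean_log2_ratio, res$perGene$class, mean)
  expect_lt(abs(means[["down"]] - log2(21 / 41)), 0.1)
  expect_lt(abs(means[["unchanged"]]), 0.05)
  tests <- res$tests
  expect_lt(tests$p[tests$contrast == "down_vs_unchanged"], 1e-6)
  expect_true("up_vs_unchanged" %in% res$skipped) # no up genes here

  # permuting the class labels destroys the planted effect
  vals <- res$perGene$mean_log2_ratio
  isDown <- res$perGene$class == "down"
  pPerm <- vapply(1:20, function(i) {
    sh <- sample(isDown)
    twoSampleTTest(vals[sh], vals[!sh])$p
  }, numeric(1))
  expect_gte(mean(pPerm > 0.01), 0.9)

  # per-bin unit is available and more extreme
  resBin <- geneBodyRatioComparison(ko, wt, genes, classes, unit = "bin")
  expect_lte(resBin$tests$p[1], tests$p[tests$contrast == "down_vs_unchanged"])
})
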