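# Region-to-gene association: gene reading, body-anchored proximity, gene
# extension, nearest-TSS assignment and the signed-distance histogram,
# cross-checked against quadratic all-pairs scans.

makeGenes <- function(chrom, start0, end0, strand, ids,
                      genome = NULL) {
  gr <- gr0(chrom, start0, end0, strand = strand)
  mcols(gr)$gene_id <- ids
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  GeneTable(gr)
}

test_that("readGenes validates BED6 gene records and applies biotype maps", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t2000\tgA\t0\t+",
               "chr1\t5000\t9000\tgB\t0\t-",
               "chr2\t0\t500\tgC\t0\t+"), p)
  gt <- readGenes(p)
  expect_s4_class(gt, "GeneTable")
  expect_equal(geneIds(gt), c("gA", "gB", "gC"))
  expect_true(all(mcols(gt)$biotype == "protein_coding"))

  writeLines(c("chr1\t100\t2000\tgA\t0\t+", "chr1\t5000\t9000\tgA\t0\t-"), p)
  expect_error(readGenes(p), "duplicated gene_id")

  writeLines("chr1\t100\t2000\tgA\t0\t.", p)
  expect_error(readGenes(p), "strand")

  writeLines(c("chr1\t100\t2000\tgA\t0\t+", "chr1\t5000\t9000\tgB\t0\t-"), p)
  bm <- tempfile()
  writeLines("gB\tlincRNA", bm)
  gt <- readGenes(p, biotypeMap = bm)
  expect_equal(mcols(gt)$biotype, c("protein_coding", "lincRNA"))
})

test_that("proximalGeneIds applies the gene-body distance rule", {
  genome <- genomeSpec("chr1", 1e6)
  genes <- makeGenes("chr1", 10000, 12000, "+", "gA", genome)
  # gap 48,000 <= 50,000: included
  expect_equal(proximalGeneIds(gr0("chr1", 60000, 60500), genes), "gA")
  # gap 50,100 > 50,000: excluded
  expect_equal(proximalGeneIds(gr0("chr1", 62100, 62500), genes),
               character(0))
  # overlap counts as distance 0, and maxDistance 0 means body overlap
  expect_equal(proximalGeneIds(gr0("chr1", 11000, 11100), genes,
                               maxDistance = 0), "gA")
  expect_equal(proximalGeneIds(gr0("chr1", 12000, 12100), genes,
                               maxDistance = 0), character(0))
})

test_that("proximalGeneIds matches a quadratic scan and is monotone", {
  genome <- smallGenome()
  set.seed(51)
  n <- 25
  chrom <- sample(c("chr1", "chr2"), n, TRUE)
  s0 <- floor(runif(n) * 7000)
  genes <- makeGenes(chrom, s0, s0 + sample(100:600, n, TRUE),
                     sample(c("+", "-"), n, TRUE),
                     sprintf("g%02d", 1:n), genome)
  peaks <- randomIntervalSet(15, genome)
  prev <- character(0)
  for (D in c(0, 100, 500, 2000, 10000)) {
    got <- proximalGeneIds(peaks, genes, maxDistance = D)
    # quadratic oracle: any peak overlapping the D-extended gene body
    want <- geneIds(genes)[vapply(seq_along(genes), function(i) {
      gs0 <- start(genes)[i] - 1; ge0 <- end(genes)[i]
      ch <- as.character(seqnames(genes))[i]
      sel <- as.character(seqnames(peaks)) == ch
      any(start(peaks)[sel] - 1 < ge0 + D & end(peaks)[sel] > gs0 - D)
    }, logical(1))]
    expect_setequal(got, want)
    expect_true(all(prev %in% got)) # monotone in maxDistance
    prev <- got
  }
})

test_that("extendGenes widens, clips, and is equivalent to proximity", {
  genome <- genomeSpec("chr1", 1e7)
  genes <- makeGenes("chr1", 200000, 210000, "+", "gA", genome)
  ext <- extendGenes(genes, flank = 100000)
  expect_equal(c(start(ext) - 1, end(ext)), c(100000, 310000))

  edge <- makeGenes("chr1", 50, 100, "+", "gE", genome)
  extE <- extendGenes(edge, flank = 100000)
  expect_equal(c(start(extE) - 1, end(extE)), c(0, 100100))

  # extend/overlap formulation == direct distance formulation for any flank
  genome2 <- smallGenome()
  set.seed(52)
  n <- 20
  chrom <- sample(c("chr1", "chr2"), n, TRUE)
  s0 <- floor(runif(n) * 7000)
  gt <- makeGenes(chrom, s0, s0 + sample(100:400, n, TRUE),
                  sample(c("+", "-"), n, TRUE), sprintf("g%02d", 1:n),
                  genome2)
  peaks <- randomIntervalSet(12, genome2)
  for (D in c(0, 250, 1000, 5000)) {
    viaExt <- geneIds(gt)[overlapsSubject(extendGenes(gt, D), peaks)]
    expect_setequal(proximalGeneIds(peaks, gt, D), viaExt)
  }
})

test_that("nearestGeneTss uses midpoints, strand-aware TSS and signed distance", {
  genome <- genomeSpec("chr1", 1e6)
  # + strand gene with TSS at 6,000; peak midpoint 5,000: upstream, -1000
  genes <- makeGenes("chr1", 6000, 9000, "+", "gA", genome)
  asn <- nearestGeneTss(gr0("chr1", 4900, 5101), genes)
  expect_equal(asn$gene_id, "gA")
  expect_equal(asn$distance, -1000)
  # downstream of a + gene is positive
  asn2 <- nearestGeneTss(gr0("chr1", 7900, 8101), genes)
  expect_equal(asn2$distance, 2000)
  # - strand gene [1000,2000): TSS at 1999; a peak centred there: 0
  genesM <- makeGenes("chr1", 1000, 2000, "-", "gM", genome)
  asn3 <- nearestGeneTss(gr0("chr1", 1949, 2050), genesM)
  expect_equal(asn3$distance, 0)
  # upstream of a - gene (higher coordinate) is negative
  asn4 <- nearestGeneTss(gr0("chr1", 2949, 3050), genesM)
  expect_equal(asn4$distance, -1000)
  # out of range -> unassigned
  asn5 <- nearestGeneTss(gr0("chr1", 900000, 900100), genesM,
                         maxDistance = 1000)
  expect_true(is.na(asn5$gene_id))
})

test_that("nearestGeneTss matches an exhaustive TSS scan", {
  genome <- smallGenome()
  set.seed(53)
  n <- 30
  chrom <- sample(c("chr1", "chr2"), n, TRUE)
  s0 <- floor(runif(n) * 7000)
  st <- sample(c("+", "-"), n, TRUE)
  gt <- makeGenes(chrom, s0, s0 + sample(100:500, n, TRUE), st,
                  sprintf("g%02d", 1:n), genome)
  peaks <- randomIntervalSet(40, genome)
  asn <- nearestGeneTss(peaks, gt, maxDistance = 3000)
  tss0 <- ifelse(st == "+", start(gt) - 1, end(gt) - 1)
  for (i in seq_along(peaks)) {
    mid0 <- (start(peaks)[i] - 1 + end(peaks)[i]) %/% 2
    same <- as.character(seqnames(gt)) == as.character(seqnames(peaks))[i]
    d <- abs(mid0 - tss0)
    d[!same] <- NA
    if (all(is.na(d)) || min(d, na.rm = TRUE) > 3000) {
      expect_true(is.na(asn$gene_id[i]))
    } else {
      expect_false(is.na(asn$gene_id[i]))
      j <- match(asn$gene_id[i], geneIds(gt))
      expect_equal(d[j], min(d, na.rm = TRUE)) # a nearest gene was chosen
      expect_equal(abs(asn$distance[i]), min(d, na.rm = TRUE))
    }
  }
})

test_that("tssDistanceHistogram bins half-open and conserves counts", {
  asn <- data.frame(peak = 1:3, gene_id = c("a", "b", "c"),
                    distance = c(-1000, 0, 500))
  h <- tssDistanceHistogram(asn, c(-5000, 0, 5000))
  expect_equal(h$count, c(1, 2))
  expect_equal(h$unassigned, 0)

  empty <- data.frame(peak = integer(0), gene_id = character(0),
                      distance = numeric(0))
  h0 <- tssDistanceHistogram(empty, c(-5000, 0, 5000))
  expect_equal(h0$count, c(0, 0))

  # out-of-range and NA distances are unassigned; totals conserved
  asn2 <- data.frame(peak = 1:5, gene_id = c("a", "b", NA, "d", "e"),
                     distance = c(-6000, -1, NA, 4999, 5000))
  h2 <- tssDistanceHistogram(asn2, c(-5000, 0, 5000))
  expect_equal(sum(h2$count) + h2$unassigned, 5)
  expect_equal(h2$count, c(1, 1))
  expect_equal(h2$unassigned, 3)
  expect_error(tssDistanceHistogram(asn2, c(0, 0)), "strictly increasing")
})
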