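# Interval arithmetic: BED I/O, merge/subtract/overlap/distance semantics,
# genome tiling, consensus, shuffling and peak classification, checked
# against per-base bitmap oracles on small genomes.

test_that("readBed parses, validates and sorts BED records", {
  p <- tempfile(fileext = ".bed")

  writeLines("chr1\t0\t100", p)
  gr <- readBed(p)
  expect_equal(start(gr), 1)
  expect_equal(end(gr), 100)

  writeLines("chr1\t100\t100", p)
  expect_error(readBed(p), "start >= end")

  writeLines(c("chr2\t500\t600", "chr1\t300\t400", "chr1\t0\t100"), p)
  gr <- readBed(p)
  expect_equal(length(gr), 3)
  expect_equal(as.character(seqnames(gr)), c("chr1", "chr1", "chr2"))
  expect_equal(start(gr), c(1, 301, 501))

  writeLines(c("chr1\t0\t100", "chr1\tfoo\t200"), p)
  expect_error(readBed(p), "line 2.*start")

  writeLines("chrX\t0\t100", p)
  expect_error(readBed(p, genome = smallGenome()), "chrX")

  writeLines("chr1\t0\t20000", p)
  expect_error(readBed(p, genome = smallGenome()), "exceeds")
})

test_that("writeBed round-trips BED3 and BED6 and handles empty sets", {
  p <- tempfile(fileext = ".bed")

  writeLines(c("chr1\t0\t100\tpk1\t5\t+", "chr1\t200\t300\tpk2\t7\t-"), p)
  gr <- readBed(p)
  p2 <- tempfile(fileext = ".bed")
  writeBed(gr, p2)
  expect_identical(readLines(p2), readLines(p))
  expect_equal(length(strsplit(readLines(p2)[1], "\t")[[1]]), 6)

  writeLines("chr1\t5\t10", p)
  gr3 <- readBed(p)
  writeBed(gr3, p2)
  expect_identical(readLines(p2), "chr1\t5\t10")

  writeBed(GRanges(), p2)
  expect_equal(length(readLines(p2)), 0)
})

test_that("mergeIntervals joins overlapping and book-ended intervals", {
  expect_equal(
    as.data.frame(mergeIntervals(gr0("chr1", c(0, 50), c(100, 150))))[, 2:3],
    data.frame(start = 1, end = 150))
  # abutting half-open intervals do not overlap but DO merge at gap 0
  m <- mergeIntervals(gr0("chr1", c(0, 100), c(100, 200)))
  expect_equal(length(m), 1)
  expect_equal(width(m), 200)
  # gap parameter joins intervals with gap <= gap
  g <- gr0("chr1", c(0, 110), c(100, 200))
  expect_equal(length(mergeIntervals(g, gap = 9)), 2)
  expect_equal(length(mergeIntervals(g, gap = 10)), 1)
})

test_that("merge preserves covered bases on random sets (bitmap oracle)", {
  genome <- smallGenome()
  set.seed(41)
  for (i in 1:20) {
    s <- randomIntervalSet(50, genome)
    m <- mergeIntervals(s)
    expect_false(any(duplicated(as.data.frame(m))))
    expect_equal(coveredBases(m), bitmapCoveredBases(s, genome))
    expect_same_bases(m, bitmap(s, genome), genome)
  }
})

test_that("subtractIntervals removes excluded bases, splitting as needed", {
  r <- subtractIntervals(gr0("chr1", 0, 100), gr0("chr1", 40, 60))
  expect_equal(start(r) - 1, c(0, 60))
  expect_equal(end(r), c(40, 100))
  expect_equal(length(subtractIntervals(gr0("chr1", 0, 100),
                                        gr0("chr1", 0, 100))), 0)
  genome <- smallGenome()
  set.seed(42)
  for (i in 1:20) {
    a <- randomIntervalSet(30, genome)
    b <- randomIntervalSet(30, genome)
    want <- bitmap(a, genome)
    bb <- bitmap(b, genome)
    for (ch in names(want)) want[[ch]] <- want[[ch]] & !bb[[ch]]
    expect_same_bases(subtractIntervals(a, b), want, genome)
  }
})

test_that("overlapsSubject uses half-open overlap semantics", {
  expect_true(overlapsSubject(gr0("chr1", 0, 100), gr0("chr1", 99, 200)))
  expect_false(overlapsSubject(gr0("chr1", 0, 100), gr0("chr1", 100, 200)))
  genome <- smallGenome()
  set.seed(43)
  for (i in 1:10) {
    a <- randomIntervalSet(25, genome)
    b <- randomIntervalSet(25, genome)
    bb <- bitmap(b, genome)
    want <- vapply(seq_along(a), function(j) {
      ch <- as.character(seqnames(a))[j]
      any(bb[[ch]][start(a)[j]:end(a)[j]])
    }, logical(1))
    expect_identical(overlapsSubject(a, b), want)
  }
})

test_that("intervalDistance is 0 for overlap/abutment and NA across chroms", {
  expect_equal(intervalDistance(gr0("chr1", 1000, 1200),
                                gr0("chr1", 1300, 2000)), 100)
  expect_equal(intervalDistance(gr0("chr1", 0, 100),
                                gr0("chr1", 50, 150)), 0)
  expect_equal(intervalDistance(gr0("chr1", 0, 100),
                                gr0("chr1", 100, 200)), 0)
  expect_true(is.na(intervalDistance(gr0("chr1", 0, 100),
                                     gr0("chr2", 0, 100))))
})

test_that("tileWindows drops partial windows and excluded windows", {
  g1 <- genomeSpec("chr1", 1050)
  expect_equal(length(tileWindows(g1, 100)), 10)
  w <- tileWindows(g1, 100, excluded = gr0("chr1", 150, 160))
  expect_equal(length(w), 9)
  expect_false(any(start(w) == 101))
  g2 <- genomeSpec(c("chrA", "chrB"), c(1000, 250))
  expect_equal(length(tileWindows(g2, 100)), 12)
  # per-chromosome counts equal floor(length/size) before exclusion
  g3 <- genomeSpec(c("c1", "c2"), c(999, 1001))
  tw <- tileWindows(g3, 100)
  expect_equal(as.integer(table(as.character(seqnames(tw)))[c("c1", "c2")]),
               c(9, 10))
})

test_that("consensusPeaks matches the per-base support oracle", {
  A <- gr0("chr1", 0, 100); B <- gr0("chr1", 50, 150); C <- gr0("chr1", 80, 90)
  cons <- consensusPeaks(list(A, B, C), minSupport = 3)
  expect_equal(length(cons), 1)
  expect_equal(c(start(cons) - 1, end(cons)), c(80, 90))

  one <- gr0("chr1", c(0, 50, 300), c(100, 150, 400))
  expect_identical(as.data.frame(consensusPeaks(list(one), 1))[, 1:3],
                   as.data.frame(mergeIntervals(one))[, 1:3])

  genome <- smallGenome()
  set.seed(44)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) randomIntervalSet(20, genome))
    supp <- bitmapSupport(sets, genome)
    prevCov <- Inf
    for (k in 1:3) {
      cons <- consensusPeaks(sets, minSupport = k, genome = genome)
      want <- lapply(supp, function(v) v >= k)
      expect_same_bases(cons, want, genome)
      expect_equal(length(cons), bitmapRegionCount(supp, k))
      # antitone in minSupport
      expect_lte(coveredBases(cons), prevCov)
      prevCov <- coveredBases(cons)
    }
  }
})

test_that("shuffleIntervals preserves counts and widths and is seeded", {
  genome <- smallGenome()
  set.seed(45)
  x <- randomIntervalSet(40, genome)
  s1 <- shuffleIntervals(x, genome, seed = 9)
  s2 <- shuffleIntervals(x, genome, seed = 9)
  s3 <- shuffleIntervals(x, genome, seed = 10)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))
  expect_equal(table(as.character(seqnames(s1))),
               table(as.character(seqnames(x))))
  expect_equal(sort(width(s1)), sort(width(x)))
  expect_true(all(end(s1) <= GenomeInfoDb::seqlengths(genome)[
    as.character(seqnames(s1))]))

  # exclusions respected
  excl <- gr0("chr1", 0, 9000)
  xs <- gr0("chr1", c(0, 10, 20), c(100, 110, 120))
  sh <- shuffleIntervals(xs, genome, excluded = excl, seed = 1)
  expect_false(any(overlapsSubject(sh, excl)))

  # interval longer than the chromosome is a loud error
  big <- gr0("chr2", 0, 8000 + 1)
  expect_error(shuffleIntervals(big, smallGenome(c(chr2 = 8000)), seed = 1),
               "longer")
})

test_that("shuffled starts are uniform (chi-square goodness of fit)", {
  genome <- genomeSpec("chr1", 1000)
  x <- gr0("chr1", 0, 100)
  starts <- vapply(1:10000, function(i)
    start(shuffleIntervals(x, genome, seed = i)) - 1L, integer(1))
  expect_gte(min(starts), 0)
  expect_lte(max(starts), 900)
  counts <- tabulate(starts + 1, nbins = 901) # one cell per legal start
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("classifyPeaks dichotomizes on heterochromatin overlap", {
  peaks <- gr0("chr1", seq(0, 9000, by = 1000), seq(100, 9100, by = 1000))
  marks <- gr0("chr1", 3050, 3080)
  cls <- classifyPeaks(peaks, marks)
  expect_equal(unname(classFractions(cls)), c(0.9, 0.1))
  expect_equal(as.character(peakClasses(cls))[4], "heterochromatic")

  allEu <- classifyPeaks(peaks, GRanges())
  expect_true(all(peakClasses(allEu) == "euchromatic"))

  genome <- smallGenome()
  set.seed(46)
  p <- randomIntervalSet(30, genome)
  m <- randomIntervalSet(10, genome)
  ev <- list(atac = randomIntervalSet(10, genome))
  cls <- classifyPeaks(p, m, ev)
  expect_identical(peakClasses(cls) == "heterochromatic",
                   overlapsSubject(p, m))
  expect_equal(unname(cls@qc["atac"]), mean(overlapsSubject(p, ev$atac)))
})
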