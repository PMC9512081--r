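# Brute-force oracles and fixture builders shared across tests. The oracles
# are deliberately naive (per-base bitmaps, exhaustive enumeration, quadratic
# scans) and independent of the interval/statistics engines they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr0 <- function(chrom, start0, end0, ...) {
  # build a GRanges from 0-based half-open coordinates, as specs and BED use
  GRanges(chrom, IRanges(start0 + 1, end0), ...)
}

smallGenome <- function(lengths = c(chr1 = 10000, chr2 = 8000)) {
  genomeSpec(names(lengths), lengths)
}

randomIntervalSet <- function(n, genome, maxLen = 300) {
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  s0 <- floor(runif(n) * (sl[chrom] - w))
  gr0(chrom, s0, s0 + w)
}

# ---- per-base bitmap oracle -------------------------------------------------

# covered-base logical vector per chromosome (index i = base i-1, 0-based)
bitmap <- function(gr, genome) {
  sl <- GenomeInfoDb::seqlengths(genome)
  out <- lapply(names(sl), function(ch) {
    v <- logical(sl[[ch]])
    sub <- gr[as.character(seqnames(gr)) == ch]
    for (i in seq_along(sub)) v[start(sub)[i]:end(sub)[i]] <- TRUE
    v
  })
  names(out) <- names(sl)
  out
}

bitmapSupport <- function(sets, genome) {
  sl <- GenomeInfoDb::seqlengths(genome)
  out <- lapply(names(sl), function(ch) integer(sl[[ch]]))
  names(out) <- names(sl)
  for (s in sets) {
    bm <- bitmap(s, genome)
    for (ch in names(out)) out[[ch]] <- out[[ch]] + bm[[ch]]
  }
  out
}

bitmapCoveredBases <- function(gr, genome) {
  sum(vapply(bitmap(gr, genome), sum, numeric(1)))
}

expect_same_bases <- function(gr, expectedBitmap, genome) {
  got <- bitmap(gr, genome)
  for (ch in names(expectedBitmap))
    expect_identical(got[[ch]], expectedBitmap[[ch]])
}

# number of maximal runs with support >= k, per the bitmap
bitmapRegionCount <- function(supportList, k) {
  sum(vapply(supportList, function(v)
    sum(diff(c(FALSE, v >= k)) == 1), numeric(1)))
}

# ---- Fisher enumeration oracle ---------------------------------------------

# Exhaustive two-sided Fisher p: enumerate the full hypergeometric support
# with log-binomial point probabilities and sum those at most the observed
# probability (relative tie tolerance 1e-7).
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  x <- max(0, k - r2):min(r1, k)
  lp <- lchoose(r1, x) + lchoose(r2, k - x) - lchoose(r1 + r2, k)
  pr <- exp(lp)
  pobs <- pr[x == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# ---- small synthetic-study configuration for unit tests ---------------------

smallStudyConfig <- function(...) {
  studyConfig(
    genome = list(n_chroms = 2L, chrom_length = 5e6),
    genes = list(n_genes = 60L, min_gap = 60000, max_length = 5000,
                 n_clusters = 2L),
    target_set_size = 15L,
    decoy_set_size = 15L,
    peaks = list(n_background = 20L, placement_window = 20000),
    cooccupancy = list(n_shared_loci = 40L, n_background_partner = 20L),
    blacklist = list(n_intervals = 5L, length = 20000),
    signal = list(up_set_size = 10L),
    ...)
}
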