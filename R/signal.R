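# Two-condition coverage comparison: per-bin log2 ratios with a pseudocount,
# aggregation over gene bodies by bin-midpoint containment, and the
# two-sample t test comparing DE classes. The unit entering the t test is
# the per-gene mean (one value per gene) by default, which avoids the
# pseudoreplication of testing bins directly; per-bin testing is available
# behind the 'unit' flag.

.trackCoverage <- function(x) {
  GenomicRanges::coverage(x, weight = mcols(x)$score)
}

#' Binned log2 ratio of two coverage tracks
#'
#' The genome is tiled into \code{binSize}-bp windows (trailing partial
#' windows dropped); each track's mean coverage over the bin is computed and
#' the bin value is \code{log2((meanA + pseudocount)/(meanB + pseudocount))}.
#'
#' @param a,b \linkS4class{SignalTrack}s on the same genome
#' @param binSize bin width in bp (default 50)
#' @param pseudocount added to both means (default 1); must be positive
#'   whenever either track can have a zero-coverage bin
#' @return a \linkS4class{BinnedLogRatio}
#' @export
binLog2Ratio <- function(a, b, binSize = 50, pseudocount = 1) {
  stopifnot(is(a, "SignalTrack"), is(b, "SignalTrack"),
            binSize >= 1, pseudocount >= 0)
  if (!identical(seqlengths(a), seqlengths(b)))
    stop("the two tracks are on different genomes")
  genome <- seqinfo(a)
  bins <- tileWindows(genome, binSize)
  covA <- .trackCoverage(a)
  covB <- .trackCoverage(b)
  bins <- GenomicRanges::binnedAverage(bins, covA, "meanA")
  bins <- GenomicRanges::binnedAverage(bins, covB, "meanB")
  mA <- mcols(bins)$meanA
  mB <- mcols(bins)$meanB
  if (pseudocount == 0 && any(mA == 0 | mB == 0))
    stop("pseudocount 0 with a zero-coverage bin")
  mcols(bins) <- DataFrame(score = log2((mA + pseudocount) /
                                        (mB + pseudocount)))
  new("BinnedLogRatio", bins, binSize = as.integer(binSize),
      pseudocount = pseudocount)
}

#' Mean binned value over regions
#'
#' A bin belongs to a region iff the bin midpoint falls inside the region
#' (half-open), the single convention used for region aggregation -- it
#' avoids double-counting bins that straddle region edges. Regions covering
#' no bin midpoint get \code{NA}.
#'
#' @param ratio a \linkS4class{BinnedLogRatio}
#' @param regions \code{GRanges}; names are carried to the result
#' @return named numeric vector, one (possibly NA) mean per region
#' @export
meanOverIntervals <- function(ratio, regions) {
  stopifnot(is(ratio, "BinnedLogRatio"), is(regions, "GRanges"))
  out <- rep(NA_real_, length(regions))
  names(out) <- names(regions)
  if (length(ratio) == 0 || length(regions) == 0) return(out)
  mid0 <- (start(ratio) - 1 + end(ratio)) %/% 2
  mids <- GRanges(seqnames(ratio), IRanges(mid0 + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(mids, .bare(regions))
  if (length(hits) == 0) return(out)
  sums <- tapply(mcols(ratio)$score[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), mean)
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}

#' Two-sample t test
#'
#' Student (pooled variance, df = n1 + n2 - 2) by default, or Welch. Zero
#' pooled variance with equal means gives t = 0, p = 1; with unequal means
#' it gives a signed infinite t and p = 0 with a warning.
#'
#' @param x,y numeric vectors with at least 2 finite values each
#' @param variant \code{"student"} or \code{"welch"}
#' @return list with \code{t}, \code{df}, \code{p}
#' @export
twoSampleTTest <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p = 1))
    warning("zero variance with unequal means; p reported as 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Gene-body log2-ratio comparison between DE classes
#'
#' Composes \code{\link{binLog2Ratio}}, \code{\link{meanOverIntervals}} over
#' gene bodies, and \code{\link{twoSampleTTest}} of down-vs-unchanged and
#' up-vs-unchanged. With \code{unit = "gene"} (default) the t test compares
#' per-gene means; \code{unit = "bin"} pools the per-bin values of each
#' class (more powerful but pseudoreplicated -- bins within a gene are not
#' independent).
#'
#' @param a,b \linkS4class{SignalTrack}s (e.g. KO and WT coverage)
#' @param genes \linkS4class{GeneTable}
#' @param deClasses named character mapping gene_id to \code{"down"},
#'   \code{"up"} or \code{"unchanged"}
#' @param binSize bin width in bp (default 50)
#' @param pseudocount added to bin means (default 1)
#' @param variant t-test variant
#' @param unit \code{"gene"} or \code{"bin"}
#' @return list with \code{perGene} (data.frame: gene_id, class,
#'   mean_log2_ratio), \code{tests} (data.frame: contrast, t, df, p),
#'   \code{unit} and \code{skipped} (contrasts with too few values)
#' @export
geneBodyRatioComparison <- function(a, b, genes, deClasses, binSize = 50,
                                    pseudocount = 1,
                                    variant = c("student", "welch"),
                                    unit = c("gene", "bin")) {
  stopifnot(is(genes, "GeneTable"))
  variant <- match.arg(variant)
  unit <- match.arg(unit)
  if (is.null(names(deClasses)) ||
      any(!deClasses %in% c("down", "up", "unchanged")))
    stop("'deClasses' must be a named character of down/up/unchanged")
  keep <- names(deClasses)[names(deClasses) %in% geneIds(genes)]
  if (!length(keep)) stop("no classified gene is present in the gene table")
  ratio <- binLog2Ratio(a, b, binSize = binSize, pseudocount = pseudocount)
  bodies <- geneBodies(genes)[keep]
  gm <- meanOverIntervals(ratio, bodies)
  perGene <- data.frame(gene_id = keep,
                        class = unname(deClasses[keep]),
                        mean_log2_ratio = unname(gm))
  groupValues <- function(cl) {
    if (unit == "gene")
      return(perGene$mean_log2_ratio[perGene$class == cl &
                                     !is.na(perGene$mean_log2_ratio)])
    sub <- bodies[perGene$class == cl]
    mid0 <- (start(ratio) - 1 + end(ratio)) %/% 2
    mids <- GRanges(seqnames(ratio), IRanges(mid0 + 1, width = 1))
    mcols(ratio)$score[overlapsAny(mids, .bare(sub))]
  }
  unch <- groupValues("unchanged")
  tests <- data.frame(contrast = character(0), t = numeric(0),
                      df = numeric(0), p = numeric(0))
  skipped <- character(0)
  for (cl in c("down", "up")) {
    v <- groupValues(cl)
    if (length(v) < 2 || length(unch) < 2) {
      skipped <- c(skipped, paste0(cl, "_vs_unchanged"))
      message("geneBodyRatioComparison: skipping ", cl,
              "-vs-unchanged (fewer than 2 values in a group)")
      next
    }
    tt <- twoSampleTTest(v, unch, variant = variant)
    tests <- rbind(tests, data.frame(contrast = paste0(cl, "_vs_unchanged"),
                                     t = tt$t, df = tt$df, p = tt$p))
  }
  list(perGene = perGene, tests = tests, unit = unit, skipped = skipped)
}
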