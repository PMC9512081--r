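# Interval arithmetic over GRanges under BED semantics: 0-based half-open on
# disk, 1-based closed in memory. Overlap requires >= 1 shared base; abutting
# intervals do not overlap but DO merge at gap 0, matching bedtools merge.

#' Merge intervals closer than or equal to a gap
#'
#' Intervals whose gap is at most \code{gap} bp are joined; abutting
#' intervals (gap 0) are always joined. The union of covered bases is
#' preserved for any \code{gap}.
#'
#' @param x a \code{GRanges}
#' @param gap maximum joining gap in bp (>= 0)
#' @return a non-overlapping, sorted \code{GRanges}
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(100, 150)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(x, gap = 0L) {
  stopifnot(is(x, "GRanges"), gap >= 0)
  GenomicRanges::reduce(.bare(x), min.gapwidth = gap + 1L)
}

#' Subtract one interval set from another
#'
#' Removes every base of \code{excluded} from \code{x}; intervals may be
#' split. Operates on the base-level union of \code{x}.
#'
#' @param x,excluded \code{GRanges}
#' @return sorted \code{GRanges} with no base overlapping \code{excluded}
#' @export
subtractIntervals <- function(x, excluded) {
  stopifnot(is(x, "GRanges"), is(excluded, "GRanges"))
  GenomicRanges::setdiff(.bare(x), .bare(excluded))
}

#' Flag query intervals overlapping any subject interval
#'
#' Overlap means at least one shared base under half-open semantics:
#' \code{[0,100)} and \code{[100,200)} do not overlap.
#'
#' @param query,subject \code{GRanges}
#' @return logical vector, one flag per query interval
#' @export
overlapsSubject <- function(query, subject) {
  stopifnot(is(query, "GRanges"), is(subject, "GRanges"))
  overlapsAny(.bare(query), .bare(subject))
}

#' Pairwise genomic distance
#'
#' 0 for overlapping or abutting intervals, the gap length otherwise, and
#' \code{NA} (a typed undefined, never a large number) across chromosomes.
#'
#' @param a,b parallel \code{GRanges} (recycled to equal length)
#' @return integer vector of distances in bp, \code{NA} across chromosomes
#' @export
intervalDistance <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  GenomicRanges::distance(.bare(a), .bare(b))
}

#' Tile a genome into fixed-size non-overlapping windows
#'
#' Windows are \code{[0,size)}, \code{[size,2*size)}, ... per chromosome; a
#' trailing partial window is dropped so every retained window has equal
#' size. Windows overlapping \code{excluded} by >= 1 bp are removed.
#'
#' @param genome a \code{Seqinfo}
#' @param size window size in bp (>= 1)
#' @param excluded optional \code{GRanges} (e.g. a blacklist)
#' @return \code{GRanges} of windows
#' @export
tileWindows <- function(genome, size, excluded = NULL) {
  stopifnot(is(genome, "Seqinfo"), size >= 1)
  size <- as.integer(size)
  sl <- seqlengths(genome)
  if (anyNA(sl)) stop("genome has undefined chromosome lengths")
  nwin <- sl %/% size
  chroms <- names(sl)[nwin > 0]
  if (!length(chroms)) return(GRanges(seqinfo = genome))
  grl <- lapply(chroms, function(ch) {
    GRanges(ch, successiveIRanges(rep.int(size, nwin[[ch]])),
            seqinfo = genome)
  })
  w <- suppressWarnings(do.call(c, grl))
  if (!is.null(excluded) && length(excluded))
    w <- w[!overlapsAny(w, .bare(excluded))]
  w
}

#' Consensus regions across interval sets
#'
#' Computes per-base support (the number of input sets covering each base,
#' counting each set at most once) and returns the merged maximal regions
#' with support >= \code{minSupport}; each output range is one consensus
#' locus.
#'
#' @param sets list (or \code{GRangesList}) of \code{GRanges}
#' @param minSupport required per-base support, between 1 and
#'   \code{length(sets)}; the default requires all sets (full intersection)
#' @param genome optional \code{Seqinfo}; otherwise lengths are inferred
#' @return sorted \code{GRanges} of consensus loci
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' consensusPeaks(list(a, b))
#' @export
consensusPeaks <- function(sets, minSupport = length(sets), genome = NULL) {
  sets <- .asGRList(sets)
  if (minSupport < 1 || minSupport > length(sets))
    stop("'minSupport' must be between 1 and the number of sets")
  sl <- if (is.null(genome)) {
    all <- suppressWarnings(do.call(c, lapply(sets, .bare)))
    if (!length(all)) return(GRanges())
    vapply(split(end(all), as.character(seqnames(all))), max, 0)
  } else seqlengths(genome)
  covs <- lapply(sets, function(g) {
    g <- GenomicRanges::reduce(.bare(g))
    cv <- GenomicRanges::coverage(g)
    missing <- setdiff(names(sl), names(cv))
    for (m in missing) cv[[m]] <- Rle(0L, sl[[m]])
    cv <- cv[names(sl)]
    for (ch in names(sl))
      if (length(cv[[ch]]) < sl[[ch]])
        cv[[ch]] <- c(cv[[ch]], Rle(0L, sl[[ch]] - length(cv[[ch]])))
    cv
  })
  support <- Reduce(`+`, covs)
  hits <- slice(support, lower = minSupport, rangesOnly = TRUE)
  gr <- GRanges(hits)
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
  }
  sort(gr, ignore.strand = TRUE)
}

#' Shuffle intervals within their chromosomes
#'
#' Each interval is re-placed uniformly at random on its own chromosome with
#' its length preserved; placements overlapping \code{excluded} are rejected
#' and redrawn (up to \code{maxAttempts} rounds). Shuffled intervals may
#' overlap one another. Deterministic given \code{seed}.
#'
#' @param x \code{GRanges} to shuffle
#' @param genome \code{Seqinfo} with chromosome lengths
#' @param excluded optional \code{GRanges} the shuffled intervals must avoid
#' @param seed integer seed
#' @param maxAttempts rejection-sampling cap per interval
#' @return \code{GRanges} with the same per-chromosome counts and widths
#' @export
shuffleIntervals <- function(x, genome, excluded = NULL, seed,
                             maxAttempts = 1000L) {
  stopifnot(is(x, "GRanges"), is(genome, "Seqinfo"))
  seed <- .checkSeed(seed)
  sl <- seqlengths(genome)
  if (anyNA(sl)) stop("genome has undefined chromosome lengths")
  chrom <- as.character(seqnames(x))
  if (any(!chrom %in% names(sl)))
    stop("intervals on chromosomes absent from genome")
  w <- width(x)
  span <- sl[chrom] - w + 1
  if (any(span < 1)) {
    i <- which(span < 1)[1]
    stop("interval ", chrom[i], ":", start(x)[i] - 1, "-", end(x)[i],
         " is longer than its chromosome")
  }
  exc <- if (is.null(excluded)) NULL else
    GenomicRanges::reduce(.bare(excluded))
  newStart <- withr::with_seed(seed, {
    s <- as.integer(floor(stats::runif(length(x)) * span)) + 1L
    if (!is.null(exc) && length(exc)) {
      for (att in seq_len(maxAttempts)) {
        cand <- GRanges(chrom, IRanges(s, width = w))
        bad <- overlapsAny(cand, exc)
        if (!any(bad)) break
        if (att == maxAttempts) {
          i <- which(bad)[1]
          stop("shuffleIntervals: could not place interval ", chrom[i],
               " (width ", w[i], ") outside exclusions after ",
               maxAttempts, " attempts")
        }
        s[bad] <- as.integer(floor(stats::runif(sum(bad)) * span[bad])) + 1L
      }
    }
    s
  })
  out <- GRanges(chrom, IRanges(newStart, width = w), seqinfo = genome)
  sort(out, ignore.strand = TRUE)
}

#' Classify peaks as euchromatic or heterochromatic
#'
#' A peak is heterochromatic iff it overlaps the heterochromatin-mark set
#' (e.g. H4K20me3/H3K9me3 peaks); all other peaks are euchromatic. The
#' fraction of peaks overlapping each euchromatin-evidence set (e.g. ATAC
#' open chromatin, H3K27ac) is reported as QC but never used for the
#' dichotomy.
#'
#' @param peaks \code{GRanges}
#' @param heterochromatinMarks \code{GRanges} of heterochromatin-mark peaks
#' @param euchromatinEvidence named list of \code{GRanges} (QC only)
#' @return a \linkS4class{PeakClassLabels}
#' @export
classifyPeaks <- function(peaks, heterochromatinMarks,
                          euchromatinEvidence = list()) {
  stopifnot(is(peaks, "GRanges"), is(heterochromatinMarks, "GRanges"))
  het <- overlapsAny(.bare(peaks), .bare(heterochromatinMarks))
  labels <- factor(ifelse(het, "heterochromatic", "euchromatic"),
                   levels = c("euchromatic", "heterochromatic"))
  n <- length(peaks)
  fractions <- if (n) c(euchromatic = mean(!het), heterochromatic = mean(het))
               else c(euchromatic = 0, heterochromatic = 0)
  qc <- vapply(euchromatinEvidence, function(ev)
    if (n) mean(overlapsAny(.bare(peaks), .bare(ev))) else NA_real_,
    numeric(1))
  new("PeakClassLabels", labels = labels, fractions = fractions, qc = qc)
}

#' Total bases covered by an interval set
#'
#' @param x a \code{GRanges}
#' @return total covered bases (union, each base counted once)
#' @export
coveredBases <- function(x) {
  sum(as.numeric(width(GenomicRanges::reduce(.bare(x)))))
}
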