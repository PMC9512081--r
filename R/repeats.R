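# Window-based repeat-family enrichment: the genome is tiled into
# non-overlapping fixed-size windows (trailing partial windows dropped,
# blacklist-overlapping windows removed), each window is flagged for overlap
# with the repeat family and with the peak set, and the per-family 2x2 table
# of window counts feeds the Fisher/BH machinery. Windows -- not bases, not
# peaks -- are the exchangeable unit.

# Per-chromosome window overlap flags as an Rle: window i (0-based) is
# flagged when >= minOverlap of its bases are covered by gr.
.windowFlags <- function(gr, chrom, L, window, minOverlap) {
  nwin <- L %/% window
  sub <- gr[as.character(seqnames(gr)) == chrom]
  if (length(sub) == 0) return(Rle(FALSE, nwin))
  cv <- GenomicRanges::coverage(GenomicRanges::reduce(.bare(sub)),
                                width = L)[[chrom]]
  sums <- viewSums(Views(cv, successiveIRanges(rep.int(window, nwin))))
  Rle(sums >= minOverlap)
}

#' Repeat-family enrichment in genomic windows
#'
#' Tiles the genome into non-overlapping \code{window}-bp windows (as
#' \code{\link{tileWindows}}: trailing partial windows dropped, windows
#' overlapping the blacklist removed), flags each retained window for
#' overlap with each repeat family and with the peak set, and tests each
#' family's 2x2 window-count table (a = family & peak, b = family only,
#' c = peak only, d = neither). BH correction is applied across the families
#' tested in this call.
#'
#' @param peaks \code{GRanges}
#' @param repeats named list or \code{GRangesList}, one element per family
#' @param genome \code{Seqinfo}
#' @param blacklist optional \code{GRanges} of excluded regions
#' @param window window size in bp (default 100)
#' @param minOverlap minimum overlapping bases for a window to count as
#'   hit (default 1, i.e. any overlap)
#' @param peakClass label recorded in the \code{peak_class} column
#' @return data.frame: family, peak_class, a, b, c, d, n_windows,
#'   odds_ratio, p_value, q_value
#' @export
repeatFamilyEnrichment <- function(peaks, repeats, genome, blacklist = NULL,
                                   window = 100, minOverlap = 1,
                                   peakClass = "all") {
  stopifnot(is(genome, "Seqinfo"), window >= 1, minOverlap >= 1)
  repeats <- .asGRList(repeats, "repeats")
  if (is.null(names(repeats)) || any(!nzchar(names(repeats))))
    stop("'repeats' must be named by family")
  window <- as.integer(window)
  sl <- seqlengths(genome)
  fams <- names(repeats)
  acc <- matrix(0, nrow = length(fams), ncol = 4,
                dimnames = list(fams, c("a", "b", "c", "d")))
  totalWindows <- 0
  for (chrom in names(sl)) {
    L <- sl[[chrom]]
    if (L < window) next
    keep <- if (is.null(blacklist) || length(blacklist) == 0)
      Rle(TRUE, L %/% window)
    else !.windowFlags(blacklist, chrom, L, window, 1L)
    nKeep <- sum(keep)
    if (nKeep == 0) next
    totalWindows <- totalWindows + nKeep
    peakW <- .windowFlags(peaks, chrom, L, window, minOverlap) & keep
    nPeak <- sum(peakW)
    for (fam in fams) {
      famW <- .windowFlags(repeats[[fam]], chrom, L, window, minOverlap) & keep
      aa <- sum(famW & peakW)
      acc[fam, "a"] <- acc[fam, "a"] + aa
      acc[fam, "b"] <- acc[fam, "b"] + (sum(famW) - aa)
      acc[fam, "c"] <- acc[fam, "c"] + (nPeak - aa)
      acc[fam, "d"] <- acc[fam, "d"] + (nKeep - sum(famW) - nPeak + aa)
    }
  }
  if (totalWindows == 0)
    stop("no windows retained after blacklist exclusion")
  res <- data.frame(family = fams, peak_class = peakClass,
                    a = acc[, "a"], b = acc[, "b"],
                    c = acc[, "c"], d = acc[, "d"],
                    n_windows = totalWindows, row.names = NULL)
  res$odds_ratio <- oddsRatio(res$a, res$b, res$c, res$d)
  res$p_value <- fisherExactTwoSided(res$a, res$b, res$c, res$d)
  res$q_value <- bhAdjust(res$p_value)
  res
}

#' Repeat enrichment split by peak class
#'
#' Runs \code{\link{repeatFamilyEnrichment}} once per chromatin class on
#' that class's peak subset; BH correction is applied within each class's
#' family of tests. An empty class yields an empty result with a message.
#'
#' @param peaks \code{GRanges}
#' @param classLabels \linkS4class{PeakClassLabels} for \code{peaks}
#' @param repeats named list or \code{GRangesList} of repeat families
#' @param genome \code{Seqinfo}
#' @param blacklist optional \code{GRanges}
#' @param window window size in bp
#' @param minOverlap minimum overlapping bases per window
#' @return named list of data.frames, one per class
#' @export
enrichmentByPeakClass <- function(peaks, classLabels, repeats, genome,
                                  blacklist = NULL, window = 100,
                                  minOverlap = 1) {
  stopifnot(is(classLabels, "PeakClassLabels"),
            length(peakClasses(classLabels)) == length(peaks))
  labs <- peakClasses(classLabels)
  out <- list()
  for (cl in levels(labs)) {
    sub <- peaks[labs == cl]
    if (length(sub) == 0) {
      message("enrichmentByPeakClass: no ", cl, " peaks; empty result")
      out[[cl]] <- data.frame(family = character(0),
                              peak_class = character(0),
                              a = integer(0), b = integer(0),
                              c = integer(0), d = integer(0),
                              n_windows = integer(0),
                              odds_ratio = numeric(0),
                              p_value = numeric(0), q_value = numeric(0))
    } else {
      out[[cl]] <- repeatFamilyEnrichment(sub, repeats, genome,
                                          blacklist = blacklist,
                                          window = window,
                                          minOverlap = minOverlap,
                                          peakClass = cl)
    }
  }
  out
}
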