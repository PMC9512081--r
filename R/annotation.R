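# Region-to-gene association rules: gene-body proximity within a distance
# cutoff (the 50 kb rule), gene extension by a flank (the +/-100 kb rule),
# and single-nearest-TSS assignment with signed, orientation-aware distance
# (the GREAT-style convention). Proximity is anchored on the gene BODY;
# nearest-gene assignment is anchored on the TSS. Both conventions are
# deliberate and documented where used.

#' Gene ids proximal to any peak
#'
#' A gene is proximal when some peak on the same chromosome overlaps (by at
#' least one base) the gene body extended by \code{maxDistance} bp on both
#' sides. With \code{maxDistance = 0} this is exactly body overlap, and for
#' every cutoff it coincides with flagging the \code{\link{extendGenes}}
#' intervals that overlap peaks -- the two formulations the proximity rule
#' must keep interchangeable.
#'
#' @param peaks \code{GRanges}
#' @param genes \linkS4class{GeneTable}
#' @param maxDistance proximity cutoff in bp (default 50 kb)
#' @return character vector of proximal gene ids (in gene-table order)
#' @export
proximalGeneIds <- function(peaks, genes, maxDistance = 50000) {
  stopifnot(is(genes, "GeneTable"), maxDistance >= 0)
  if (length(peaks) == 0) return(character(0))
  gb <- geneBodies(genes)
  D <- as.integer(maxDistance)
  ext <- GRanges(as.character(seqnames(gb)),
                 IRanges(pmax(1L, start(gb) - D), end(gb) + D))
  pk <- GRanges(as.character(seqnames(peaks)), ranges(peaks))
  hit <- suppressWarnings(overlapsAny(ext, pk))
  geneIds(genes)[hit]
}

#' Extend gene bodies by a flank
#'
#' Widens each gene body by \code{flank} bp on both sides, clipped to the
#' chromosome. Overlap of a peak with the extended gene is equivalent to the
#' peak lying within \code{flank} bp of the gene body.
#'
#' @param genes \linkS4class{GeneTable}
#' @param flank extension in bp on each side (default 100 kb)
#' @param genome optional \code{Seqinfo} used for clipping (defaults to the
#'   gene table's own seqinfo)
#' @return \code{GRanges} named by gene_id, with a \code{gene_id} column
#' @export
extendGenes <- function(genes, flank = 100000, genome = NULL) {
  stopifnot(is(genes, "GeneTable"), flank >= 0)
  gr <- geneBodies(genes)
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
  }
  sl <- seqlengths(gr)
  if (anyNA(sl)) stop("chromosome lengths are required to clip extensions")
  newStart <- pmax(1L, start(gr) - as.integer(flank))
  newEnd <- pmin(sl[as.character(seqnames(gr))], end(gr) + as.integer(flank))
  out <- GRanges(seqnames(gr), IRanges(newStart, newEnd),
                 seqinfo = seqinfo(gr))
  names(out) <- geneIds(genes)
  mcols(out)$gene_id <- geneIds(genes)
  out
}

#' Assign each peak to its single nearest gene TSS
#'
#' The peak is represented by its midpoint (integer floor in 0-based
#' coordinates); the gene by its strand-aware TSS (0-based: \code{start} for
#' \code{+} genes, \code{end - 1} for \code{-} genes). The nearest TSS within
#' \code{maxDistance} is assigned (ties broken deterministically by the
#' interval engine); peaks with no TSS in range are unassigned. The signed
#' distance is negative when the peak midpoint lies upstream of the TSS in
#' the gene's orientation.
#'
#' @param peaks \code{GRanges}
#' @param genes \linkS4class{GeneTable}
#' @param maxDistance assignment cutoff in bp (default 1,000 kb, the
#'   single-nearest-gene convention)
#' @return data.frame with one row per peak: \code{peak} (index),
#'   \code{gene_id} (\code{NA} when unassigned), \code{distance} (signed bp)
#' @export
nearestGeneTss <- function(peaks, genes, maxDistance = 1e6) {
  stopifnot(is(peaks, "GRanges"), is(genes, "GeneTable"))
  n <- length(peaks)
  out <- data.frame(peak = seq_len(n), gene_id = NA_character_,
                    distance = NA_real_)
  if (n == 0 || length(genes) == 0) return(out)
  mid0 <- (start(peaks) - 1 + end(peaks)) %/% 2
  st <- as.character(strand(genes))
  tss0 <- ifelse(st == "+", start(genes) - 1, end(genes) - 1)
  midGR <- GRanges(seqnames(peaks), IRanges(mid0 + 1, width = 1))
  tssGR <- GRanges(seqnames(genes), IRanges(tss0 + 1, width = 1))
  sq <- unique(c(as.character(seqnames(midGR)), as.character(seqnames(tssGR))))
  seqlevels(midGR) <- sq
  seqlevels(tssGR) <- sq
  h <- GenomicRanges::nearest(midGR, tssGR, select = "arbitrary",
                              ignore.strand = TRUE)
  ok <- !is.na(h)
  dAbs <- abs(mid0[ok] - tss0[h[ok]])
  inRange <- dAbs <= maxDistance
  idx <- which(ok)[inRange]
  g <- h[ok][inRange]
  signed <- ifelse(st[g] == "+", mid0[idx] - tss0[g], tss0[g] - mid0[idx])
  out$gene_id[idx] <- geneIds(genes)[g]
  out$distance[idx] <- signed
  out
}

#' Histogram of signed TSS distances
#'
#' Bins are half-open \code{[edge_i, edge_{i+1})} on the signed distance
#' (upstream negative). Unassigned peaks, and assigned peaks whose distance
#' falls outside the edge range, are counted under \code{unassigned}; counts
#' always sum to the number of input peaks.
#'
#' @param assignments data.frame from \code{\link{nearestGeneTss}}
#' @param binEdges strictly increasing numeric vector of signed bp edges
#' @return list with \code{binStart}, \code{binEnd}, \code{count} (parallel
#'   vectors) and \code{unassigned}
#' @export
tssDistanceHistogram <- function(assignments, binEdges) {
  if (is.unsorted(binEdges, strictly = TRUE) || length(binEdges) < 2)
    stop("'binEdges' must be strictly increasing with length >= 2")
  d <- assignments$distance
  assigned <- !is.na(d)
  bin <- findInterval(d[assigned], binEdges)
  inRange <- bin >= 1 & d[assigned] < binEdges[length(binEdges)]
  counts <- tabulate(bin[inRange], nbins = length(binEdges) - 1)
  list(binStart = binEdges[-length(binEdges)],
       binEnd = binEdges[-1],
       count = counts,
       unassigned = nrow(assignments) - sum(inRange))
}
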