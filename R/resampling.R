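# Empirical-p machinery: the matched-size gene-set resampling test and the
# multi-set interval-overlap permutation test. Both use the add-one
# convention (k + 1) / (R + 1), so a reported p is never 0 and "p < 0.001
# with R = 1000" is attainable exactly as 1/1001; the raw exceedance count k
# is kept so a k/R convention can be recovered.

#' Add-one empirical p-value
#'
#' \code{p = (1 + #\{null >= observed\}) / (1 + R)} for
#' \code{direction = "greater"} (ties count against the observation), and
#' symmetrically with \code{<=} for \code{"less"}. Never returns 0; the
#' smallest attainable value is \code{1/(R+1)}.
#'
#' @param observed observed statistic
#' @param null numeric vector of null statistics (non-empty)
#' @param direction \code{"greater"} or \code{"less"}
#' @return the empirical p-value
#' @examples
#' empiricalPvalue(10, rep(1, 1000)) # 1/1001
#' @export
empiricalPvalue <- function(observed, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(null)) stop("'null' must be non-empty")
  k <- if (direction == "greater") sum(null >= observed)
       else sum(null <= observed)
  (1 + k) / (1 + length(null))
}

#' Gene-set resampling test of peak proximity
#'
#' The observed statistic is the percentage of target-set genes whose bodies
#' lie within \code{maxDistance} of a peak (the same proximity rule as
#' \code{\link{proximalGeneIds}}). The null distribution is built from
#' \code{R} random gene sets drawn uniformly without replacement from the
#' background pool, each scored with the same statistic; the empirical p is
#' add-one, direction greater. Deterministic given \code{seed}.
#'
#' @param targetSet character vector of target gene ids
#' @param backgroundPool character vector of gene ids to resample from
#'   (e.g. all expressed genes); must be part of the gene table
#' @param peaks \code{GRanges}
#' @param genes \linkS4class{GeneTable}
#' @param maxDistance proximity cutoff in bp (default 50 kb)
#' @param R number of resamples (default 1000)
#' @param matchSize \code{"target"} to draw sets the size of the target set
#'   (the default, a matched-size null) or an integer for fixed-size draws
#'   (e.g. 512)
#' @param seed integer seed
#' @return a \linkS4class{ResamplingResult}; the observed statistic and null
#'   values are percentages in [0, 100]
#' @export
geneSetResamplingTest <- function(targetSet, backgroundPool, peaks, genes,
                                  maxDistance = 50000, R = 1000,
                                  matchSize = "target", seed) {
  stopifnot(is(genes, "GeneTable"), R >= 1)
  seed <- .checkSeed(seed)
  ids <- geneIds(genes)
  if (any(!targetSet %in% ids))
    stop("targetSet contains gene ids absent from the gene table")
  if (any(!backgroundPool %in% ids))
    stop("backgroundPool contains gene ids absent from the gene table")
  size <- if (identical(matchSize, "target")) length(targetSet)
          else as.integer(matchSize)
  if (size > length(backgroundPool))
    stop("resample size (", size, ") exceeds the background pool (",
         length(backgroundPool), ")")
  prox <- proximalGeneIds(peaks, genes, maxDistance)
  observed <- 100 * mean(targetSet %in% prox)
  poolProx <- backgroundPool %in% prox
  nulls <- withr::with_seed(seed, vapply(seq_len(R), function(i)
    100 * mean(poolProx[sample.int(length(poolProx), size)]), numeric(1)))
  k <- sum(nulls >= observed)
  new("ResamplingResult", observed = observed, nullValues = nulls,
      R = as.integer(R), k = as.integer(k),
      empiricalP = (1 + k) / (1 + R), seed = seed, direction = "greater")
}

# ---- fast per-chromosome machinery for the permutation null ----------------

# Count maximal regions with per-set-deduplicated coverage >= minSupport,
# given 0-based starts/ends grouped by set. Within a set, overlapping
# intervals are unioned first so each set contributes at most 1 per base.
.consensusCount <- function(startsBySet, endsBySet, minSupport) {
  evPos <- vector("list", 2 * length(startsBySet))
  evDel <- vector("list", 2 * length(startsBySet))
  j <- 0
  for (i in seq_along(startsBySet)) {
    s <- startsBySet[[i]]
    if (!length(s)) next
    e <- endsBySet[[i]]
    o <- order(s)
    s <- s[o]; e <- e[o]
    ecm <- cummax(e)
    grp <- cumsum(c(TRUE, s[-1] > ecm[-length(ecm)]))
    us <- s[!duplicated(grp)]
    ue <- vapply(split(ecm, grp), function(z) z[length(z)], numeric(1))
    j <- j + 1
    evPos[[j]] <- c(us, ue)
    evDel[[j]] <- c(rep(1L, length(us)), rep(-1L, length(ue)))
  }
  if (j == 0) return(0L)
  pos <- unlist(evPos[seq_len(j)], use.names = FALSE)
  del <- unlist(evDel[seq_len(j)], use.names = FALSE)
  o <- order(pos)
  pos <- pos[o]; del <- del[o]
  cs <- cumsum(del)
  lastOfRun <- c(pos[-1] != pos[-length(pos)], TRUE)
  covered <- cs[lastOfRun] >= minSupport
  sum(diff(c(FALSE, covered)) == 1)
}

# One shuffled replicate of every set on one chromosome: uniform starts with
# rejection against the merged excluded intervals (0-based [es, ee)).
.shuffleStarts <- function(widths, L, es, ee, maxAttempts) {
  span <- L - widths + 1
  s <- floor(stats::runif(length(widths)) * span)
  if (length(es)) {
    for (att in seq_len(maxAttempts)) {
      j <- findInterval(s, es)
      bad <- (j >= 1 & ee[pmax(j, 1)] > s) |
             (j < length(es) & es[j + 1] < s + widths)
      if (!any(bad)) break
      if (att == maxAttempts)
        stop("permutation shuffle: rejection cap reached")
      s[bad] <- floor(stats::runif(sum(bad)) * span[bad])
    }
  }
  s
}

#' Permutation test for multi-set interval overlap
#'
#' The observed statistic is the number of consensus loci (maximal regions
#' supported by at least \code{minSupport} of the sets at the base level, as
#' in \code{\link{consensusPeaks}}). The null shuffles every set
#' independently -- each interval re-placed uniformly on its own chromosome,
#' length preserved, avoiding \code{excluded} -- and recounts, \code{R}
#' times. Empirical p is add-one, direction greater. Deterministic given
#' \code{seed}; the draw order is fixed (replicates outer, chromosomes
#' inner, sets innermost).
#'
#' @param sets list (or \code{GRangesList}) of \code{GRanges}
#' @param genome \code{Seqinfo}
#' @param excluded optional \code{GRanges} the shuffled intervals must avoid
#' @param minSupport per-base support required (default all sets)
#' @param R number of permutations (default 1000)
#' @param seed integer seed
#' @param maxAttempts rejection-sampling cap per interval per replicate
#' @return a \linkS4class{PermutationResult}
#' @export
multiwayOverlapPermutationTest <- function(sets, genome, excluded = NULL,
                                           minSupport = length(sets),
                                           R = 1000, seed,
                                           maxAttempts = 1000L) {
  sets <- .asGRList(sets)
  stopifnot(is(genome, "Seqinfo"), R >= 1)
  seed <- .checkSeed(seed)
  observed <- length(consensusPeaks(sets, minSupport = minSupport,
                                    genome = genome))
  sl <- seqlengths(genome)
  exc <- if (is.null(excluded)) GRanges() else
    GenomicRanges::reduce(.bare(excluded))
  # Pre-extract plain vectors per chromosome to keep the R x sets x chrom
  # loop cheap.
  chroms <- names(sl)
  widthsBy <- lapply(chroms, function(ch) lapply(sets, function(g) {
    w <- width(g)[as.character(seqnames(g)) == ch]
    if (any(w > sl[[ch]]))
      stop("an interval on ", ch, " is longer than the chromosome")
    w
  }))
  excBy <- lapply(chroms, function(ch) {
    e <- exc[as.character(seqnames(exc)) == ch]
    list(es = start(e) - 1, ee = end(e))
  })
  nulls <- withr::with_seed(seed, vapply(seq_len(R), function(r) {
    total <- 0L
    for (ci in seq_along(chroms)) {
      wl <- widthsBy[[ci]]
      if (!any(lengths(wl) > 0)) next
      eb <- excBy[[ci]]
      ss <- vector("list", length(wl))
      ee2 <- vector("list", length(wl))
      for (si in seq_along(wl)) {
        w <- wl[[si]]
        if (!length(w)) { ss[[si]] <- numeric(0); ee2[[si]] <- numeric(0); next }
        s <- .shuffleStarts(w, sl[[chroms[ci]]], eb$es, eb$ee, maxAttempts)
        ss[[si]] <- s
        ee2[[si]] <- s + w
      }
      total <- total + .consensusCount(ss, ee2, minSupport)
    }
    as.numeric(total)
  }, numeric(1)))
  k <- sum(nulls >= observed)
  new("PermutationResult", observed = as.numeric(observed),
      nullValues = nulls, R = as.integer(R), k = as.integer(k),
      empiricalP = (1 + k) / (1 + R), seed = seed, direction = "greater")
}
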