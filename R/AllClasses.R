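#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame Rle runValue metadata metadata<-
#' @importFrom IRanges IRanges Views successiveIRanges viewSums slice
#'   ranges overlapsAny subsetByOverlaps
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqlevels seqinfo
#'   seqinfo<- seqlevels<- genome
#' @importFrom BiocGenerics start end width strand strand<- sort
NULL

#' Gene models with identifiers and biotypes
#'
#' A \code{GeneTable} is a \linkS4class{GRanges} of gene bodies (one range per
#' gene) carrying two required metadata columns: \code{gene_id} (unique
#' character identifiers) and \code{biotype} (e.g. \code{"protein_coding"}).
#' Strand must be \code{+} or \code{-} for every gene, because the
#' transcription start site used by \code{\link{nearestGeneTss}} is
#' strand-dependent.
#'
#' @seealso \code{\link{readGenes}}, \code{\link{proximalGeneIds}},
#'   \code{\link{nearestGeneTss}}
#' @export
setClass("GeneTable", contains = "GRanges")

setValidity("GeneTable", function(object) {
  mc <- mcols(object)
  if (!all(c("gene_id", "biotype") %in% colnames(mc)))
    return("metadata columns 'gene_id' and 'biotype' are required")
  ids <- mc$gene_id
  if (anyNA(ids) || !is.character(ids))
    return("'gene_id' must be character without NA")
  if (anyDuplicated(ids))
    return(paste0("duplicated gene_id: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (any(!as.character(strand(object)) %in% c("+", "-")))
    return("every gene must have strand '+' or '-'")
  TRUE
})

#' Construct a GeneTable
#'
#' @param gr a \code{GRanges} with metadata columns \code{gene_id} and
#'   (optionally) \code{biotype}; missing biotypes default to
#'   \code{"protein_coding"}.
#' @return a \linkS4class{GeneTable}
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000),
#'                              strand = "+", gene_id = "gA")
#' GeneTable(gr)
#' @export
GeneTable <- function(gr) {
  if (!is(gr, "GRanges")) stop("'gr' must be a GRanges")
  if (is.null(mcols(gr)$biotype))
    mcols(gr)$biotype <- rep("protein_coding", length(gr))
  new("GeneTable", gr)
}

#' @describeIn GeneTable gene identifiers, in table order
#' @param x a \code{GeneTable}
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "GeneTable"))
  mcols(x)$gene_id
}

#' @describeIn GeneTable gene bodies as a plain \code{GRanges} (identifiers
#'   kept as names)
#' @export
geneBodies <- function(x) {
  stopifnot(is(x, "GeneTable"))
  gr <- granges(x)
  names(gr) <- geneIds(x)
  gr
}

#' Piecewise-constant coverage track
#'
#' A \code{SignalTrack} is a \linkS4class{GRanges} with a numeric
#' \code{score} column under bedGraph semantics: non-overlapping intervals
#' within each chromosome, finite non-negative values, and every base not
#' covered by an interval reading as 0. Sequence lengths must be set so that
#' coverage vectors are well defined.
#'
#' @seealso \code{\link{readBedgraph}}, \code{\link{binLog2Ratio}}
#' @export
setClass("SignalTrack", contains = "GRanges")

setValidity("SignalTrack", function(object) {
  sc <- mcols(object)$score
  if (is.null(sc) || !is.numeric(sc))
    return("a numeric 'score' metadata column is required")
  if (length(sc) && (anyNA(sc) || any(!is.finite(sc)) || any(sc < 0)))
    return("scores must be finite and >= 0")
  if (!isDisjoint(object, ignore.strand = TRUE))
    return("track intervals overlap within a chromosome")
  if (anyNA(seqlengths(object)))
    return("seqlengths must be set for all chromosomes")
  if (length(object) && any(end(object) > seqlengths(object)[as.character(seqnames(object))]))
    return("track intervals exceed chromosome lengths")
  TRUE
})

#' Construct a SignalTrack
#'
#' @param gr a \code{GRanges} with a numeric \code{score} column
#' @param genome optional \code{Seqinfo} supplying chromosome lengths
#' @return a \linkS4class{SignalTrack}
#' @export
SignalTrack <- function(gr, genome = NULL) {
  if (!is(gr, "GRanges")) stop("'gr' must be a GRanges")
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
  }
  new("SignalTrack", sort(gr, ignore.strand = TRUE))
}

setClassUnion("SignalTrackOrNULL", c("SignalTrack", "NULL"))

#' Binned two-condition log2 coverage ratio
#'
#' Bins are the equal-width windows of \code{\link{tileWindows}} and carry a
#' \code{score} metadata column holding
#' \code{log2((meanA + pseudocount) / (meanB + pseudocount))} per bin.
#'
#' @slot binSize bin width in bp
#' @slot pseudocount the pseudocount added to both bin means
#' @seealso \code{\link{binLog2Ratio}}, \code{\link{meanOverIntervals}}
#' @export
setClass("BinnedLogRatio", contains = "GRanges",
         representation(binSize = "integer", pseudocount = "numeric"))

setValidity("BinnedLogRatio", function(object) {
  sc <- mcols(object)$score
  if (is.null(sc) || !is.numeric(sc)) return("numeric 'score' column required")
  if (length(sc) && any(!is.finite(sc))) return("bin values must be finite")
  if (length(object) && !all(width(object) == object@binSize))
    return("all bins must have width binSize")
  TRUE
})

#' Euchromatic/heterochromatic peak classification
#'
#' Produced by \code{\link{classifyPeaks}}. Each input peak receives exactly
#' one label; \code{fractions} sum to 1 over the two classes and \code{qc}
#' reports, for each supplied euchromatin-evidence set, the fraction of peaks
#' overlapping it (reported only, never used for the dichotomy).
#'
#' @slot labels factor with levels \code{euchromatic}, \code{heterochromatic},
#'   one per peak
#' @slot fractions named numeric of length 2, summing to 1
#' @slot qc named numeric, one overlap fraction per evidence set
#' @export
setClass("PeakClassLabels",
         representation(labels = "factor", fractions = "numeric",
                        qc = "numeric"))

setValidity("PeakClassLabels", function(object) {
  if (!identical(levels(object@labels), c("euchromatic", "heterochromatic")))
    return("labels must have levels euchromatic, heterochromatic")
  if (anyNA(object@labels)) return("every peak must be labeled")
  if (length(object@labels) &&
      abs(sum(object@fractions) - 1) > 1e-12)
    return("class fractions must sum to 1")
  TRUE
})

#' @describeIn PeakClassLabels per-peak class labels
#' @param x a \code{PeakClassLabels}
#' @export
peakClasses <- function(x) {
  stopifnot(is(x, "PeakClassLabels"))
  x@labels
}

#' @describeIn PeakClassLabels named fractions of peaks per class
#' @export
classFractions <- function(x) {
  stopifnot(is(x, "PeakClassLabels"))
  x@fractions
}

#' Result of an empirical-p resampling or permutation test
#'
#' Both classes store the observed statistic, the null values, the raw
#' exceedance count \code{k} and the add-one empirical p-value
#' \code{(k + 1) / (R + 1)}, which can never be 0 (floor \code{1/(R+1)}).
#'
#' @slot observed observed statistic
#' @slot nullValues the \code{R} null statistics
#' @slot R number of resamples/permutations
#' @slot k number of null values at least as extreme as the observation
#'   (ties count against the observation)
#' @slot empiricalP add-one empirical p-value
#' @slot seed the seed that makes the result reproducible
#' @slot direction \code{"greater"} or \code{"less"}
#' @export
setClass("ResamplingResult",
         representation(observed = "numeric", nullValues = "numeric",
                        R = "integer", k = "integer", empiricalP = "numeric",
                        seed = "integer", direction = "character"))

#' @rdname ResamplingResult-class
#' @export
setClass("PermutationResult", contains = "ResamplingResult")

.validEmpirical <- function(object) {
  if (length(object@nullValues) != object@R)
    return("length(nullValues) must equal R")
  lo <- 1 / (object@R + 1)
  if (object@empiricalP < lo - 1e-12 || object@empiricalP > 1 + 1e-12)
    return("empirical p must lie in [1/(R+1), 1]")
  if (!object@direction %in% c("greater", "less"))
    return("direction must be 'greater' or 'less'")
  TRUE
}
setValidity("ResamplingResult", .validEmpirical)

#' @describeIn ResamplingResult the add-one empirical p-value
#' @param x a result object
#' @export
empiricalP <- function(x) {
  stopifnot(is(x, "ResamplingResult"))
  x@empiricalP
}

#' @describeIn ResamplingResult the observed statistic
#' @export
observedStatistic <- function(x) {
  stopifnot(is(x, "ResamplingResult"))
  x@observed
}

#' @describeIn ResamplingResult the null statistics (length \code{R})
#' @export
nullValues <- function(x) {
  stopifnot(is(x, "ResamplingResult"))
  x@nullValues
}

#' A complete synthetic regulatory-genomics study
#'
#' Container produced by \code{\link{generateStudy}}: a coordinate frame
#' (\code{Seqinfo}), non-overlapping gene models, a planted target gene set
#' plus decoy sets, peak tracks with planted proximity and three-way
#' co-occupancy, repeat-family annotations with one planted within-peak
#' excess, a blacklist, and WT/KO coverage tracks with planted fold changes
#' over the down- and up-regulated gene bodies. The \code{manifest} records
#' every planted truth so recovery can be audited.
#'
#' @slot genome \code{Seqinfo} coordinate frame
#' @slot genes \linkS4class{GeneTable}
#' @slot geneSets named list of gene-id character vectors (first the target
#'   set, then decoys)
#' @slot targetSet gene ids of the planted target set
#' @slot backgroundPool gene ids eligible for resampling draws (the universe)
#' @slot peaks named \code{GRangesList} of peak tracks; the first track
#'   carries the planted gene proximity
#' @slot repeats named \code{GRangesList}, one element per repeat family
#' @slot blacklist \code{GRanges} of excluded regions
#' @slot wt,ko \linkS4class{SignalTrack} coverage (or \code{NULL} when the
#'   signal component was not generated)
#' @slot deClasses named character mapping gene_id to
#'   \code{down}/\code{up}/\code{unchanged}
#' @slot manifest list of planted truths and realised counts
#' @slot config the \code{\link{studyConfig}} used
#' @slot seed master seed
#' @seealso \code{\link{generateStudy}}, \code{\link{nullVariant}},
#'   \code{\link{writeStudy}}
#' @export
setClass("StudyBundle",
         representation(genome = "Seqinfo", genes = "GeneTable",
                        geneSets = "list", targetSet = "character",
                        backgroundPool = "character",
                        peaks = "GRangesList", repeats = "GRangesList",
                        blacklist = "GRanges", wt = "SignalTrackOrNULL",
                        ko = "SignalTrackOrNULL", deClasses = "character",
                        manifest = "list", config = "list", seed = "integer"))

setValidity("StudyBundle", function(object) {
  if (!all(object@targetSet %in% geneIds(object@genes)))
    return("targetSet contains unknown gene ids")
  if (!all(object@backgroundPool %in% geneIds(object@genes)))
    return("backgroundPool contains unknown gene ids")
  TRUE
})

#' @describeIn StudyBundle the \code{Seqinfo} coordinate frame
#' @param x a \code{StudyBundle}
#' @export
studyGenome <- function(x) { stopifnot(is(x, "StudyBundle")); x@genome }

#' @describeIn StudyBundle the gene models
#' @export
studyGenes <- function(x) { stopifnot(is(x, "StudyBundle")); x@genes }

#' @describeIn StudyBundle peak tracks; \code{track = NULL} returns the
#'   full \code{GRangesList}
#' @param track track name or index, or NULL for all tracks
#' @export
studyPeaks <- function(x, track = NULL) {
  stopifnot(is(x, "StudyBundle"))
  if (is.null(track)) x@peaks else x@peaks[[track]]
}

#' @describeIn StudyBundle repeat annotation, one GRanges per family
#' @export
studyRepeats <- function(x) { stopifnot(is(x, "StudyBundle")); x@repeats }

#' @describeIn StudyBundle blacklist regions
#' @export
studyBlacklist <- function(x) { stopifnot(is(x, "StudyBundle")); x@blacklist }

#' @describeIn StudyBundle the planted target gene set
#' @export
studyTargetSet <- function(x) { stopifnot(is(x, "StudyBundle")); x@targetSet }

#' @describeIn StudyBundle the resampling background pool (gene universe)
#' @export
studyBackgroundPool <- function(x) {
  stopifnot(is(x, "StudyBundle")); x@backgroundPool
}

#' @describeIn StudyBundle named list of gene sets (target first)
#' @export
studyGeneSets <- function(x) { stopifnot(is(x, "StudyBundle")); x@geneSets }

#' @describeIn StudyBundle WT or KO coverage track
#' @param which \code{"wt"} or \code{"ko"}
#' @export
studySignal <- function(x, which = c("wt", "ko")) {
  stopifnot(is(x, "StudyBundle"))
  if (match.arg(which) == "wt") x@wt else x@ko
}

#' @describeIn StudyBundle gene_id to down/up/unchanged class map
#' @export
studyDeClasses <- function(x) { stopifnot(is(x, "StudyBundle")); x@deClasses }

#' @describeIn StudyBundle manifest of planted truths
#' @export
studyManifest <- function(x) { stopifnot(is(x, "StudyBundle")); x@manifest }

#' @describeIn StudyBundle the generating configuration
#' @export
bundleConfig <- function(x) { stopifnot(is(x, "StudyBundle")); x@config }

setMethod("show", "GeneTable", function(object) {
  cat(class(object), "with", length(object), "genes on",
      length(unique(as.character(seqnames(object)))), "chromosome(s)\n")
  bt <- table(mcols(object)$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = ", "), "\n")
})

setMethod("show", "PeakClassLabels", function(object) {
  n <- length(object@labels)
  cat("PeakClassLabels for", n, "peaks\n")
  f <- object@fractions
  cat(sprintf("  euchromatic: %.1f%%  heterochromatic: %.1f%%\n",
              100 * f[["euchromatic"]], 100 * f[["heterochromatic"]]))
  if (length(object@qc))
    cat("  QC overlap fractions:",
        paste(names(object@qc), sprintf("%.3f", object@qc),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ResamplingResult", function(object) {
  cat(class(object), sprintf(
    ": observed = %.4g, R = %d, k = %d, empirical p = %.4g (%s)\n",
    object@observed, object@R, object@k, object@empiricalP,
    object@direction))
})

setMethod("show", "StudyBundle", function(object) {
  cat("StudyBundle (seed", object@seed, ")\n")
  cat("  genome:", length(seqlevels(object@genome)), "chromosomes,",
      sprintf("%.1f Mb", sum(as.numeric(seqlengths(object@genome))) / 1e6), "\n")
  cat("  genes:", length(object@genes),
      "| target set:", length(object@targetSet), "\n")
  cat("  peak tracks:", paste(names(object@peaks),
                              lengths(object@peaks), sep = "=",
                              collapse = ", "), "\n")
  cat("  repeat families:", paste(names(object@repeats), collapse = ", "), "\n")
  cat("  signal:", if (is.null(object@wt)) "absent" else
    sprintf("WT/KO, bin %d bp", object@config$signal$bin), "\n")
})
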