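# Readers and writers for the plain-text formats the package consumes:
# BED3/BED6 (0-based half-open), chrom.sizes, gene-set TSV, repeat BED,
# and 4-column bedGraph. Readers validate aggressively and report the
# offending line so malformed inputs fail loudly rather than silently.

#' Build a genome coordinate frame
#'
#' @param names chromosome names (unique)
#' @param lengths chromosome lengths in bp (>= 1)
#' @return a \code{Seqinfo} in the given, stable order
#' @examples
#' genomeSpec(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genomeSpec <- function(names, lengths) {
  if (anyDuplicated(names)) stop("chromosome names must be unique")
  lengths <- as.integer(lengths)
  if (anyNA(lengths) || any(lengths < 1))
    stop("chromosome lengths must be integers >= 1")
  Seqinfo(seqnames = as.character(names), seqlengths = lengths)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path tab-separated file: chromosome name, length
#' @return a \code{Seqinfo}
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genomeSpec(df$chrom, df$length)
}

# Tokenize a BED-like file, skipping comment/track lines but remembering
# original line numbers for error messages.
.readTabLines <- function(path, minFields, what) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < minFields))
    stop(what, ": line ", idx[which(nf < minFields)[1]], " has fewer than ",
         minFields, " tab-separated fields")
  list(fields = fields, lineNo = idx)
}

.parseCoord <- function(x, lineNo, what, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v) | v < 0
  if (any(bad))
    stop(what, ": line ", lineNo[which(bad)[1]],
         " has a malformed ", col, " coordinate")
  v
}

#' Read a BED3/BED6 file of intervals
#'
#' Coordinates are interpreted as 0-based half-open (BED convention) and
#' stored as a sorted \code{GRanges} (1-based closed, the GenomicRanges
#' convention). Name, score and strand columns are kept when present.
#'
#' @param path BED file (tab-separated, >= 3 columns; \code{#}, \code{track}
#'   and \code{browser} lines are skipped)
#' @param genome optional \code{Seqinfo}; when given, chromosomes must be
#'   known and intervals must fit
#' @param label optional label stored in \code{metadata(x)$label}
#' @return a sorted \code{GRanges}
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100", p)
#' readBed(p)
#' @export
readBed <- function(path, genome = NULL, label = NULL) {
  tl <- .readTabLines(path, 3L, "readBed")
  f <- tl$fields; ln <- tl$lineNo
  n <- length(f)
  if (n == 0) {
    gr <- GRanges()
  } else {
    chrom <- vapply(f, `[[`, "", 1L)
    start0 <- .parseCoord(vapply(f, `[[`, "", 2L), ln, "readBed", "start")
    end0 <- .parseCoord(vapply(f, `[[`, "", 3L), ln, "readBed", "end")
    empty <- start0 >= end0
    if (any(empty))
      stop("readBed: line ", ln[which(empty)[1]],
           " has start >= end (empty interval)")
    if (!is.null(genome))
      .checkAgainstGenome(chrom, start0, end0, genome, "readBed")
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    nf <- lengths(f)
    if (all(nf >= 4L)) {
      nm <- vapply(f, `[[`, "", 4L)
      if (any(nm != ".")) mcols(gr)$name <- nm
    }
    if (all(nf >= 5L)) {
      sc <- vapply(f, `[[`, "", 5L)
      if (any(sc != "."))
        mcols(gr)$score <- suppressWarnings(as.numeric(sc))
    }
    if (all(nf >= 6L)) {
      st <- vapply(f, `[[`, "", 6L)
      bad <- !st %in% c("+", "-", ".")
      if (any(bad))
        stop("readBed: line ", ln[which(bad)[1]], " has an invalid strand")
      strand(gr) <- sub("^\\.$", "*", st)
    }
  }
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
  } else {
    seqlevels(gr) <- sort(seqlevels(gr))
  }
  gr <- sort(gr, ignore.strand = TRUE)
  if (!is.null(label)) metadata(gr)$label <- label
  gr
}

#' Write intervals as BED
#'
#' Writes BED6 when any of name/score/strand is informative, BED3 otherwise,
#' always in 0-based half-open coordinates. Round-trips with
#' \code{\link{readBed}}.
#'
#' @param x a \code{GRanges}
#' @param path output file
#' @return the path, invisibly
#' @export
writeBed <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x))
  nm <- mcols(x)$name
  sc <- mcols(x)$score
  st <- as.character(strand(x))
  if (!is.null(nm) || !is.null(sc) || any(st != "*")) {
    df$name <- if (is.null(nm)) rep(".", length(x)) else nm
    df$score <- if (is.null(sc)) rep(".", length(x)) else
      ifelse(is.na(sc), ".", format(sc, trim = TRUE, scientific = FALSE))
    df$strand <- sub("^\\*$", ".", st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6
#'
#' The BED name column carries the gene identifier; strand is required.
#' Biotypes default to \code{protein_coding} unless a two-column
#' (gene_id, biotype) TSV is supplied.
#'
#' @param path BED6 file of gene bodies
#' @param genome optional \code{Seqinfo}
#' @param biotypeMap optional path to a two-column TSV mapping gene_id to
#'   biotype; unmapped genes keep the default
#' @return a \linkS4class{GeneTable}
#' @export
readGenes <- function(path, genome = NULL, biotypeMap = NULL) {
  tl <- .readTabLines(path, 6L, "readGenes")
  f <- tl$fields; ln <- tl$lineNo
  chrom <- vapply(f, `[[`, "", 1L)
  start0 <- .parseCoord(vapply(f, `[[`, "", 2L), ln, "readGenes", "start")
  end0 <- .parseCoord(vapply(f, `[[`, "", 3L), ln, "readGenes", "end")
  if (any(start0 >= end0))
    stop("readGenes: line ", ln[which(start0 >= end0)[1]],
         " has start >= end")
  ids <- vapply(f, `[[`, "", 4L)
  if (anyDuplicated(ids))
    stop("readGenes: duplicated gene_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  st <- vapply(f, `[[`, "", 6L)
  if (any(!st %in% c("+", "-")))
    stop("readGenes: line ", ln[which(!st %in% c("+", "-"))[1]],
         " is missing a +/- strand")
  if (!is.null(genome))
    .checkAgainstGenome(chrom, start0, end0, genome, "readGenes")
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = st)
  mcols(gr)$gene_id <- ids
  mcols(gr)$biotype <- rep("protein_coding", length(gr))
  if (!is.null(biotypeMap)) {
    bm <- utils::read.table(biotypeMap, sep = "\t", header = FALSE,
                            col.names = c("gene_id", "biotype"),
                            colClasses = "character")
    hit <- match(ids, bm$gene_id)
    mcols(gr)$biotype[!is.na(hit)] <- bm$biotype[hit[!is.na(hit)]]
  }
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(genome)
    seqinfo(gr) <- genome
  }
  GeneTable(sort(gr, ignore.strand = TRUE))
}

#' Read gene-set membership from TSV
#'
#' @param path two-column TSV (set_name, gene_id); lines starting with
#'   \code{#} are skipped
#' @return named list of gene-id character vectors
#' @export
readGeneSets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("set_name", "gene_id"),
                          colClasses = "character")
  if (!nrow(df)) stop("readGeneSets: no gene-set records in ", path)
  lapply(split(df$gene_id, df$set_name), unique)
}

#' Read a family-labeled repeat annotation
#'
#' Accepts BED with the family in the name column (column 4).
#'
#' @param path BED4+ file
#' @param genome optional \code{Seqinfo}
#' @return named \code{GRangesList}, one element per family
#' @export
readRepeats <- function(path, genome = NULL) {
  gr <- readBed(path, genome = genome)
  fam <- mcols(gr)$name
  if (is.null(fam))
    stop("readRepeats: a name column carrying the repeat family is required")
  mcols(gr) <- NULL
  GRangesList(lapply(split(gr, fam), sort))
}

#' Read a 4-column bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open)
#' @param genome \code{Seqinfo} with chromosome lengths (required: uncovered
#'   bases read as 0 up to the chromosome end)
#' @return a \linkS4class{SignalTrack}
#' @export
readBedgraph <- function(path, genome) {
  tl <- .readTabLines(path, 4L, "readBedgraph")
  f <- tl$fields; ln <- tl$lineNo
  if (!length(f)) {
    gr <- GRanges()
    mcols(gr)$score <- numeric(0)
    return(SignalTrack(gr, genome))
  }
  chrom <- vapply(f, `[[`, "", 1L)
  start0 <- .parseCoord(vapply(f, `[[`, "", 2L), ln, "readBedgraph", "start")
  end0 <- .parseCoord(vapply(f, `[[`, "", 3L), ln, "readBedgraph", "end")
  if (any(start0 >= end0))
    stop("readBedgraph: line ", ln[which(start0 >= end0)[1]],
         " has start >= end")
  val <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 4L)))
  if (anyNA(val) || any(val < 0))
    stop("readBedgraph: line ",
         ln[which(is.na(val) | val < 0)[1]],
         " has a missing or negative value")
  .checkAgainstGenome(chrom, start0, end0, genome, "readBedgraph")
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), score = val)
  if (!isDisjoint(gr, ignore.strand = TRUE))
    stop("readBedgraph: overlapping records in ", path)
  SignalTrack(gr, genome)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued intervals are emitted as given (no run merging).
#'
#' @param x a \linkS4class{SignalTrack}
#' @param path output file
#' @return the path, invisibly
#' @export
writeBedgraph <- function(x, path) {
  stopifnot(is(x, "SignalTrack"))
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x),
                   value = format(mcols(x)$score, trim = TRUE,
                                  scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an enrichment result table as TSV
#'
#' Emits a \code{#}-prefixed header line; infinite odds ratios are
#' serialized as \code{"inf"}.
#'
#' @param results data.frame from \code{\link{geneSetEnrichment}} or
#'   \code{\link{repeatFamilyEnrichment}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeEnrichmentTsv <- function(results, path) {
  df <- results
  if ("odds_ratio" %in% names(df)) {
    or <- df$odds_ratio
    df$odds_ratio <- ifelse(is.na(or), "NA",
                            ifelse(is.infinite(or), "inf",
                                   format(or, trim = TRUE)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
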