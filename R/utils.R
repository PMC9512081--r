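# Internal helpers shared across modules.

# Deterministic substream seed derived from a master seed. Keeps every
# derived seed inside the 32-bit integer range.
.substream <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + id * 7919) %% 2147483647L)
}

.checkSeed <- function(seed) {
  if (length(seed) != 1 || is.na(seed) || seed != floor(seed))
    stop("'seed' must be a single integer")
  as.integer(seed)
}

# Chromosome lengths for a GRanges, preferring an explicit Seqinfo.
.chromLengths <- function(genome = NULL, ...) {
  if (!is.null(genome)) {
    sl <- seqlengths(genome)
    if (anyNA(sl)) stop("genome has undefined chromosome lengths")
    return(sl)
  }
  grs <- Filter(function(g) length(g) > 0, list(...))
  if (!length(grs)) stop("no genome and no intervals to infer lengths from")
  all <- suppressWarnings(do.call(c, lapply(grs, granges)))
  sl <- vapply(split(end(all), as.character(seqnames(all))), max, 0)
  sl
}

# Strip strand and metadata; used before coverage-type arithmetic.
.bare <- function(gr) {
  gr <- granges(gr)
  strand(gr) <- "*"
  mcols(gr) <- NULL
  gr
}

.asGRList <- function(x, what = "sets") {
  if (is(x, "GRangesList")) x <- as.list(x)
  if (!is.list(x) || !length(x) || !all(vapply(x, is, TRUE, "GRanges")))
    stop("'", what, "' must be a non-empty list of GRanges")
  x
}

# Validate intervals against a Seqinfo; used by the readers.
.checkAgainstGenome <- function(chrom, start0, end0, genome, where = "input") {
  sl <- seqlengths(genome)
  bad <- !chrom %in% names(sl)
  if (any(bad))
    stop(where, ": chromosome(s) absent from genome: ",
         paste(unique(chrom[bad]), collapse = ", "))
  over <- end0 > sl[chrom]
  if (any(over))
    stop(where, ": interval end exceeds chromosome length on ",
         paste(unique(chrom[over]), collapse = ", "))
  invisible(TRUE)
}
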