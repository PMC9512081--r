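# The 2x2 statistical core: sample odds ratio, two-sided Fisher exact test
# by the point-probability rule, Benjamini-Hochberg correction, and the
# peak-proximity gene-set enrichment procedure built from them. Tables are
# parameterised (a, b, c, d) with a = in-set & proximal, b = in-set & not,
# c = proximal & not in-set, d = neither.

#' Sample odds ratio of a 2x2 table
#'
#' Returns \code{(a*d)/(b*c)}; \code{+Inf} when \code{b*c == 0} with
#' \code{a*d > 0}; \code{NA} (undefined) when both products are 0. With
#' \code{haldane = TRUE} the Haldane-Anscombe correction (0.5 added to every
#' cell) is applied instead, which is always finite.
#'
#' @param a,b,c,d non-negative integer counts (vectorised)
#' @param haldane apply the 0.5 continuity correction (default off)
#' @return numeric vector of odds ratios
#' @examples
#' oddsRatio(20, 80, 10, 90) # 2.25
#' @export
oddsRatio <- function(a, b, c, d, haldane = FALSE) {
  stopifnot(all(c(a, b, c, d) >= 0))
  if (haldane)
    return(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
  ad <- as.numeric(a) * as.numeric(d)
  bc <- as.numeric(b) * as.numeric(c)
  out <- ad / bc
  out[bc == 0 & ad > 0] <- Inf
  out[bc == 0 & ad == 0] <- NA_real_
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' With margins fixed, sums the hypergeometric probabilities of all tables
#' whose point probability is at most that of the observed table, using a
#' relative tie tolerance of 1e-7 (the dominant convention, stated explicitly
#' so ports in other languages agree). The returned p lies in (0, 1].
#'
#' @param a,b,c,d non-negative integer counts (vectorised)
#' @param tieTolerance relative tolerance for probability ties
#' @return numeric vector of two-sided p-values
#' @examples
#' fisherExactTwoSided(10, 10, 10, 10) # 1
#' @export
fisherExactTwoSided <- function(a, b, c, d, tieTolerance = 1e-7) {
  stopifnot(all(c(a, b, c, d) >= 0),
            all(c(a, b, c, d) == floor(c(a, b, c, d))))
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (r1 + r2 == 0) stop("all four counts are zero")
    lo <- max(0, k - r2); hi <- min(r1, k)
    pr <- stats::dhyper(lo:hi, r1, r2, k)
    pobs <- pr[a[i] - lo + 1]
    min(1, sum(pr[pr <= pobs * (1 + tieTolerance)]))
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' \code{q_(i) = min_{j >= i} p_(j) * m / j}, capped at 1, returned in input
#' order. Always at least the input p, elementwise.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return q-values in input order
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment near peaks
#'
#' For each gene set, builds the 2x2 table over the universe from two
#' indicator vectors -- membership in the set, and proximity of the gene
#' body to any peak within \code{maxDistance} -- then reports the sample
#' odds ratio, the two-sided Fisher exact p, and BH q-values computed across
#' exactly the family of sets passed in this one call (never pooled across
#' calls).
#'
#' @param peaks \code{GRanges}
#' @param genes \linkS4class{GeneTable}
#' @param universe character vector of gene ids defining the test space
#'   (e.g. all protein-coding or all expressed genes); set members outside
#'   the universe are dropped before counting
#' @param geneSets named list of gene-id character vectors
#' @param maxDistance proximity cutoff in bp (default 50 kb)
#' @param haldane passed to \code{\link{oddsRatio}}
#' @return data.frame: set_name, a, b, c, d, odds_ratio, p_value, q_value
#' @export
geneSetEnrichment <- function(peaks, genes, universe, geneSets,
                              maxDistance = 50000, haldane = FALSE) {
  stopifnot(is(genes, "GeneTable"))
  universe <- unique(universe)
  if (length(universe) == 0) stop("the gene universe is empty")
  missing <- setdiff(universe, geneIds(genes))
  if (length(missing))
    stop("universe contains gene ids absent from the gene table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(names(geneSets)) || any(!nzchar(names(geneSets))))
    stop("'geneSets' must be a named list")
  prox <- universe %in% proximalGeneIds(peaks, genes, maxDistance)
  counts <- t(vapply(geneSets, function(members) {
    inset <- universe %in% members
    c(a = sum(inset & prox), b = sum(inset & !prox),
      c = sum(!inset & prox), d = sum(!inset & !prox))
  }, numeric(4)))
  res <- data.frame(set_name = names(geneSets),
                    a = counts[, "a"], b = counts[, "b"],
                    c = counts[, "c"], d = counts[, "d"],
                    row.names = NULL)
  res$odds_ratio <- oddsRatio(res$a, res$b, res$c, res$d, haldane = haldane)
  res$p_value <- fisherExactTwoSided(res$a, res$b, res$c, res$d)
  res$q_value <- bhAdjust(res$p_value)
  res
}
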