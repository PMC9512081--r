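# Seeded generator of complete synthetic studies carrying the statistical
# structure the analyses assume: a target gene set with planted peak
# proximity (a configurable planted odds ratio), three peak tracks with
# planted three-way co-occupancy, repeat families with one planted
# within-peak density excess, and WT/KO coverage with planted fold changes
# over down- and up-regulated gene bodies. A single master seed feeds named
# substreams (genes, blacklist, target, decoys, peaks, co-occupancy,
# repeats, WT signal, KO signal, up set) so regenerating or nulling one
# component never perturbs the draws of another.

.SUBSTREAM <- c(genes = 1L, blacklist = 2L, target = 3L, decoys = 4L,
                peaks = 5L, cooccupancy = 6L, repeats = 7L,
                signal_wt = 8L, signal_ko = 9L, up_set = 10L,
                null_gene_sets = 20L, null_peaks = 21L, null_signal = 22L)

#' Synthetic-study configuration
#'
#' Returns the full configuration with this package's default study
#' conditions; any element can be overridden by passing a partial list of
#' the same shape. Defaults: a 5 x 60 Mb genome; 2,000 non-overlapping
#' genes (log-uniform lengths 1-10 kb, >= 110 kb intergenic gap -- wide
#' enough that a peak planted within the 50 kb window of one gene cannot be
#' proximal to a neighbour) including 20 clusters of 3 genes within 100 kb;
#' a 100-gene target set with planted proximity odds ratio 5 against a 15\%
#' per-gene background rate; 100 uniform background peaks per track and 150
#' shared loci copied into all 3 tracks with +/-50 bp jitter; three repeat
#' families of which LINE_like carries a 12x within-peak density excess;
#' Poisson(20) coverage per 50 bp bin with KO fold 0.5 over the down class
#' and 2 over the up class.
#'
#' @param ... partial overrides, e.g. \code{peaks = list(planted_or = 2)}
#' @param seed master seed stored in the config (default 1)
#' @return a nested configuration list of class \code{StudyConfig}
#' @export
studyConfig <- function(..., seed = 1L) {
  cfg <- list(
    genome = list(n_chroms = 5L, chrom_length = 60e6),
    genes = list(n_genes = 2000L, min_length = 1000, max_length = 10000,
                 min_gap = 110000, n_clusters = 20L, genes_per_cluster = 3L,
                 cluster_gap_min = 2000, cluster_gap_max = 15000),
    target_set_size = 100L,
    n_decoy_sets = 3L,
    decoy_set_size = 100L,
    peaks = list(planted_or = 5, p_nontarget = 0.15, p_target = NULL,
                 n_background = 100L, min_length = 200, max_length = 600,
                 placement_window = 50000),
    cooccupancy = list(n_tracks = 3L, n_shared_loci = 150L, jitter = 50,
                       locus_min = 300, locus_max = 500,
                       n_background_partner = 100L),
    repeats = list(families = data.frame(
      family = c("LINE_like", "SINE_like", "LTR_like"),
      density_per_mb = c(30, 60, 15),
      length_min = c(150, 150, 150),
      length_max = c(600, 400, 500),
      peak_excess = c(12, 1, 1))),
    signal = list(bin = 50L, lambda = 20, fold_down = 0.5, fold_up = 2,
                  up_set_size = 100L),
    blacklist = list(n_intervals = 25L, length = 40000),
    seed = .checkSeed(seed))
  over <- list(...)
  for (i in seq_along(over)) {
    nm <- names(over)[i]
    ov <- over[[i]]
    if (is.null(nm) || !nm %in% names(cfg))
      stop("unknown config field: ", nm)
    if (is.list(cfg[[nm]]) && is.list(ov) && !is.data.frame(ov)) {
      bad <- setdiff(names(ov), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config field: ", nm, "$", bad[1])
      cfg[[nm]][names(ov)] <- ov
    } else {
      cfg[[nm]] <- ov
    }
  }
  structure(cfg, class = "StudyConfig")
}

#' Read a study configuration from YAML
#'
#' Fields present in the file override the defaults of
#' \code{\link{studyConfig}}; everything else keeps its default.
#'
#' @param path YAML file mirroring the \code{studyConfig} structure
#' @return a \code{StudyConfig}
#' @export
studyConfigFromYaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$repeats$families))
    raw$repeats$families <- as.data.frame(raw$repeats$families)
  do.call(studyConfig, raw)
}

.plantedProbs <- function(pk) {
  p_nt <- pk$p_nontarget
  p_t <- pk$p_target
  if (is.null(p_t))
    p_t <- stats::plogis(log(pk$planted_or) + stats::qlogis(p_nt))
  or <- (p_t / (1 - p_t)) / (p_nt / (1 - p_nt))
  list(p_target = p_t, p_nontarget = p_nt, planted_or = or)
}

# Uniform placement of n intervals of the given widths on the genome
# (chromosome chosen proportional to length), with rejection against an
# excluded set.
.placeUniform <- function(n, widths, sl, excluded = NULL,
                          maxAttempts = 1000L) {
  if (n == 0)
    return(data.frame(chrom = character(0), start0 = numeric(0),
                      end0 = numeric(0)))
  chrom <- sample(names(sl), n, replace = TRUE,
                  prob = as.numeric(sl) / sum(as.numeric(sl)))
  widths <- rep_len(widths, n)
  s <- floor(stats::runif(n) * (sl[chrom] - widths + 1))
  if (!is.null(excluded) && length(excluded)) {
    for (att in seq_len(maxAttempts)) {
      cand <- GRanges(chrom, IRanges(s + 1, width = widths))
      bad <- overlapsAny(cand, excluded)
      if (!any(bad)) break
      if (att == maxAttempts)
        stop("could not place intervals outside exclusions")
      s[bad] <- floor(stats::runif(sum(bad)) * (sl[chrom[bad]] - widths[bad] + 1))
    }
  }
  data.frame(chrom = chrom, start0 = unname(s),
             end0 = unname(s + widths))
}

.generateGenes <- function(cfg, genomeSi, seed) {
  g <- cfg$genes
  nc <- length(seqlevels(genomeSi))
  sl <- seqlengths(genomeSi)
  nClustered <- g$n_clusters * g$genes_per_cluster
  nSingle <- g$n_genes - nClustered
  if (nSingle < 0) stop("genes do not fit: n_clusters * genes_per_cluster ",
                        "exceeds n_genes")
  m <- nSingle + g$n_clusters
  unitsPerChrom <- rep(m %/% nc, nc) + (seq_len(nc) <= m %% nc)
  clustersPerChrom <- tabulate(((seq_len(g$n_clusters) - 1) %% nc) + 1, nc)
  if (any(clustersPerChrom > unitsPerChrom))
    stop("genes do not fit: n_clusters too large for the genome")
  withr::with_seed(.substream(seed, .SUBSTREAM[["genes"]]), {
    rows <- list()
    clusterIdx <- list()
    for (ci in seq_len(nc)) {
      chrom <- seqlevels(genomeSi)[ci]
      L <- sl[[chrom]]
      nCl <- clustersPerChrom[ci]
      nSi <- unitsPerChrom[ci] - nCl
      # Unit = a single gene, or a whole cluster laid out internally first.
      units <- c(rep(list(NULL), nSi), vector("list", nCl))
      isCluster <- c(rep(FALSE, nSi), rep(TRUE, nCl))
      singleLens <- round(exp(stats::runif(nSi, log(g$min_length),
                                           log(g$max_length))))
      for (k in seq_len(nCl)) {
        lens <- round(exp(stats::runif(g$genes_per_cluster, log(g$min_length),
                                       log(g$max_length))))
        gaps <- round(stats::runif(g$genes_per_cluster - 1,
                                   g$cluster_gap_min, g$cluster_gap_max))
        off <- cumsum(c(0, lens[-length(lens)] + gaps))
        units[[nSi + k]] <- cbind(off = off, len = lens)
      }
      widths <- numeric(length(units))
      widths[!isCluster] <- singleLens
      widths[isCluster] <- vapply(units[isCluster],
                                  function(u) u[nrow(u), "off"] +
                                    u[nrow(u), "len"], numeric(1))
      ord <- sample.int(length(units))
      units <- units[ord]; isCluster <- isCluster[ord]
      widths <- widths[ord]
      mU <- length(units)
      free <- L - sum(widths) - (mU - 1) * g$min_gap
      if (free < 0)
        stop("genes do not fit on ", chrom,
             ": reduce genes$n_genes or genes$min_gap")
      extra <- diff(c(0, sort(stats::runif(mU, 0, free)), free))[seq_len(mU)]
      starts <- cumsum(extra + c(0, widths[-mU] + g$min_gap))
      for (ui in seq_len(mU)) {
        if (isCluster[ui]) {
          u <- units[[ui]]
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, start0 = starts[ui] + u[, "off"],
            end0 = starts[ui] + u[, "off"] + u[, "len"], cluster = TRUE)
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, start0 = starts[ui],
            end0 = starts[ui] + widths[ui], cluster = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    gr <- GRanges(df$chrom, IRanges(df$start0 + 1, df$end0),
                  strand = df$strand, seqinfo = genomeSi)
    ord <- order(match(as.character(seqnames(gr)), seqlevels(genomeSi)),
                 start(gr))
    gr <- gr[ord]
    clustered <- df$cluster[ord]
    mcols(gr)$gene_id <- sprintf("g%04d", seq_along(gr))
    mcols(gr)$biotype <- "protein_coding"
    list(genes = GeneTable(gr),
         clusterGenes = mcols(gr)$gene_id[clustered])
  })
}

.generateSignalTrack <- function(genomeSi, bin, lambdaByChrom, seed) {
  sl <- seqlengths(genomeSi)
  withr::with_seed(seed, {
    grl <- lapply(seqlevels(genomeSi), function(chrom) {
      nb <- sl[[chrom]] %/% bin
      vals <- stats::rpois(nb, lambdaByChrom[[chrom]])
      GRanges(chrom, successiveIRanges(rep.int(as.integer(bin), nb)),
              score = as.numeric(vals), seqinfo = genomeSi)
    })
    SignalTrack(suppressWarnings(do.call(c, grl)), genomeSi)
  })
}

# lambda vector per chromosome with fold applied to bins whose midpoint
# falls in the given gene bodies.
.lambdaWithFolds <- function(genomeSi, bin, lambda, bodiesByFold) {
  sl <- seqlengths(genomeSi)
  h <- bin %/% 2
  lams <- lapply(seqlevels(genomeSi), function(chrom) {
    nb <- sl[[chrom]] %/% bin
    lam <- rep(lambda, nb)
    for (bf in bodiesByFold) {
      sub <- bf$bodies[as.character(seqnames(bf$bodies)) == chrom]
      if (!length(sub)) next
      for (i in seq_along(sub)) {
        iMin <- max(0, ceiling((start(sub)[i] - 1 - h) / bin))
        iMax <- min(nb - 1, ceiling((end(sub)[i] - h) / bin) - 1)
        if (iMin <= iMax) lam[(iMin:iMax) + 1] <- lambda * bf$fold
      }
    }
    lam
  })
  names(lams) <- seqlevels(genomeSi)
  lams
}

#' Generate a complete synthetic study
#'
#' Deterministic given the master seed; each component draws from its own
#' named substream (genes, blacklist, target set, decoy sets, peaks,
#' co-occupancy, repeats, WT signal, KO signal, up set), so changing one
#' component's parameters does not perturb the others' draws.
#'
#' @param config a \code{\link{studyConfig}}
#' @param seed master seed (defaults to \code{config$seed})
#' @param components which optional components to generate; genes, gene
#'   sets, blacklist and the primary peak track are always generated
#' @param writeDir optional directory; when given, \code{\link{writeStudy}}
#'   is called on the result
#' @return a \linkS4class{StudyBundle}
#' @examples
#' cfg <- studyConfig(genome = list(n_chroms = 2L, chrom_length = 5e6),
#'                    genes = list(n_genes = 40L, min_gap = 60000,
#'                                 n_clusters = 2L),
#'                    target_set_size = 10L)
#' bundle <- generateStudy(cfg, seed = 1, components = character(0))
#' bundle
#' @export
generateStudy <- function(config = studyConfig(), seed = config$seed,
                          components = c("cooccupancy", "repeats", "signal"),
                          writeDir = NULL) {
  stopifnot(inherits(config, "StudyConfig"))
  seed <- .checkSeed(seed)
  bad <- setdiff(components, c("cooccupancy", "repeats", "signal"))
  if (length(bad)) stop("unknown component: ", bad[1])
  genomeSi <- genomeSpec(paste0("chr", seq_len(config$genome$n_chroms)),
                         rep(config$genome$chrom_length,
                             config$genome$n_chroms))
  sl <- seqlengths(genomeSi)

  gg <- .generateGenes(config, genomeSi, seed)
  genes <- gg$genes
  ids <- geneIds(genes)

  blacklist <- withr::with_seed(.substream(seed, .SUBSTREAM[["blacklist"]]), {
    df <- .placeUniform(config$blacklist$n_intervals,
                        config$blacklist$length, sl)
    sort(GRanges(df$chrom, IRanges(df$start0 + 1, df$end0),
                 seqinfo = genomeSi), ignore.strand = TRUE)
  })

  targetSet <- withr::with_seed(.substream(seed, .SUBSTREAM[["target"]]),
                                sample(ids, config$target_set_size))
  decoys <- withr::with_seed(.substream(seed, .SUBSTREAM[["decoys"]]), {
    out <- lapply(seq_len(config$n_decoy_sets), function(i)
      sample(ids, config$decoy_set_size))
    names(out) <- paste0("random", seq_along(out))
    out
  })
  geneSets <- c(list(target = targetSet), decoys)

  pp <- .plantedProbs(config$peaks)
  pk <- config$peaks
  mainPeaks <- withr::with_seed(.substream(seed, .SUBSTREAM[["peaks"]]), {
    p <- ifelse(ids %in% targetSet, pp$p_target, pp$p_nontarget)
    hit <- stats::runif(length(ids)) < p
    gb <- geneBodies(genes)[hit]
    w <- round(stats::runif(sum(hit), pk$min_length, pk$max_length))
    W <- pk$placement_window
    lo <- start(gb) - 1 - W
    hiS <- end(gb) + W - w
    s0 <- floor(stats::runif(sum(hit)) * (hiS - lo + 1)) + lo
    s0 <- pmax(0, pmin(s0, sl[as.character(seqnames(gb))] - w))
    planted <- GRanges(seqnames(gb), IRanges(s0 + 1, width = w),
                       seqinfo = genomeSi)
    bgw <- round(stats::runif(pk$n_background, pk$min_length, pk$max_length))
    bg <- .placeUniform(pk$n_background, bgw, sl, excluded = blacklist)
    bgGR <- GRanges(bg$chrom, IRanges(bg$start0 + 1, bg$end0),
                    seqinfo = genomeSi)
    list(gr = sort(c(planted, bgGR), ignore.strand = TRUE),
         nPlantedTarget = sum(hit & ids %in% targetSet),
         nPlantedOther = sum(hit & !ids %in% targetSet))
  })

  co <- config$cooccupancy
  nTracks <- if ("cooccupancy" %in% components) co$n_tracks else 1L
  tracks <- vector("list", nTracks)
  sharedDf <- NULL
  if ("cooccupancy" %in% components) {
    res <- withr::with_seed(.substream(seed, .SUBSTREAM[["cooccupancy"]]), {
      lw <- round(stats::runif(co$n_shared_loci, co$locus_min, co$locus_max))
      sh <- .placeUniform(co$n_shared_loci, lw, sl, excluded = blacklist)
      perTrack <- lapply(seq_len(co$n_tracks), function(t) {
        if (nrow(sh) == 0)
          return(GRanges(seqinfo = genomeSi))
        shift <- round(stats::runif(nrow(sh), -co$jitter, co$jitter))
        w <- sh$end0 - sh$start0
        s0 <- pmax(0, pmin(sh$start0 + shift, sl[sh$chrom] - w))
        gr <- GRanges(sh$chrom, IRanges(s0 + 1, width = w),
                      seqinfo = genomeSi)
        if (t > 1) {
          bgw <- round(stats::runif(co$n_background_partner,
                                    pk$min_length, pk$max_length))
          bg <- .placeUniform(co$n_background_partner, bgw, sl,
                              excluded = blacklist)
          gr <- c(gr, GRanges(bg$chrom, IRanges(bg$start0 + 1, bg$end0),
                              seqinfo = genomeSi))
        }
        sort(gr, ignore.strand = TRUE)
      })
      list(perTrack = perTrack, shared = sh)
    })
    sharedDf <- res$shared
    tracks[[1]] <- sort(c(mainPeaks$gr, res$perTrack[[1]]),
                        ignore.strand = TRUE)
    for (t in seq_len(nTracks)[-1]) tracks[[t]] <- res$perTrack[[t]]
  } else {
    tracks[[1]] <- mainPeaks$gr
  }
  names(tracks) <- paste0("tf", seq_len(nTracks))
  peaks <- GRangesList(tracks)

  repeatsGRL <- GRangesList()
  if ("repeats" %in% components) {
    fams <- config$repeats$families
    main <- peaks[[1]]
    peakMb <- coveredBases(main) / 1e6
    repeatsGRL <- withr::with_seed(.substream(seed, .SUBSTREAM[["repeats"]]), {
      out <- lapply(seq_len(nrow(fams)), function(fi) {
        fam <- fams[fi, ]
        counts <- stats::rpois(length(sl), fam$density_per_mb *
                                 as.numeric(sl) / 1e6)
        dfs <- lapply(seq_along(sl), function(ci) {
          n <- counts[ci]
          if (n == 0) return(NULL)
          w <- round(stats::runif(n, fam$length_min, fam$length_max))
          s <- floor(stats::runif(n) * (sl[[ci]] - w + 1))
          data.frame(chrom = names(sl)[ci], start0 = s, end0 = s + w)
        })
        df <- do.call(rbind, dfs)
        if (fam$peak_excess > 1 && length(main) > 0 && peakMb > 0) {
          nEx <- stats::rpois(1, fam$density_per_mb * peakMb *
                                (fam$peak_excess - 1))
          if (nEx > 0) {
            pi <- sample.int(length(main), nEx, replace = TRUE)
            w <- round(stats::runif(nEx, fam$length_min, fam$length_max))
            ps0 <- start(main)[pi] - 1
            pe0 <- end(main)[pi]
            s0 <- ps0 + floor(stats::runif(nEx) * (pe0 - ps0))
            ch <- as.character(seqnames(main))[pi]
            e0 <- pmin(s0 + w, sl[ch])
            df <- rbind(df, data.frame(chrom = ch, start0 = s0, end0 = e0))
          }
        }
        if (is.null(df)) return(GRanges(seqinfo = genomeSi))
        sort(GRanges(df$chrom, IRanges(df$start0 + 1, df$end0),
                     seqinfo = genomeSi), ignore.strand = TRUE)
      })
      names(out) <- fams$family
      GRangesList(out)
    })
  }

  sg <- config$signal
  upSet <- withr::with_seed(.substream(seed, .SUBSTREAM[["up_set"]]),
                            sample(setdiff(ids, targetSet),
                                   sg$up_set_size))
  deClasses <- stats::setNames(rep("unchanged", length(ids)), ids)
  deClasses[targetSet] <- "down"
  deClasses[upSet] <- "up"

  wt <- NULL; ko <- NULL
  if ("signal" %in% components) {
    flat <- lapply(seqlevels(genomeSi), function(ch)
      rep(sg$lambda, sl[[ch]] %/% sg$bin))
    names(flat) <- seqlevels(genomeSi)
    wt <- .generateSignalTrack(genomeSi, sg$bin, flat,
                               .substream(seed, .SUBSTREAM[["signal_wt"]]))
    bodies <- geneBodies(genes)
    lamKo <- .lambdaWithFolds(genomeSi, sg$bin, sg$lambda, list(
      list(bodies = bodies[targetSet], fold = sg$fold_down),
      list(bodies = bodies[upSet], fold = sg$fold_up)))
    ko <- .generateSignalTrack(genomeSi, sg$bin, lamKo,
                               .substream(seed, .SUBSTREAM[["signal_ko"]]))
  }

  manifest <- list(
    seed = seed,
    planted_or = pp$planted_or,
    p_target = pp$p_target,
    p_nontarget = pp$p_nontarget,
    n_target = length(targetSet),
    n_planted_target_peaks = mainPeaks$nPlantedTarget,
    n_planted_nontarget_peaks = mainPeaks$nPlantedOther,
    target_ids = targetSet,
    up_ids = upSet,
    cluster_gene_ids = gg$clusterGenes,
    shared_loci = sharedDf,
    enriched_repeat_family = if ("repeats" %in% components)
      config$repeats$families$family[config$repeats$families$peak_excess > 1]
      else character(0),
    fold_down = sg$fold_down,
    fold_up = sg$fold_up,
    peak_counts = stats::setNames(as.integer(lengths(peaks)), names(peaks)))

  bundle <- new("StudyBundle", genome = genomeSi, genes = genes,
                geneSets = geneSets, targetSet = targetSet,
                backgroundPool = ids, peaks = peaks, repeats = repeatsGRL,
                blacklist = blacklist, wt = wt, ko = ko,
                deClasses = deClasses, manifest = manifest,
                config = unclass(config), seed = seed)
  if (!is.null(writeDir)) writeStudy(bundle, writeDir)
  bundle
}

#' Destroy one planted structure of a study
#'
#' Returns a copy of the bundle with the chosen component's planted signal
#' removed, everything else fixed: \code{gene_sets} redraws the target set
#' uniformly from the background pool; \code{peaks} re-shuffles every peak
#' track within chromosomes (avoiding the blacklist); \code{signal}
#' regenerates the KO track with both folds set to 1.
#'
#' @param bundle a \linkS4class{StudyBundle}
#' @param which \code{"gene_sets"}, \code{"peaks"} or \code{"signal"}
#' @param seed integer seed for the null draw
#' @return a \linkS4class{StudyBundle}
#' @export
nullVariant <- function(bundle, which = c("gene_sets", "peaks", "signal"),
                        seed) {
  stopifnot(is(bundle, "StudyBundle"))
  which <- match.arg(which)
  seed <- .checkSeed(seed)
  out <- bundle
  if (which == "gene_sets") {
    newTarget <- withr::with_seed(
      .substream(seed, .SUBSTREAM[["null_gene_sets"]]),
      sample(bundle@backgroundPool, length(bundle@targetSet)))
    out@targetSet <- newTarget
    out@geneSets[["target"]] <- newTarget
  } else if (which == "peaks") {
    base <- .substream(seed, .SUBSTREAM[["null_peaks"]])
    shuffled <- lapply(seq_along(bundle@peaks), function(i)
      shuffleIntervals(bundle@peaks[[i]], bundle@genome,
                       excluded = bundle@blacklist,
                       seed = .substream(base, i)))
    names(shuffled) <- names(bundle@peaks)
    out@peaks <- GRangesList(shuffled)
  } else {
    if (is.null(bundle@wt)) stop("the bundle has no signal component")
    sg <- bundle@config$signal
    sl <- seqlengths(bundle@genome)
    flat <- lapply(seqlevels(bundle@genome), function(ch)
      rep(sg$lambda, sl[[ch]] %/% sg$bin))
    names(flat) <- seqlevels(bundle@genome)
    out@ko <- .generateSignalTrack(bundle@genome, sg$bin, flat,
                                   .substream(seed,
                                              .SUBSTREAM[["null_signal"]]))
  }
  out@manifest$nulled <- which
  out
}

#' Write a study bundle to disk as plain-text files
#'
#' Emits chrom.sizes, genes.bed, genesets.tsv, peaks_<track>.bed,
#' repeats.bed, blacklist.bed, de_classes.tsv, wt.bedgraph / ko.bedgraph
#' (when signal was generated), manifest.json and config.yaml. Every file
#' re-reads into an object passing its type's invariants.
#'
#' @param bundle a \linkS4class{StudyBundle}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeStudy <- function(bundle, dir) {
  stopifnot(is(bundle, "StudyBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  si <- bundle@genome
  utils::write.table(data.frame(seqlevels(si), seqlengths(si)),
                     file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  genesGR <- granges(bundle@genes)
  mcols(genesGR)$name <- geneIds(bundle@genes)
  mcols(genesGR)$score <- 0
  writeBed(genesGR, file.path(dir, "genes.bed"))
  sets <- bundle@geneSets
  gsDf <- data.frame(set_name = rep(names(sets), lengths(sets)),
                     gene_id = unlist(sets, use.names = FALSE))
  utils::write.table(gsDf, file.path(dir, "genesets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (nm in names(bundle@peaks))
    writeBed(bundle@peaks[[nm]], file.path(dir, paste0("peaks_", nm, ".bed")))
  if (length(bundle@repeats)) {
    rep.gr <- unlist(bundle@repeats, use.names = FALSE)
    mcols(rep.gr)$name <- rep(names(bundle@repeats),
                              lengths(bundle@repeats))
    writeBed(sort(rep.gr, ignore.strand = TRUE),
             file.path(dir, "repeats.bed"))
  }
  writeBed(bundle@blacklist, file.path(dir, "blacklist.bed"))
  utils::write.table(data.frame(names(bundle@deClasses),
                                unname(bundle@deClasses)),
                     file.path(dir, "de_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(bundle@wt)) {
    writeBedgraph(bundle@wt, file.path(dir, "wt.bedgraph"))
    writeBedgraph(bundle@ko, file.path(dir, "ko.bedgraph"))
  }
  man <- bundle@manifest
  if (!is.null(man$shared_loci)) man$shared_loci <- as.list(man$shared_loci)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- bundle@config
  cfg$repeats$families <- as.list(cfg$repeats$families)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
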